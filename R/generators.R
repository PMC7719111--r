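# Seeded generators for worked-example systems and random test systems.
# All generators are pure functions of their arguments plus the seed; the
# RNG kind is pinned so the same call always yields identical objects.

#' Six-node binary example with three interaction terms
#'
#' The instructive system with binary inputs `x1..x6`, binary output, and
#' interaction terms supported exactly on `{x1,x2,x3}`, `{x3,x4}` and
#' `{x5,x6}`, with values drawn uniformly in `[-amplitude, amplitude]`.
#' Knocking out node 3 removes the first two terms, so the surviving
#' kernel depends only on `(x5, x6)`.
#'
#' @param seed integer seed.
#' @param amplitude positive half-width of the uniform value range.
#' @return List with `system`, `interactions` (an [interaction_family()])
#'   and `modalities` (all 64 post-knockout kernels).
#' @export
gen_six_node <- function(seed, amplitude = 1) {
  stopifnot(amplitude > 0)
  sys <- state_system(
    stats::setNames(rep(list(c("0", "1")), 6), paste0("x", 1:6)),
    c("0", "1"))
  supports <- list(c("x1", "x2", "x3"), c("x3", "x4"), c("x5", "x6"))
  terms <- seeded(seed, {
    lapply(supports, function(A) {
      m <- n_configs(sys, A)
      matrix(stats::runif(m * 2, -amplitude, amplitude), m, 2)
    })
  })
  names(terms) <- vapply(supports, set_key, character(1))
  phi <- interaction_family(sys, terms)
  list(system = sys, interactions = phi,
       modalities = modalities_from_interactions(phi))
}

#' Stochastic neuron with weighted inputs
#'
#' A neuron with inputs in `{-1, +1}` firing (`y = +1`) with probability
#' \eqn{1 / (1 + e^{-\sum_i w_i x_i})}. Its energy decomposes into the
#' singleton terms \eqn{\phi_{\{i\}}(x_i; y) = \tfrac12 w_i x_i y}, so the
#' post-knockout kernel after removing a node set is exactly the logistic
#' of the surviving weighted sum.
#'
#' @param weights numeric vector of synaptic weights `w_1..w_n`.
#' @return List with `system`, `interactions`, and `kernel` (the
#'   closed-form unperturbed kernel).
#' @export
gen_neuron <- function(weights) {
  stopifnot(is.numeric(weights), length(weights) >= 1, all(is.finite(weights)))
  n <- length(weights)
  nms <- paste0("x", seq_len(n))
  sys <- state_system(
    stats::setNames(rep(list(c("-1", "+1")), n), nms), c("-1", "+1"))
  terms <- lapply(seq_len(n), function(i) {
    xv <- c(-1, 1); yv <- c(-1, 1)
    outer(xv, yv, function(x, y) 0.5 * weights[i] * x * y)
  })
  names(terms) <- nms
  phi <- interaction_family(sys, terms)
  list(system = sys, interactions = phi,
       kernel = neuron_modality(weights, seq_len(n), sys))
}

#' @rdname gen_neuron
#' @param surviving indices (or names `x<i>`) of the surviving inputs `J`.
#' @param system the neuron's state system (rebuilt from `weights` when
#'   omitted).
#' @return `neuron_modality()`: the closed-form logistic post-knockout
#'   kernel \eqn{\kappa_J(x_J; +1) = 1/(1 + e^{-\sum_{i \in J} w_i x_i})}.
#' @export
neuron_modality <- function(weights, surviving, system = NULL) {
  n <- length(weights)
  if (is.null(system)) {
    nms <- paste0("x", seq_len(n))
    system <- state_system(
      stats::setNames(rep(list(c("-1", "+1")), n), nms), c("-1", "+1"))
  }
  J <- if (is.character(surviving)) canon_inputs(system, surviving)
       else system$input_names[sort(surviving)]
  idx <- match(J, system$input_names)
  codes <- config_codes(system, J)                 # 0 -> -1, 1 -> +1
  s <- if (length(J) == 0) rep(0, 1)
       else drop((2 * codes - 1) %*% weights[idx])
  p_plus <- 1 / (1 + exp(-s))
  new_kernel(system, J, unname(cbind(1 - p_plus, p_plus)))
}

#' Two-input grid support with a prescribed component count
#'
#' A system with two inputs on 16 states each (256 joint configurations).
#' Builds a support set with exactly `n_components` connected components
#' under Hamming-distance-1 adjacency (two configurations are adjacent when
#' they share either coordinate), with the uniform input distribution on
#' the support. Each component is a random "cross" inside its own block of
#' rows and columns, so components can never touch.
#'
#' @param seed integer seed.
#' @param n_components requested component count, between 1 and 16.
#' @return List with `system`, `mu` (uniform on the support), `support`
#'   (tibble) and `partition` (the [hamming_components()] of the support at
#'   `k = 1`).
#' @export
gen_grid_support <- function(seed, n_components) {
  if (n_components < 1 || n_components > 16)
    stop("between 1 and 16 components are feasible for the cross construction",
         call. = FALSE)
  labs <- as.character(1:16)
  sys <- state_system(list(x1 = labs, x2 = labs), c("0", "1"))
  # disjoint row and column blocks, one per component
  cuts <- floor(seq(0, 16, length.out = n_components + 1))
  S <- seeded(seed, {
    parts <- lapply(seq_len(n_components), function(i) {
      rows <- (cuts[i] + 1):cuts[i + 1]
      cols <- (cuts[i] + 1):cuts[i + 1]
      r0 <- if (length(rows) == 1) rows else sample(rows, 1)
      c0 <- if (length(cols) == 1) cols else sample(cols, 1)
      rbind(expand.grid(x1 = rows, x2 = c0),
            expand.grid(x1 = r0, x2 = cols))
    })
    do.call(rbind, parts)
  })
  S <- unique(data.frame(x1 = as.character(S$x1), x2 = as.character(S$x2)))
  grid <- configurations(sys)
  mu_tab <- dplyr::mutate(S, p = 1 / nrow(S))
  mu <- as_input_dist(mu_tab, sys)
  list(system = sys, mu = mu, support = support(mu),
       partition = hamming_components(mu, 1))
}

#' Random system: input distribution plus interaction family
#'
#' Reproducible random test systems: a positive (or sparse-support) input
#' distribution with exponential weights, and Gaussian interaction terms on
#' given hyperedges or on randomly included subsets.
#'
#' @param seed integer seed.
#' @param n number of input nodes (at most 16 for full-lattice use).
#' @param alphabet_sizes integer vector (recycled to length `n`) of input
#'   alphabet sizes; labels are `"0", "1", ...`.
#' @param n_outputs output alphabet size.
#' @param hyperedges optional list of node-name vectors carrying
#'   interaction terms; overrides `density`.
#' @param density probability for each non-empty subset to carry a term
#'   (used when `hyperedges` is `NULL`; `0` gives the empty family and a
#'   uniform kernel).
#' @param support_density probability for a configuration to be in the
#'   support of `mu` (1 = full support; at least one configuration is
#'   always kept).
#' @param sd standard deviation of the Gaussian term values.
#' @return List with `system`, `mu` and `interactions`.
#' @export
gen_random_system <- function(seed, n, alphabet_sizes = 2, n_outputs = 2,
                              hyperedges = NULL, density = 0.3,
                              support_density = 1, sd = 1) {
  stopifnot(n >= 1, n <= 16)
  sizes <- rep_len(alphabet_sizes, n)
  nms <- paste0("x", seq_len(n))
  sys <- state_system(
    stats::setNames(lapply(sizes, function(s) as.character(0:(s - 1))), nms),
    as.character(0:(n_outputs - 1)))
  seeded(seed, {
    m <- n_configs(sys)
    keep <- stats::runif(m) < support_density
    if (!any(keep)) keep[sample.int(m, 1)] <- TRUE
    w <- ifelse(keep, stats::rexp(m), 0)
    mu <- as_input_dist(w / sum(w), sys)
    if (is.null(hyperedges)) {
      cand <- Filter(function(A) length(A) > 0, all_subsets(nms))
      hyperedges <- cand[stats::runif(length(cand)) < density]
    } else {
      hyperedges <- lapply(hyperedges, function(A) canon_inputs(sys, A))
    }
    terms <- lapply(hyperedges, function(A) {
      mA <- n_configs(sys, A)
      matrix(stats::rnorm(mA * n_outputs, sd = sd), mA, n_outputs)
    })
    names(terms) <- vapply(hyperedges, set_key, character(1))
    list(system = sys, mu = mu, interactions = interaction_family(sys, terms))
  })
}

#' Random strictly positive Markov kernel
#'
#' @param seed integer seed.
#' @param system a [state_system()].
#' @param inputs surviving input subset the kernel conditions on.
#' @return A strictly positive `"markov_kernel"` with independent
#'   exponential row weights, row-normalised.
#' @export
gen_random_kernel <- function(seed, system, inputs = system$input_names) {
  inputs <- canon_inputs(system, inputs)
  m <- n_configs(system, inputs)
  ny <- length(system$output_alphabet)
  W <- seeded(seed, matrix(stats::rexp(m * ny), m, ny))
  new_kernel(system, inputs, W / rowSums(W))
}
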