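#' Connected components of a support set under bounded-Hamming adjacency
#'
#' Connects two support configurations when their Hamming distance is at
#' most `k` (the canonical adjacency for knockouts of up to `k` nodes), and
#' partitions the support into the connected components \eqn{\mathfrak{N}(S)}
#' of the resulting graph. A kernel that is constant on each component is
#' exactly the neutral construction of a k-exclusion independent system.
#'
#' @param x the support: a tibble/data frame of configurations (one column
#'   per input node), or an `"input_dist"` whose support is used.
#' @param k maximal knockout size (`k = 0` makes every configuration its
#'   own component).
#' @param system the [state_system()]; not needed when `x` is an
#'   `"input_dist"`.
#' @param adjacency optional custom relation, a `function(x, x_prime)`
#'   receiving two one-row data frames of labels and returning `TRUE` when
#'   they are to be connected. Non-canonical; provided for illustrations
#'   such as grid-metric neighbourhoods. When supplied, `k` is ignored for
#'   adjacency (but recorded).
#' @return An object of class `"component_partition"`: list with `system`,
#'   `support` (tibble in canonical order), `k`, `membership` (component id
#'   per support row), `components` (named list of support row indices; each
#'   component is named after, and ordered by, its lexicographically
#'   smallest member).
#' @export
hamming_components <- function(x, k, system = NULL, adjacency = NULL) {
  if (inherits(x, "input_dist")) {
    system <- x$system
    S <- support(x)
  } else {
    if (is.null(system)) stop("`system` is required when `x` is a table", call. = FALSE)
    S <- tibble::as_tibble(as.data.frame(x))[, system$input_names, drop = FALSE]
    S <- S[order(config_index(system, S, system$input_names)), , drop = FALSE]
    if (anyDuplicated(config_index(system, S, system$input_names)))
      stop("duplicated configurations in support", call. = FALSE)
  }
  if (nrow(S) == 0) stop("support set is empty", call. = FALSE)
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  m <- nrow(S)
  edges <- integer(0)
  if (m >= 2) {
    if (is.null(adjacency)) {
      codes <- as.matrix(as.data.frame(lapply(system$input_names, function(nm)
        match(S[[nm]], system$input_alphabets[[nm]]))))
      for (i in seq_len(m - 1)) {
        d <- rowSums(codes[(i + 1):m, , drop = FALSE] !=
                       matrix(codes[i, ], m - i, ncol(codes), byrow = TRUE))
        hits <- which(d <= k)
        if (length(hits) > 0) edges <- c(edges, rbind(i, i + hits))
      }
    } else {
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        if (isTRUE(adjacency(S[i, , drop = FALSE], S[j, , drop = FALSE])))
          edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  memb <- igraph::components(g)$membership
  # rename components by their lexicographically smallest member (support is
  # already in canonical order, so first occurrence = smallest member)
  relabel <- match(memb, unique(memb))
  comp_ids <- sort(unique(relabel))
  components <- lapply(comp_ids, function(ci) which(relabel == ci))
  names(components) <- vapply(components, function(ix)
    paste(unlist(S[ix[1], ]), collapse = ","), character(1))
  structure(list(system = system, support = S, k = k,
                 membership = relabel, components = components),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  cat("<component_partition>", nrow(x$support), "support configurations,",
      length(x$components), "component(s) at k =", x$k, "\n")
  sizes <- vapply(x$components, length, integer(1))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.component_partition <- function(x, ...) {
  out <- x$support
  out$component <- names(x$components)[x$membership]
  tibble::as_tibble(out)
}

#' Build a neutral kernel from the components of an input support
#'
#' The construction that guarantees k-exclusion independence: compute the
#' connected components of the support of `mu` under Hamming-\eqn{\le k}
#' adjacency, then give every configuration of a component the same output
#' distribution \eqn{\lambda_N}. Off-support rows are arbitrary in the
#' theory; here they default to uniform.
#'
#' @param mu an [as_input_dist()] object.
#' @param k maximal knockout size the kernel must tolerate.
#' @param lambdas named list of output distributions (numeric vectors over
#'   the output alphabet), keyed by component name as produced by
#'   [hamming_components()]; or a single unnamed distribution used for every
#'   component.
#' @param off_support rule for rows outside the support; only `"uniform"`.
#' @return A `"markov_kernel"` on the full input set. The pair
#'   `(mu, kernel)` passes [k_exclusion_independent()] at level `k`.
#' @export
neutral_kernel <- function(mu, k, lambdas, off_support = c("uniform")) {
  stopifnot(inherits(mu, "input_dist"))
  off_support <- match.arg(off_support)
  sys <- mu$system
  part <- hamming_components(mu, k)
  ny <- length(sys$output_alphabet)
  if (is.numeric(lambdas)) lambdas <- stats::setNames(
    rep(list(lambdas), length(part$components)), names(part$components))
  miss <- setdiff(names(part$components), names(lambdas))
  if (length(miss) > 0)
    stop("missing output distribution for component(s): ",
         paste(miss, collapse = "; "), call. = FALSE)
  K <- matrix(1 / ny, n_configs(sys), ny)
  sup_idx <- which(mu$p > 0)
  for (nm in names(part$components)) {
    lam <- as.numeric(lambdas[[nm]])
    if (length(lam) != ny || any(lam < 0) || abs(sum(lam) - 1) > 1e-9)
      stop("invalid output distribution for component ", nm, call. = FALSE)
    lam <- lam / sum(lam)
    rows <- sup_idx[part$components[[nm]]]
    K[rows, ] <- matrix(lam, length(rows), ny, byrow = TRUE)
  }
  new_kernel(sys, sys$input_names, K)
}

#' Neutral mixture model of a robust joint distribution
#'
#' The structural form every k-exclusion independent joint distribution
#' takes: a mixture over the connected components `N` of the support, with
#' component weights `alpha`, per-component input distributions `mu_n`
#' (supported exactly on their component) and output distributions
#' `lambda_n`.
#'
#' @param partition a [hamming_components()] result.
#' @param alpha numeric vector of component weights (named by component or
#'   in component order); must sum to 1.
#' @param mu_n named list (by component) of input distributions restricted
#'   to the component: numeric vectors over the component's member
#'   configurations (in component order), summing to 1, all positive.
#' @param lambda_n named list (by component) of output distributions.
#' @return An object of class `"neutral_mixture"`.
#' @export
neutral_mixture <- function(partition, alpha, mu_n, lambda_n) {
  stopifnot(inherits(partition, "component_partition"))
  comp_names <- names(partition$components)
  if (is.null(names(alpha))) names(alpha) <- comp_names
  alpha <- alpha[comp_names]
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-9)
    stop("`alpha` must be a probability vector over components", call. = FALSE)
  ny <- length(partition$system$output_alphabet)
  for (nm in comp_names) {
    sz <- length(partition$components[[nm]])
    v <- mu_n[[nm]]
    if (length(v) != sz || any(v <= 0) || abs(sum(v) - 1) > 1e-9)
      stop("`mu_n[[", nm, "]]` must be positive on its component and sum to 1",
           call. = FALSE)
    l <- lambda_n[[nm]]
    if (length(l) != ny || any(l < 0) || abs(sum(l) - 1) > 1e-9)
      stop("`lambda_n[[", nm, "]]` must be a distribution over the output alphabet",
           call. = FALSE)
  }
  structure(list(partition = partition, alpha = alpha / sum(alpha),
                 mu_n = mu_n[comp_names], lambda_n = lambda_n[comp_names]),
            class = "neutral_mixture")
}

#' @export
print.neutral_mixture <- function(x, ...) {
  cat("<neutral_mixture>", length(x$alpha), "component(s), weights:",
      paste(sprintf("%.4g", x$alpha), collapse = ", "), "\n")
  invisible(x)
}

#' Joint distribution of a neutral mixture
#'
#' \eqn{p(x, y) = \sum_N \alpha(N) \mu_N(x) \lambda_N(y)}. The resulting
#' joint distribution is k-exclusion independent at the partition's `k`.
#'
#' @param mixture a [neutral_mixture()].
#' @return A `"joint_dist"`.
#' @export
mixture_joint <- function(mixture) {
  stopifnot(inherits(mixture, "neutral_mixture"))
  part <- mixture$partition
  sys <- part$system
  P <- matrix(0, n_configs(sys), length(sys$output_alphabet))
  sup_idx <- config_index(sys, part$support, sys$input_names)
  for (nm in names(part$components)) {
    rows <- sup_idx[part$components[[nm]]]
    P[rows, ] <- P[rows, ] +
      mixture$alpha[[nm]] * outer(mixture$mu_n[[nm]], mixture$lambda_n[[nm]])
  }
  new_joint(sys, P)
}

#' Decompose a robust joint distribution into a neutral mixture
#'
#' The converse direction of the neutrality characterisation: if the
#' conditional output distribution \eqn{p(y | x)} is constant (sup-norm
#' within `tol`) on every connected component of the input support at level
#' `k`, the joint distribution is returned in mixture form; [mixture_joint()]
#' of the result reproduces `p` within `tol`. Otherwise the decomposition is
#' rejected with the first offending pair of same-component configurations
#' in canonical scan order.
#'
#' @param p a [as_joint_dist()] object.
#' @param k maximal knockout size defining the component structure.
#' @param tol sup-norm tolerance for "constant conditional" (default `1e-9`).
#' @return An object of class `"robust_decomposition"`: list with `accepted`
#'   (logical), `mixture` (a [neutral_mixture()], when accepted), `witness`
#'   (offending pair with its sup-norm difference, when rejected), `k`,
#'   `tol`, and `max_within_diff` (largest within-component conditional
#'   difference observed).
#' @export
decompose_robust_joint <- function(p, k, tol = 1e-9) {
  stopifnot(inherits(p, "joint_dist"))
  sys <- p$system
  mu <- rowSums(p$prob)
  sup_idx <- which(mu > 0)
  S <- configurations(sys)[sup_idx, , drop = FALSE]
  part <- hamming_components(S, k, system = sys)
  cond <- p$prob[sup_idx, , drop = FALSE] / mu[sup_idx]
  max_diff <- 0
  witness <- NULL
  for (nm in names(part$components)) {
    ix <- part$components[[nm]]
    if (length(ix) < 2) next
    ref <- cond[ix[1], ]
    for (j in ix[-1]) {
      d <- max(abs(cond[j, ] - ref))
      if (d > max_diff) max_diff <- d
      if (d > tol && is.null(witness))
        witness <- list(x = S[ix[1], , drop = FALSE],
                        x_prime = S[j, , drop = FALSE],
                        component = nm, sup_diff = d)
    }
  }
  if (!is.null(witness))
    return(structure(list(accepted = FALSE, mixture = NULL, witness = witness,
                          k = k, tol = tol, max_within_diff = max_diff),
                     class = "robust_decomposition"))
  alpha <- mu_n <- lambda_n <- list()
  for (nm in names(part$components)) {
    ix <- part$components[[nm]]
    w <- mu[sup_idx][ix]
    alpha[[nm]] <- sum(w)
    mu_n[[nm]] <- w / sum(w)
    # mass-weighted mean conditional: reproduces p within tol
    lam <- colSums(p$prob[sup_idx[ix], , drop = FALSE]) / sum(w)
    lambda_n[[nm]] <- lam / sum(lam)
  }
  mix <- neutral_mixture(part, unlist(alpha), mu_n, lambda_n)
  structure(list(accepted = TRUE, mixture = mix, witness = NULL,
                 k = k, tol = tol, max_within_diff = max_diff),
            class = "robust_decomposition")
}

#' @export
print.robust_decomposition <- function(x, ...) {
  if (x$accepted) {
    cat("<robust_decomposition> accepted:",
        length(x$mixture$alpha), "component(s), max within-component",
        sprintf("conditional difference %.3g (tol %g)\n", x$max_within_diff, x$tol))
  } else {
    cat("<robust_decomposition> REJECTED: conditional differs by",
        sprintf("%.3g (tol %g) within component {%s}\n",
                x$witness$sup_diff, x$tol, x$witness$component))
  }
  invisible(x)
}
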