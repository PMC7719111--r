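#' Kullback-Leibler divergence between two finite probability vectors
#'
#' \eqn{D(p \| q) = \sum_z p(z) \ln(p(z)/q(z))} in nats, with the
#' conventions \eqn{0 \ln(0/q) = 0} and \eqn{p \ln(p/0) = \infty} when
#' \eqn{p > 0}. Infinity is returned as `Inf`, never as a finite sentinel.
#'
#' @param p,q numeric probability vectors over the same finite set (same
#'   length; if both are named, names must agree). Each must sum to 1
#'   within `tol`.
#' @param tol normalisation tolerance (default `1e-9`).
#' @return A single non-negative number (possibly `Inf`), in nats.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # log(2)
#' @export
kl_divergence <- function(p, q, tol = 1e-9) {
  if (length(p) != length(q))
    stop("`p` and `q` must be over the same index set", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("`p` and `q` have mismatched names", call. = FALSE)
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("`p` and `q` must each sum to 1 within tolerance", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("negative probabilities", call. = FALSE)
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Joint distribution of an input distribution and a kernel
#'
#' \eqn{p(x, y) = \mu(x) \kappa(x; y)}; the input marginal of the result
#' recovers \eqn{\mu} exactly.
#'
#' @param mu an [as_input_dist()] object.
#' @param kappa a [as_markov_kernel()] on the full input set of the same
#'   system.
#' @return A `"joint_dist"`.
#' @export
joint_distribution <- function(mu, kappa) {
  stopifnot(inherits(mu, "input_dist"), inherits(kappa, "markov_kernel"))
  check_same_system(mu$system, kappa$system)
  if (!identical(kappa$inputs, kappa$system$input_names))
    stop("`kappa` must condition on the full input set", call. = FALSE)
  new_joint(mu$system, mu$p * kappa$prob)
}

check_same_system <- function(a, b) {
  if (!identical(a, b))
    stop("objects belong to different state systems", call. = FALSE)
  invisible(TRUE)
}

#' Exclusion dependence of a post-knockout kernel
#'
#' The input-averaged KL deviation of the post-knockout function from the
#' unperturbed function,
#' \deqn{D_\mu(\kappa \| \kappa_J) = \sum_x \mu(x) \sum_y \kappa(x; y)
#'   \ln \frac{\kappa(x; y)}{\kappa_J(x_J; y)},}
#' which is zero exactly when \eqn{\kappa_J(x_J; \cdot)} reproduces
#' \eqn{\kappa(x; \cdot)} on the whole support of \eqn{\mu}.
#'
#' @param mu an [as_input_dist()] object.
#' @param kappa the unperturbed kernel (full input set).
#' @param kappa_j a kernel on a subset `J` of the inputs.
#' @return Non-negative number in nats; `Inf` if `kappa_j` puts zero mass
#'   where `kappa` does not, on the support of `mu`.
#' @export
exclusion_dependence <- function(mu, kappa, kappa_j) {
  stopifnot(inherits(mu, "input_dist"), inherits(kappa, "markov_kernel"),
            inherits(kappa_j, "markov_kernel"))
  check_same_system(mu$system, kappa$system)
  check_same_system(mu$system, kappa_j$system)
  sys <- mu$system
  if (!identical(kappa$inputs, sys$input_names))
    stop("`kappa` must condition on the full input set", call. = FALSE)
  proj <- project_index(sys, sys$input_names, kappa_j$inputs)
  KJ <- kappa_j$prob[proj, , drop = FALSE]
  W <- mu$p * kappa$prob          # weights mu(x) kappa(x; y)
  pos <- W > 0
  if (any(pos & KJ == 0)) return(Inf)
  sum(W[pos] * log(kappa$prob[pos] / KJ[pos]))
}

#' Conditional mutual information I(Y; X_K | X_J) of a joint distribution
#'
#' Computed from the exact joint table as
#' \eqn{\sum_{x} p(x) \sum_y p(y|x) \ln\left(p(y|x)/p(y|x_J)\right)}.
#' `J` and `K` must be disjoint and together cover all input nodes. The
#' value is non-negative and vanishes exactly when \eqn{Y} is conditionally
#' independent of \eqn{X_K} given \eqn{X_J}.
#'
#' @param p a [as_joint_dist()] object.
#' @param K input node names whose influence is tested.
#' @param J conditioning node names; defaults to the complement of `K`.
#' @return Non-negative number in nats.
#' @export
conditional_mutual_information <- function(p, K, J = NULL) {
  stopifnot(inherits(p, "joint_dist"))
  sys <- p$system
  K <- canon_inputs(sys, K)
  J <- canon_inputs(sys, J %||% setdiff(sys$input_names, K))
  if (length(intersect(J, K)) > 0 ||
      !setequal(union(J, K), sys$input_names))
    stop("`J` and `K` must be disjoint and cover all input nodes", call. = FALSE)
  P <- p$prob
  px <- rowSums(P)
  proj <- project_index(sys, sys$input_names, J)
  PJ <- aggregate_rows(P, proj, n_configs(sys, J))
  pj <- rowSums(PJ)
  tot <- 0
  pos <- which(P > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(0)
  r <- pos[, 1]; cc <- pos[, 2]
  num <- P[pos] / px[r]                       # p(y | x)
  den <- PJ[cbind(proj[r], cc)] / pj[proj[r]] # p(y | x_J)
  sum(P[pos] * log(num / den))
}

# sum rows of `M` into `nout` groups given by `group` (1-based), keeping
# empty groups as zero rows
aggregate_rows <- function(M, group, nout) {
  out <- matrix(0, nout, ncol(M))
  agg <- rowsum(M, group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Optimal post-knockout kernel
#'
#' Among all kernels with inputs `J`, the one minimising the exclusion
#' dependence from `kappa` under `mu` is the conditional distribution
#' \eqn{\kappa^*_J(x_J; y) = p(y | x_J)} wherever \eqn{p(x_J) > 0}; its
#' deviation equals the conditional mutual information
#' \eqn{I(Y; X_K | X_J)}. Where \eqn{p(x_J) = 0} any row is optimal; this
#' implementation fills such rows uniformly.
#'
#' @param mu an [as_input_dist()] object.
#' @param kappa the unperturbed kernel (full input set).
#' @param J surviving input node names.
#' @return A `"markov_kernel"` on `J`.
#' @export
optimal_postknockout <- function(mu, kappa, J) {
  stopifnot(inherits(mu, "input_dist"), inherits(kappa, "markov_kernel"))
  check_same_system(mu$system, kappa$system)
  sys <- mu$system
  J <- canon_inputs(sys, J)
  p <- joint_distribution(mu, kappa)
  proj <- project_index(sys, sys$input_names, J)
  PJ <- aggregate_rows(p$prob, proj, n_configs(sys, J))
  pj <- rowSums(PJ)
  ny <- ncol(PJ)
  K <- PJ / ifelse(pj > 0, pj, 1)
  K[pj == 0, ] <- 1 / ny
  new_kernel(sys, J, K)
}

#' Test k-exclusion independence
#'
#' A pair \eqn{(\mu, \kappa)} is k-exclusion independent when
#' \eqn{Y \perp X_K \mid X_{I \setminus K}} holds for every knockout set
#' `K` of at most `k` nodes, i.e. every such conditional mutual information
#' is at most `tol`. This is exactly the condition under which every
#' knockout of at most `k` inputs can in principle be compensated.
#'
#' @param mu an [as_input_dist()] object.
#' @param kappa the unperturbed kernel (full input set).
#' @param k maximal knockout size, `0 <= k <= n`.
#' @param tol threshold on each conditional mutual information (nats).
#' @return An object of class `"exclusion_verdict"`: a list with
#'   `independent` (logical), `k`, `tol`, `table` (tibble of every tested
#'   knockout set with its CMI), and `worst` (the maximising set and value).
#' @export
k_exclusion_independent <- function(mu, kappa, k, tol = 1e-9) {
  stopifnot(inherits(mu, "input_dist"), inherits(kappa, "markov_kernel"))
  sys <- mu$system
  n <- length(sys$input_names)
  if (k < 0 || k > n) stop("`k` must be between 0 and n", call. = FALSE)
  p <- joint_distribution(mu, kappa)
  sets <- Filter(function(s) length(s) >= 1 && length(s) <= k,
                 all_subsets(sys$input_names))
  tab <- tibble::tibble(
    K = vapply(sets, set_key, character(1)),
    size = vapply(sets, length, integer(1)),
    cmi = vapply(sets, function(K) conditional_mutual_information(p, K),
                 numeric(1)))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$cmi))
  worst <- if (nrow(tab) > 0) tab[1, ] else
    tibble::tibble(K = "", size = 0L, cmi = 0)
  structure(list(independent = all(tab$cmi <= tol), k = k, tol = tol,
                 table = tab, worst = worst),
            class = "exclusion_verdict")
}

#' @export
print.exclusion_verdict <- function(x, ...) {
  cat("<exclusion_verdict> k =", x$k, "->",
      if (x$independent) "k-exclusion independent" else "NOT k-exclusion independent",
      sprintf("(tol %g)\n", x$tol))
  if (nrow(x$table) > 0)
    cat(sprintf("  worst knockout set {%s}: CMI = %.12g nats\n",
                x$worst$K, x$worst$cmi))
  invisible(x)
}

#' Test mutational neutrality of a kernel on its input support
#'
#' k-exclusion independence forces the kernel itself to be invariant under
#' mutations: any two support configurations that differ in at most `k`
#' coordinates must receive the same output distribution. This checks that
#' consequence directly on \eqn{\kappa}, without reference to any
#' post-knockout kernel.
#'
#' @inheritParams k_exclusion_independent
#' @param tol sup-norm tolerance on the difference of kernel rows.
#' @return An object of class `"neutrality_verdict"`: list with `neutral`
#'   (logical), `k`, `tol`, `max_diff`, and `witness` (first offending pair
#'   of configurations in canonical scan order, or `NULL`).
#' @export
mutation_neutrality <- function(mu, kappa, k, tol = 1e-9) {
  stopifnot(inherits(mu, "input_dist"), inherits(kappa, "markov_kernel"))
  check_same_system(mu$system, kappa$system)
  sys <- mu$system
  if (!identical(kappa$inputs, sys$input_names))
    stop("`kappa` must condition on the full input set", call. = FALSE)
  idx <- which(mu$p > 0)
  codes <- config_codes(sys)[idx, , drop = FALSE]
  Kmat <- kappa$prob[idx, , drop = FALSE]
  grid <- configurations(sys)[idx, , drop = FALSE]
  max_diff <- 0
  witness <- NULL
  m <- length(idx)
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      d <- rowSums(codes[(i + 1):m, , drop = FALSE] !=
                     matrix(codes[i, ], m - i, ncol(codes), byrow = TRUE))
      for (j in which(d >= 1 & d <= k)) {
        diff <- max(abs(Kmat[i, ] - Kmat[i + j, ]))
        if (diff > max_diff) max_diff <- diff
        if (diff > tol && is.null(witness))
          witness <- list(x = grid[i, , drop = FALSE],
                          x_prime = grid[i + j, , drop = FALSE],
                          sup_diff = diff)
      }
    }
  }
  structure(list(neutral = max_diff <= tol, k = k, tol = tol,
                 max_diff = max_diff, witness = witness),
            class = "neutrality_verdict")
}

#' @export
print.neutrality_verdict <- function(x, ...) {
  cat("<neutrality_verdict> k =", x$k, "->",
      if (x$neutral) "neutral on support" else "NOT neutral",
      sprintf("(max row difference %.3g, tol %g)\n", x$max_diff, x$tol))
  invisible(x)
}
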