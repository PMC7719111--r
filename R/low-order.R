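#' Exact coefficients of the low-order interaction representation
#'
#' For a system whose function must survive knockouts of up to `k` of its
#' `n` inputs, set \eqn{r = n - k}. The interaction terms of such a robust
#' family collapse onto the kernels of order at most `r` with coefficients
#' \deqn{\alpha_{A,J} = (-1)^{|A| - |J|} \quad (|J| < r), \qquad
#'   \alpha_{A,J} = \sum_{R \subseteq A \setminus J}
#'   \frac{(-1)^{|A| - |R| - r}}{\binom{|R| + r}{r}} \quad (|J| = r),}
#' which depend only on the cardinalities of `A` and `J`. The alternating
#' binomial sum is evaluated in exact rational arithmetic (collapsed over
#' the cardinality of `R` with binomial multiplicity), because it is badly
#' cancellation-prone in floating point.
#'
#' @param size_a,size_j cardinalities \eqn{|A| \ge |J|}.
#' @param r maximal interaction order, \eqn{r = n - k}; requires
#'   `size_j <= r`.
#' @return A [rational()] number; use `as.numeric()` for a double.
#' @examples
#' as.numeric(low_order_coefficient(3, 2, 2)) # -1 + 1/3
#' @export
low_order_coefficient <- function(size_a, size_j, r) {
  stopifnot(size_a >= 0, size_j >= 0, r >= 0)
  if (size_j > size_a) stop("|J| must not exceed |A|", call. = FALSE)
  if (size_j > r) stop("|J| must not exceed r", call. = FALSE)
  if (size_j < r) return(rational((-1)^(size_a - size_j)))
  # |J| = r: sum over s = |R|, R subsets of A \ J, with multiplicity C(|A|-r, s)
  acc <- rational(0)
  for (s in 0:(size_a - size_j)) {
    term <- rational((-1)^(size_a - s - r) * choose_exact(size_a - size_j, s),
                     choose_exact(s + r, r))
    acc <- rat_add(acc, term)
  }
  acc
}

#' Knockout-adjusted coefficients of an alternative interaction basis
#'
#' When the energy is expanded in alternative terms
#' \eqn{\psi_B} via \eqn{\phi_A = \sum_{B \subseteq A} \alpha_{A,B} \psi_B},
#' the post-knockout kernel with surviving set `J` carries \eqn{\psi_B} with
#' weight \deqn{\beta_{J,B} = \sum_{C \subseteq J \setminus B}
#' \alpha_{B \cup C, B}.} Removing weighted terms is thus not enough after a
#' basis change: the surviving coefficients shift with `J`.
#'
#' @param alpha a `function(A, B)` returning the coefficient
#'   \eqn{\alpha_{A,B}} for node-name vectors `A`, `B`.
#' @param J surviving node names.
#' @param B node names of the term, `B` a subset of `J`.
#' @return The numeric value of \eqn{\beta_{J,B}}.
#' @export
beta_coefficient <- function(alpha, J, B) {
  if (!all(B %in% J)) stop("`B` must be a subset of `J`", call. = FALSE)
  rest <- setdiff(J, B)
  sum(vapply(all_subsets(rest), function(C) alpha(union(B, C), B), numeric(1)))
}

#' @rdname beta_coefficient
#' @param size_j,size_b cardinalities of `J` and `B` for the
#'   cardinality-only low-order coefficients.
#' @param r maximal interaction order.
#' @return `low_order_beta()`: the exact [rational()] value of
#'   \eqn{\beta_{J,B}} under the [low_order_coefficient()] basis.
#' @export
low_order_beta <- function(size_j, size_b, r) {
  stopifnot(size_b <= size_j, size_b <= r)
  acc <- rational(0)
  for (cc in 0:(size_j - size_b)) {
    acc <- rat_add(acc, rat_mul(rational(choose_exact(size_j - size_b, cc)),
                                low_order_coefficient(size_b + cc, size_b, r)))
  }
  acc
}

#' Build a robust modality family from low-order generators
#'
#' Given arbitrary generator tables \eqn{\psi_J}, one per subset of order at
#' most \eqn{r = n - k}, this assembles interaction terms
#' \eqn{\phi_A = \sum_{J \subseteq A, |J| \le r} \alpha_{A,J} \psi_J} with
#' the exact [low_order_coefficient()] weights and derives all \eqn{2^n}
#' post-knockout kernels from them. Internally it verifies the collapsed
#' representation: each \eqn{\ln \kappa_J} equals, up to an input-only
#' function, \eqn{\sum_{B \subseteq J, |B| \le r} \beta_{J,B} \psi_B}; the
#' largest entrywise deviation is reported.
#'
#' @param system a [state_system()].
#' @param psi named list of generator tables keyed like interaction terms
#'   (comma-joined node names, `"{}"` for the empty set); each a numeric
#'   matrix over the subset's configurations by outputs, of order at most
#'   `r`. Absent subsets are zero.
#' @param k maximal knockout size; `r = n - k`.
#' @return An object of class `"low_order_family"`: list with `modalities`
#'   (a [functional_modalities()]), `interactions` (the assembled
#'   [interaction_family()]), `psi`, `r`, and `identity_max_error` (the
#'   internal verification residual).
#' @export
low_order_modalities <- function(system, psi, k) {
  stopifnot(inherits(system, "state_system"))
  n <- length(system$input_names)
  stopifnot(k >= 0, k <= n)
  r <- n - k
  ny <- length(system$output_alphabet)
  psi_terms <- interaction_family(system, psi)$terms  # validates shapes
  ord <- vapply(names(psi_terms), function(kk) length(key_set(kk)), integer(1))
  if (any(ord > r))
    stop("generator tables must have order at most r = n - k", call. = FALSE)
  terms <- list()
  for (A in all_subsets(system$input_names)) {
    M <- matrix(0, n_configs(system, A), ny)
    for (J in all_subsets(A)) {
      key <- set_key(J)
      if (length(J) > r || is.null(psi_terms[[key]])) next
      w <- as.numeric(low_order_coefficient(length(A), length(J), r))
      M <- M + w * psi_terms[[key]][project_index(system, A, J), , drop = FALSE]
    }
    terms[[set_key(A)]] <- M
  }
  phi <- interaction_family(system)
  phi$terms <- terms
  mod <- modalities_from_interactions(phi)
  # collapsed-representation identity, compared through the output gauge
  max_err <- 0
  for (J in all_subsets(system$input_names)) {
    lhs <- log(mod$kernels[[set_key(J)]]$prob)
    rhs <- matrix(0, nrow(lhs), ny)
    for (B in all_subsets(J)) {
      keyb <- set_key(B)
      if (length(B) > r || is.null(psi_terms[[keyb]])) next
      w <- as.numeric(low_order_beta(length(J), length(B), r))
      rhs <- rhs + w * psi_terms[[keyb]][project_index(system, J, B), , drop = FALSE]
    }
    max_err <- max(max_err, max(abs((lhs - rowMeans(lhs)) - (rhs - rowMeans(rhs)))))
  }
  structure(list(modalities = mod, interactions = phi, psi = psi_terms,
                 r = r, identity_max_error = max_err),
            class = "low_order_family")
}

#' @export
print.low_order_family <- function(x, ...) {
  cat("<low_order_family> r =", x$r, "generators:",
      paste(names(x$psi), collapse = "; "),
      sprintf("\n  collapsed-representation residual %.3g\n", x$identity_max_error))
  invisible(x)
}

#' Verify that a robust modality family has an order-limited representation
#'
#' For a complete, strictly positive family that is k-exclusion independent
#' on the support of `mu`, there exists an equivalent family whose
#' interactions have order at most \eqn{r = n - k}. This check (i) verifies
#' the precondition on the support, through the family equality
#' \eqn{\kappa_J(x_J; \cdot) = \kappa_B(x_B; \cdot)} for all
#' \eqn{B \subseteq J} with \eqn{|B| = r}; (ii) assembles an order-\eqn{\le r}
#' interaction family from the low-order kernels with the exact
#' [low_order_coefficient()] weights; and (iii) compares the rebuilt
#' modalities with the originals on every support configuration.
#'
#' @param modalities a complete, strictly positive
#'   [functional_modalities()].
#' @param mu an [as_input_dist()] giving the support on which robustness is
#'   claimed.
#' @param k maximal knockout size.
#' @param tol sup-norm tolerance for agreement of rebuilt modalities
#'   (default `1e-8`).
#' @param pre_tol tolerance for the precondition equality check (default
#'   `1e-8`).
#' @return An object of class `"low_order_report"`: list with `status`
#'   (`"ok"`, `"mismatch"`, or `"not_robust"` when the precondition fails),
#'   `r`, `max_discrepancy` (over rebuilt modalities on the support; `NA`
#'   if the precondition fails), `precondition_max` and `witness`.
#' @export
verify_low_order <- function(modalities, mu, k, tol = 1e-8, pre_tol = 1e-8) {
  stopifnot(inherits(modalities, "functional_modalities"),
            inherits(mu, "input_dist"))
  check_same_system(modalities$system, mu$system)
  sys <- modalities$system
  n <- length(sys$input_names)
  stopifnot(k >= 0, k <= n)
  r <- n - k
  if (!modality_complete(modalities))
    stop("the complete modality family is required", call. = FALSE)
  sup_idx <- which(mu$p > 0)
  # precondition: family-level k-exclusion independence on the support
  pre_max <- 0
  witness <- NULL
  for (J in all_subsets(sys$input_names)) {
    if (length(J) < r) next
    kJ <- modalities$kernels[[set_key(J)]]
    pJ <- project_index(sys, sys$input_names, J)
    for (B in all_subsets(J)) {
      if (length(B) != r) next
      kB <- modalities$kernels[[set_key(B)]]
      pB <- project_index(sys, sys$input_names, B)
      d <- abs(kJ$prob[pJ[sup_idx], , drop = FALSE] -
                 kB$prob[pB[sup_idx], , drop = FALSE])
      dm <- if (length(d) > 0) max(d) else 0
      if (dm > pre_max) {
        pre_max <- dm
        if (dm > pre_tol && is.null(witness))
          witness <- list(J = set_key(J), B = set_key(B), sup_diff = dm)
      }
    }
  }
  if (!is.null(witness))
    return(structure(list(status = "not_robust", r = r,
                          max_discrepancy = NA_real_,
                          precondition_max = pre_max, witness = witness),
                     class = "low_order_report"))
  # rebuild an order-<= r family from the low-order kernels only
  ny <- length(sys$output_alphabet)
  terms <- list()
  for (A in all_subsets(sys$input_names)) {
    M <- matrix(0, n_configs(sys, A), ny)
    for (J in all_subsets(A)) {
      if (length(J) > r) next
      w <- as.numeric(low_order_coefficient(length(A), length(J), r))
      M <- M + w * log(modalities$kernels[[set_key(J)]]$prob)[
        project_index(sys, A, J), , drop = FALSE]
    }
    terms[[set_key(A)]] <- M
  }
  phi <- interaction_family(sys)
  phi$terms <- terms
  rebuilt <- modalities_from_interactions(phi)
  max_disc <- 0
  for (J in all_subsets(sys$input_names)) {
    key <- set_key(J)
    pJ <- project_index(sys, sys$input_names, J)
    rows <- unique(pJ[sup_idx])
    d <- max(abs(rebuilt$kernels[[key]]$prob[rows, , drop = FALSE] -
                   modalities$kernels[[key]]$prob[rows, , drop = FALSE]))
    if (d > max_disc) max_disc <- d
  }
  structure(list(status = if (max_disc <= tol) "ok" else "mismatch",
                 r = r, max_discrepancy = max_disc,
                 precondition_max = pre_max, witness = NULL,
                 rebuilt = rebuilt, interactions = phi),
            class = "low_order_report")
}

#' @export
print.low_order_report <- function(x, ...) {
  cat("<low_order_report> r =", x$r, "status:", x$status, "\n")
  if (x$status == "not_robust") {
    cat(sprintf("  family not k-exclusion independent: kernels {%s} and {%s} differ by %.3g on support\n",
                x$witness$J, x$witness$B, x$witness$sup_diff))
  } else {
    cat(sprintf("  max discrepancy of rebuilt modalities on support: %.3g\n",
                x$max_discrepancy))
  }
  invisible(x)
}
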