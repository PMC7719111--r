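#' A single knockout experiment
#'
#' @param remaining surviving input node names `J`.
#' @param kernel the measured post-knockout kernel, a strictly positive
#'   `"markov_kernel"` on `remaining`.
#' @return An object of class `"knockout_experiment"`.
#' @export
knockout_experiment <- function(remaining, kernel) {
  stopifnot(inherits(kernel, "markov_kernel"))
  remaining <- canon_inputs(kernel$system, remaining)
  if (!identical(remaining, kernel$inputs))
    stop("`kernel` must condition exactly on `remaining`", call. = FALSE)
  if (any(kernel$prob <= 0))
    stop("measured kernels must be strictly positive", call. = FALSE)
  structure(list(remaining = remaining, kernel = kernel),
            class = "knockout_experiment")
}

#' A knockout protocol: experiments plus an interaction hypothesis
#'
#' @param experiments list of [knockout_experiment()] objects with distinct
#'   surviving sets.
#' @param hypothesis list of candidate interaction supports (each a vector
#'   of input node names; use `character(0)` for the output-bias term).
#' @return An object of class `"knockout_protocol"`.
#' @export
knockout_protocol <- function(experiments, hypothesis) {
  stopifnot(length(experiments) >= 0)
  if (length(experiments) > 0) {
    sys <- experiments[[1]]$kernel$system
    for (e in experiments) {
      stopifnot(inherits(e, "knockout_experiment"))
      check_same_system(sys, e$kernel$system)
    }
    keys <- vapply(experiments, function(e) set_key(e$remaining), character(1))
    if (anyDuplicated(keys))
      stop("experiments must have distinct surviving sets", call. = FALSE)
    hypothesis <- lapply(hypothesis, function(A) canon_inputs(sys, A))
  }
  structure(list(experiments = experiments, hypothesis = hypothesis),
            class = "knockout_protocol")
}

# design matrix of the log-linear identification system: one row per
# (experiment, configuration of its surviving set), one column per
# (hypothesis set, configuration of the set); entry 1 when the row's
# configuration restricts to the column's
protocol_design <- function(sys, remaining_sets, hypothesis) {
  col_blocks <- list()
  off <- 0L
  for (i in seq_along(hypothesis)) {
    A <- hypothesis[[i]]
    mA <- n_configs(sys, A)
    col_blocks[[i]] <- list(set = A, cols = off + seq_len(mA))
    off <- off + mA
  }
  nrow_tot <- sum(vapply(remaining_sets, function(J) n_configs(sys, J), numeric(1)))
  M <- matrix(0, nrow_tot, off)
  row_blocks <- list()
  roff <- 0L
  for (i in seq_along(remaining_sets)) {
    J <- remaining_sets[[i]]
    mJ <- n_configs(sys, J)
    rows <- roff + seq_len(mJ)
    row_blocks[[i]] <- list(set = J, rows = rows)
    for (b in col_blocks) {
      if (!all(b$set %in% J)) next
      pr <- project_index(sys, J, b$set)
      M[cbind(rows, b$cols[pr])] <- 1
    }
    roff <- roff + mJ
  }
  list(M = M, row_blocks = row_blocks, col_blocks = col_blocks)
}

#' Structural identifiability of interaction terms under a protocol
#'
#' Reports, for every hypothesis set, whether its (gauge-normalised,
#' output-dependent) interaction term is determined by the experiment
#' design: the set must be covered by at least one experiment's surviving
#' set, and the design matrix of the log-linear system must leave no null
#' direction through the set's coefficient block (rank test at `tol`).
#' No measured kernels are needed; only the surviving sets enter.
#'
#' @param hypothesis list of candidate interaction supports (node-name
#'   vectors).
#' @param experiments list of surviving sets (node-name vectors), or a list
#'   of [knockout_experiment()] objects.
#' @param system the [state_system()]; may be omitted when `experiments`
#'   are experiment objects.
#' @param tol rank-detection tolerance (default `1e-10`).
#' @return A tibble with one row per hypothesis set: `set`, `order`,
#'   `covered`, `identifiable`.
#' @export
design_report <- function(hypothesis, experiments, system = NULL, tol = 1e-10) {
  if (length(experiments) > 0 && inherits(experiments[[1]], "knockout_experiment")) {
    system <- system %||% experiments[[1]]$kernel$system
    experiments <- lapply(experiments, `[[`, "remaining")
  }
  stopifnot(inherits(system, "state_system"))
  hypothesis <- lapply(hypothesis, function(A) canon_inputs(system, A))
  experiments <- lapply(experiments, function(J) canon_inputs(system, J))
  covered <- vapply(hypothesis, function(A)
    any(vapply(experiments, function(J) all(A %in% J), logical(1))), logical(1))
  identifiable <- rep(FALSE, length(hypothesis))
  inc <- which(covered)
  if (length(inc) > 0 && length(experiments) > 0) {
    des <- protocol_design(system, experiments, hypothesis[inc])
    nullb <- null_basis(des$M, tol)
    for (i in seq_along(inc)) {
      cols <- des$col_blocks[[i]]$cols
      identifiable[inc[i]] <-
        is.null(nullb) || max(abs(nullb[cols, , drop = FALSE])) < 1e-8
    }
  }
  tibble::tibble(
    set = vapply(hypothesis, set_key, character(1)),
    order = vapply(hypothesis, length, integer(1)),
    covered = covered,
    identifiable = identifiable)
}

# orthonormal basis of the null space of M (columns), or NULL if trivial
null_basis <- function(M, tol = 1e-10) {
  sv <- svd(M, nu = 0)
  keep <- sv$d <= tol * max(sv$d, 1)
  if (!any(keep)) return(NULL)
  sv$v[, keep, drop = FALSE]
}

#' Identify interaction terms from a knockout protocol
#'
#' Solves, in the log domain and on the output-gauge quotient (every
#' quantity centred over outputs), the linear system
#' \deqn{\ln \kappa_J(x_J; y) \simeq \sum_{A \in H,\, A \subseteq J}
#'   \phi_A(x_A; y) + (\text{input-only offset})}
#' over the measured experiments by least squares, using the minimum-norm
#' solution of the shared design matrix (the system decouples over output
#' states). A hypothesis set is declared identifiable when the design
#' leaves no null direction through its coefficient block; identifiable
#' terms are recovered gauge-normalised and, in the exact (noise-free)
#' setting, uniquely. Structurally uncovered sets are reported, not raised.
#'
#' @param protocol a [knockout_protocol()].
#' @param tol rank-detection tolerance (default `1e-10`).
#' @param misfit_tol residual above which the report flags model misfit
#'   (default `1e-8`).
#' @return An object of class `"identification_result"`: list with
#'   `recovered` (an [interaction_family()] containing the identifiable
#'   terms, gauge-normalised), `verdicts` (tibble as in [design_report()]),
#'   `residual` (max absolute reconstruction error over all experiments)
#'   and `misfit` (logical).
#' @export
solve_protocol <- function(protocol, tol = 1e-10, misfit_tol = 1e-8) {
  stopifnot(inherits(protocol, "knockout_protocol"))
  if (length(protocol$experiments) == 0)
    stop("protocol contains no experiments", call. = FALSE)
  sys <- protocol$experiments[[1]]$kernel$system
  remaining <- lapply(protocol$experiments, `[[`, "remaining")
  verdicts <- design_report(protocol$hypothesis, remaining, sys, tol)
  inc <- which(verdicts$covered)
  hyp_inc <- protocol$hypothesis[inc]
  des <- protocol_design(sys, remaining, hyp_inc)
  # centred log-kernels, one column per output state
  ny <- length(sys$output_alphabet)
  G <- matrix(0, nrow(des$M), ny)
  for (i in seq_along(protocol$experiments)) {
    L <- log(protocol$experiments[[i]]$kernel$prob)
    G[des$row_blocks[[i]]$rows, ] <- L - rowMeans(L)
  }
  sv <- svd(des$M)
  pos <- sv$d > tol * max(sv$d, 1)
  # minimum-norm least-squares solution; zero-mean over outputs by linearity
  V <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) %*% G / sv$d[pos])
  residual <- if (nrow(des$M) > 0) max(abs(des$M %*% V - G)) else 0
  recovered <- interaction_family(sys)
  for (i in seq_along(inc)) {
    if (!verdicts$identifiable[inc[i]]) next
    blk <- des$col_blocks[[i]]
    recovered$terms[[set_key(blk$set)]] <- V[blk$cols, , drop = FALSE]
  }
  recovered <- gauge_normalize(recovered)
  structure(list(recovered = recovered, verdicts = verdicts,
                 residual = residual, misfit = residual > misfit_tol),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result>",
      sum(x$verdicts$identifiable), "of", nrow(x$verdicts),
      "hypothesis set(s) identifiable;",
      sprintf("residual %.3g%s\n", x$residual,
              if (x$misfit) " (MODEL MISFIT)" else ""))
  print(x$verdicts)
  invisible(x)
}

#' @export
tidy.identification_result <- function(x, ...) x$verdicts

#' @export
glance.identification_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$verdicts),
    n_identifiable = sum(x$verdicts$identifiable),
    residual = x$residual,
    misfit = x$misfit)
}

#' Full identification from the complete knockout lattice
#'
#' When every knockout can be performed, the log-linear system is solved
#' exactly by the subset-lattice Mobius inversion; the result is returned
#' gauge-normalised. Equivalent to [solve_protocol()] with the full lattice
#' of experiments and the full hypothesis.
#'
#' @param modalities a complete strictly positive
#'   [functional_modalities()].
#' @return A gauge-normalised [interaction_family()].
#' @export
full_identification <- function(modalities) {
  gauge_normalize(mobius_invert(modalities))
}
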