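#' Input distribution over joint configurations
#'
#' Builds an input distribution \eqn{\mu} on the joint configurations of a
#' state system from a (possibly sparse) table. Absent configurations get
#' mass zero. The total mass must be 1 within `tol`; masses are then
#' renormalised exactly.
#'
#' @param x a data frame with one column per input node plus a column `p`,
#'   or a numeric vector of length `n_configs(system)` in canonical order.
#' @param system a [state_system()].
#' @param tol normalisation tolerance on read (default `1e-9`).
#' @return An object of class `"input_dist"`.
#' @examples
#' sys <- state_system(list(x1 = c("0", "1")), c("0", "1"))
#' mu <- as_input_dist(data.frame(x1 = c("0", "1"), p = c(0.25, 0.75)), sys)
#' @export
as_input_dist <- function(x, system, tol = 1e-9) {
  stopifnot(inherits(system, "state_system"))
  m <- n_configs(system)
  if (is.numeric(x)) {
    if (length(x) != m) stop("numeric mass vector has wrong length", call. = FALSE)
    p <- as.numeric(x)
  } else {
    x <- as.data.frame(x)
    miss <- setdiff(c(system$input_names, "p"), names(x))
    if (length(miss) > 0)
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    idx <- config_index(system, x, system$input_names)
    if (anyDuplicated(idx)) stop("duplicated configurations in table", call. = FALSE)
    p <- rep(0, m)
    p[idx] <- as.numeric(x$p)
  }
  if (any(!is.finite(p)) || any(p < 0))
    stop("masses must be finite and non-negative", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop(sprintf("masses sum to %.12g, not 1 within tolerance %g", s, tol), call. = FALSE)
  structure(list(system = system, p = p / s), class = "input_dist")
}

#' @export
as_tibble.input_dist <- function(x, ...) {
  dplyr::mutate(configurations(x$system), p = x$p)
}

#' @export
print.input_dist <- function(x, ...) {
  cat("<input_dist> on", n_configs(x$system), "configurations,",
      sum(x$p > 0), "in support\n")
  print(dplyr::filter(as_tibble.input_dist(x), .data$p > 0), n = 10)
  invisible(x)
}

#' Support of an input distribution
#'
#' @param mu an [as_input_dist()] object.
#' @return Tibble of configurations with positive mass, in canonical order.
#' @export
support <- function(mu) {
  stopifnot(inherits(mu, "input_dist"))
  configurations(mu$system)[mu$p > 0, , drop = FALSE]
}

#' Markov kernel (conditional probability table)
#'
#' A Markov kernel \eqn{\kappa_J(x_J; y)} assigns each configuration of the
#' input nodes `inputs` a probability distribution over the output alphabet.
#' The unperturbed function uses all inputs; post-knockout kernels use the
#' surviving subset `J`. The table must be complete over \eqn{X_J \times Y};
#' each row must sum to 1 within `tol` and is then renormalised.
#'
#' @param x a data frame with one column per node in `inputs`, a column `y`
#'   and a column `p`; or a numeric matrix (`n_configs(system, inputs)` rows
#'   in canonical order, one column per output label).
#' @param system a [state_system()].
#' @param inputs the input node subset `J` the kernel conditions on. Defaults
#'   to all inputs for a matrix; inferred from the columns for a data frame.
#' @param tol row-normalisation tolerance (default `1e-9`).
#' @return An object of class `"markov_kernel"`.
#' @export
as_markov_kernel <- function(x, system, inputs = NULL, tol = 1e-9) {
  stopifnot(inherits(system, "state_system"))
  ny <- length(system$output_alphabet)
  if (is.matrix(x)) {
    inputs <- canon_inputs(system, inputs %||% system$input_names)
    m <- n_configs(system, inputs)
    if (nrow(x) != m || ncol(x) != ny)
      stop("kernel matrix has wrong dimensions", call. = FALSE)
    K <- unname(x)
  } else {
    x <- as.data.frame(x)
    if (is.null(inputs)) inputs <- setdiff(names(x), c("y", "p"))
    inputs <- canon_inputs(system, inputs)
    m <- n_configs(system, inputs)
    if (!all(c("y", "p") %in% names(x)))
      stop("kernel table needs columns `y` and `p`", call. = FALSE)
    if (nrow(x) != m * ny)
      stop("kernel table must be complete over X_J x Y", call. = FALSE)
    ri <- config_index(system, x, inputs)
    ci <- match(as.character(x$y), system$output_alphabet)
    if (anyNA(ci)) stop("unknown output label(s)", call. = FALSE)
    if (anyDuplicated(ri * (ny + 1L) + ci))
      stop("duplicated (configuration, output) rows", call. = FALSE)
    K <- matrix(NA_real_, m, ny)
    K[cbind(ri, ci)] <- as.numeric(x$p)
  }
  if (any(!is.finite(K)) || any(K < 0))
    stop("kernel entries must be finite and non-negative", call. = FALSE)
  rs <- rowSums(K)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("kernel row sums deviate from 1 by up to %.3g (tolerance %g)",
                 max(abs(rs - 1)), tol), call. = FALSE)
  structure(list(system = system, inputs = inputs, prob = K / rs),
            class = "markov_kernel")
}

# internal fast constructor (matrix already validated/normalised)
new_kernel <- function(system, inputs, prob) {
  structure(list(system = system, inputs = inputs, prob = prob),
            class = "markov_kernel")
}

#' Uniform Markov kernel
#'
#' @inheritParams as_markov_kernel
#' @return A kernel whose every row is uniform over the output alphabet.
#' @export
uniform_kernel <- function(system, inputs = system$input_names) {
  inputs <- canon_inputs(system, inputs)
  ny <- length(system$output_alphabet)
  new_kernel(system, inputs,
             matrix(1 / ny, n_configs(system, inputs), ny))
}

#' @export
as_tibble.markov_kernel <- function(x, ...) {
  grid <- configurations(x$system, x$inputs)
  ny <- length(x$system$output_alphabet)
  out <- grid[rep(seq_len(nrow(grid)), each = ny), , drop = FALSE]
  out$y <- rep(x$system$output_alphabet, times = nrow(grid))
  out$p <- as.vector(t(x$prob))
  tibble::as_tibble(out)
}

#' @export
print.markov_kernel <- function(x, ...) {
  cat("<markov_kernel> inputs {", paste(x$inputs, collapse = ", "), "} -> {",
      paste(x$system$output_alphabet, collapse = ", "), "}, ",
      nrow(x$prob), " rows\n", sep = "")
  print(as_tibble.markov_kernel(x), n = 8)
  invisible(x)
}

#' Joint input-output distribution
#'
#' @param x a data frame with input columns, `y` and `p` (complete or
#'   sparse), or a matrix (`n_configs(system)` rows, one column per output
#'   label).
#' @param system a [state_system()].
#' @param tol normalisation tolerance (default `1e-9`).
#' @return An object of class `"joint_dist"` with total mass exactly 1.
#' @export
as_joint_dist <- function(x, system, tol = 1e-9) {
  stopifnot(inherits(system, "state_system"))
  m <- n_configs(system)
  ny <- length(system$output_alphabet)
  if (is.matrix(x)) {
    if (nrow(x) != m || ncol(x) != ny)
      stop("joint matrix has wrong dimensions", call. = FALSE)
    P <- unname(x)
  } else {
    x <- as.data.frame(x)
    ri <- config_index(system, x, system$input_names)
    ci <- match(as.character(x$y), system$output_alphabet)
    if (anyNA(ci)) stop("unknown output label(s)", call. = FALSE)
    P <- matrix(0, m, ny)
    P[cbind(ri, ci)] <- as.numeric(x$p)
  }
  if (any(!is.finite(P)) || any(P < 0))
    stop("joint masses must be finite and non-negative", call. = FALSE)
  s <- sum(P)
  if (abs(s - 1) > tol)
    stop(sprintf("joint mass sums to %.12g, not 1 within tolerance %g", s, tol),
         call. = FALSE)
  structure(list(system = system, prob = P / s), class = "joint_dist")
}

new_joint <- function(system, prob) {
  structure(list(system = system, prob = prob), class = "joint_dist")
}

#' @export
as_tibble.joint_dist <- function(x, ...) {
  grid <- configurations(x$system)
  ny <- length(x$system$output_alphabet)
  out <- grid[rep(seq_len(nrow(grid)), each = ny), , drop = FALSE]
  out$y <- rep(x$system$output_alphabet, times = nrow(grid))
  out$p <- as.vector(t(x$prob))
  tibble::as_tibble(out)
}

#' @export
print.joint_dist <- function(x, ...) {
  cat("<joint_dist> on", n_configs(x$system), "x",
      length(x$system$output_alphabet), "input-output states\n")
  print(dplyr::filter(as_tibble.joint_dist(x), .data$p > 0), n = 10)
  invisible(x)
}

#' Input marginal of a joint distribution
#'
#' @param p a [as_joint_dist()] object.
#' @return An `"input_dist"` with \eqn{\mu(x) = \sum_y p(x, y)}.
#' @export
input_marginal <- function(p) {
  stopifnot(inherits(p, "joint_dist"))
  structure(list(system = p$system, p = rowSums(p$prob)), class = "input_dist")
}

#' Conditional kernel of a joint distribution
#'
#' Returns \eqn{p(y | x)} as a Markov kernel on the full input set. Rows with
#' zero input marginal are set per `off_support` ("uniform").
#'
#' @param p a [as_joint_dist()] object.
#' @param off_support rule for rows of zero marginal mass; only `"uniform"`.
#' @return A `"markov_kernel"`.
#' @export
conditional_kernel <- function(p, off_support = c("uniform")) {
  stopifnot(inherits(p, "joint_dist"))
  off_support <- match.arg(off_support)
  mu <- rowSums(p$prob)
  ny <- ncol(p$prob)
  K <- p$prob / ifelse(mu > 0, mu, 1)
  K[mu == 0, ] <- 1 / ny
  new_kernel(p$system, p$system$input_names, K)
}
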