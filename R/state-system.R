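#' Define a finite input-output state system
#'
#' A state system records the input nodes `I = {1, ..., n}`, one finite
#' alphabet per input node, and the finite output alphabet. All probability
#' tables in the package (input distributions, Markov kernels, joint
#' distributions, interaction terms) are defined relative to such a system.
#'
#' Joint configurations are enumerated lexicographically: the first input
#' name varies slowest, labels in the order given by each alphabet. That
#' enumeration is the canonical row order of every internal table.
#'
#' @param inputs named list; one character vector of state labels per input
#'   node. Names are the input node names, order is meaningful.
#' @param output character vector of output state labels.
#' @return An object of class `"state_system"`.
#' @examples
#' sys <- state_system(list(x1 = c("0", "1"), x2 = c("0", "1")), c("a", "b"))
#' configurations(sys)
#' @export
state_system <- function(inputs, output) {
  if (!is.list(inputs) || length(inputs) < 1)
    stop("`inputs` must be a non-empty named list of alphabets", call. = FALSE)
  if (is.null(names(inputs)) || anyDuplicated(names(inputs)) || any(names(inputs) == ""))
    stop("input nodes must have unique non-empty names", call. = FALSE)
  if (any(names(inputs) %in% c("y", "p", "{}")) || any(grepl(",", names(inputs), fixed = TRUE)))
    stop("input names must not be 'y', 'p' or '{}' and must not contain commas",
         call. = FALSE)
  inputs <- lapply(inputs, as.character)
  output <- as.character(output)
  for (nm in names(inputs)) {
    a <- inputs[[nm]]
    if (length(a) < 1 || anyDuplicated(a))
      stop("alphabet of `", nm, "` must be non-empty with unique labels", call. = FALSE)
  }
  if (length(output) < 1 || anyDuplicated(output))
    stop("output alphabet must be non-empty with unique labels", call. = FALSE)
  structure(
    list(input_names = names(inputs),
         input_alphabets = inputs,
         output_alphabet = output),
    class = "state_system")
}

#' @export
print.state_system <- function(x, ...) {
  cat("<state_system> ", length(x$input_names), " input node(s), ",
      n_configs(x), " joint configurations, |Y| = ",
      length(x$output_alphabet), "\n", sep = "")
  for (nm in x$input_names)
    cat("  ", nm, ": {", paste(x$input_alphabets[[nm]], collapse = ", "), "}\n", sep = "")
  cat("  output: {", paste(x$output_alphabet, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# validate and order a node subset by system order
canon_inputs <- function(sys, J) {
  J <- as.character(J)
  bad <- setdiff(J, sys$input_names)
  if (length(bad) > 0)
    stop("unknown input node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(J)) stop("duplicated input node names", call. = FALSE)
  sys$input_names[sys$input_names %in% J]
}

alphabet_sizes <- function(sys, inputs = sys$input_names) {
  vapply(sys$input_alphabets[inputs], length, integer(1))
}

#' Number of joint configurations over a set of input nodes
#'
#' @param sys a [state_system()].
#' @param inputs input node names (default: all).
#' @return Integer count, the product of the alphabet sizes.
#' @export
n_configs <- function(sys, inputs = sys$input_names) {
  prod(alphabet_sizes(sys, inputs))
}

# 0-based code matrix (m x p) of all configurations over `inputs`,
# canonical order: first column most significant
config_codes <- function(sys, inputs = sys$input_names) {
  p <- length(inputs)
  sizes <- alphabet_sizes(sys, inputs)
  m <- prod(sizes)
  if (p == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  codes <- matrix(0L, m, p, dimnames = list(NULL, inputs))
  inner <- rev(cumprod(rev(c(sizes[-1], 1))))
  for (j in seq_len(p)) {
    codes[, j] <- rep(rep(0:(sizes[j] - 1L), each = inner[j]),
                      length.out = m)
  }
  codes
}

#' Enumerate joint configurations of a state system
#'
#' @param sys a [state_system()].
#' @param inputs node names to enumerate over (default: all inputs).
#' @return A tibble with one label column per node, rows in canonical
#'   (lexicographic) order.
#' @export
configurations <- function(sys, inputs = sys$input_names) {
  inputs <- canon_inputs(sys, inputs)
  if (length(inputs) == 0)                      # the single empty configuration
    return(tibble::new_tibble(list(), nrow = 1L))
  codes <- config_codes(sys, inputs)
  cols <- lapply(inputs, function(nm) sys$input_alphabets[[nm]][codes[, nm] + 1L])
  names(cols) <- inputs
  tibble::as_tibble(cols, .name_repair = "minimal")
}

# canonical row index (1-based) of each configuration in `df` over `inputs`
config_index <- function(sys, df, inputs) {
  p <- length(inputs)
  if (p == 0) return(rep(1L, max(1L, nrow(df))))
  sizes <- alphabet_sizes(sys, inputs)
  idx <- rep(0, nrow(df))
  for (j in seq_len(p)) {
    nm <- inputs[j]
    code <- match(as.character(df[[nm]]), sys$input_alphabets[[nm]]) - 1L
    if (anyNA(code))
      stop("unknown label(s) for input `", nm, "`", call. = FALSE)
    idx <- idx * sizes[j] + code
  }
  as.integer(idx + 1)
}

# for each configuration over `from` (canonical order), the canonical index of
# its restriction to `to` (`to` a subset of `from`)
project_index <- function(sys, from, to) {
  from <- canon_inputs(sys, from)
  to <- canon_inputs(sys, to)
  if (!all(to %in% from)) stop("`to` must be a subset of `from`", call. = FALSE)
  codes <- config_codes(sys, from)
  m <- nrow(codes)
  if (length(to) == 0) return(rep(1L, m))
  sizes <- alphabet_sizes(sys, to)
  idx <- rep(0, m)
  for (j in seq_along(to)) idx <- idx * sizes[j] + codes[, to[j]]
  as.integer(idx + 1)
}
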