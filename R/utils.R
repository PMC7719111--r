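# Internal helpers: subset lattice keys, exact rationals, pinned RNG.

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical key for a node set: names joined by ",", empty set -> "{}"
# (empty-string list names are not retrievable by [[ in R)
set_key <- function(nms) {
  if (length(nms) == 0) "{}" else paste(nms, collapse = ",")
}

key_set <- function(key) {
  if (length(key) == 0 || key %in% c("", "{}")) character(0)
  else strsplit(key, ",", fixed = TRUE)[[1]]
}

# all subsets of `nms` in bitmask order (first element = least significant bit);
# guarded at 16 nodes (full-lattice operations are exponential)
all_subsets <- function(nms) {
  n <- length(nms)
  if (n > 16) stop("full subset lattice is limited to 16 input nodes", call. = FALSE)
  if (n == 0) return(list(character(0)))
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  lapply(0:(2^n - 1), function(b) nms[bitwAnd(b, bits) > 0L])
}

# evaluate `code` under a pinned, versioned RNG so generated fixtures are
# stable across platforms and sessions
seeded <- function(seed, code) {
  withr::with_seed(seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection")
}

## ---- exact rational arithmetic (integers held exactly in doubles) ----

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Exact rational number
#'
#' A minimal exact fraction used for the alternating binomial sums in the
#' low-order interaction coefficients, which are cancellation-prone in
#' floating point. Numerator and denominator are integers held exactly in
#' doubles (all magnitudes involved stay far below 2^53 for systems of at
#' most 16 nodes).
#'
#' @param num,den integer-valued numerator and denominator (`den != 0`).
#' @return An object of class `"rational"`.
#' @examples
#' as.numeric(rational(3, 6)) # 0.5
#' @export
rational <- function(num, den = 1) {
  stopifnot(length(num) == 1, length(den) == 1, den != 0,
            num == round(num), den == round(den))
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  structure(list(num = num, den = den), class = "rational")
}

rat_add <- function(a, b) rational(a$num * b$den + b$num * a$den, a$den * b$den)
rat_mul <- function(a, b) rational(a$num * b$num, a$den * b$den)

# as.numeric() dispatches S3 methods registered for as.double
#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  if (x$den == 1) sprintf("%.0f", x$num) else sprintf("%.0f/%.0f", x$num, x$den)
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# exact binomial coefficient (exact in double for the sizes used here)
choose_exact <- function(n, k) round(choose(n, k))
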