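#' Interaction (energy) decomposition of a stochastic map
#'
#' An interaction family stores real-valued terms \eqn{\phi_A(x_A; y)}, one
#' per input subset `A`, whose sum is the energy of the unperturbed kernel.
#' Knocking out a node set `K` discards every term whose support meets `K`,
#' which is the mechanistic model of knockouts used throughout.
#'
#' @param system a [state_system()].
#' @param terms named list of term tables keyed by the comma-joined node
#'   names of `A` in system order (`""` for the empty set). Each table is a
#'   numeric matrix with `n_configs(system, A)` rows (canonical order) and
#'   one column per output label, or an equivalent long data frame with
#'   columns for the nodes of `A`, `y` and `value`. Absent subsets are
#'   implicitly zero.
#' @return An object of class `"interaction_family"`.
#' @export
interaction_family <- function(system, terms = list()) {
  stopifnot(inherits(system, "state_system"))
  ny <- length(system$output_alphabet)
  out <- list()
  for (key in names(terms)) {
    A <- canon_inputs(system, key_set(key))
    ck <- set_key(A)
    tab <- terms[[key]]
    m <- n_configs(system, A)
    if (is.data.frame(tab)) {
      ri <- config_index(system, tab, A)
      ci <- match(as.character(tab$y), system$output_alphabet)
      if (anyNA(ci)) stop("unknown output label(s) in term ", ck, call. = FALSE)
      M <- matrix(0, m, ny)
      M[cbind(ri, ci)] <- as.numeric(tab$value)
      tab <- M
    }
    if (!is.matrix(tab) || nrow(tab) != m || ncol(tab) != ny)
      stop("term table for {", ck, "} has wrong dimensions", call. = FALSE)
    if (any(!is.finite(tab)))
      stop("term table for {", ck, "} has non-finite values", call. = FALSE)
    out[[ck]] <- unname(tab)
  }
  structure(list(system = system, terms = out), class = "interaction_family")
}

#' @export
print.interaction_family <- function(x, ...) {
  cat("<interaction_family>", length(x$terms), "stored term(s)\n")
  for (key in names(x$terms))
    cat(sprintf("  {%s}: order %d, output dependence %.4g\n", key,
                length(key_set(key)), output_dependence(x$terms[[key]])))
  invisible(x)
}

#' @export
tidy.interaction_family <- function(x, ...) {
  tibble::tibble(
    set = names(x$terms),
    order = vapply(names(x$terms), function(k) length(key_set(k)), integer(1)),
    output_dependence = vapply(x$terms, output_dependence, numeric(1)))
}

#' @export
glance.interaction_family <- function(x, ...) {
  dep <- vapply(x$terms, output_dependence, numeric(1))
  active <- dep > 1e-8
  tibble::tibble(
    n_terms = length(x$terms),
    n_active = sum(active),
    max_order = if (any(active))
      max(vapply(names(x$terms)[active], function(k) length(key_set(k)), integer(1)))
      else 0L)
}

#' Boltzmann-Gibbs kernel of an energy function
#'
#' \eqn{\kappa(x; y) = e^{Q(x; y)} / \sum_{y'} e^{Q(x; y')}}. Rows are
#' computed with a per-row maximum shift, so arbitrarily large energies are
#' safe. The result is strictly positive; adding any input-only function to
#' `Q` leaves it unchanged (gauge invariance).
#'
#' @param Q numeric energy matrix (`n_configs(system, inputs)` rows in
#'   canonical order, one column per output label).
#' @param system a [state_system()].
#' @param inputs input node subset the energy conditions on (default: all).
#' @return A strictly positive `"markov_kernel"`.
#' @export
kernel_from_energy <- function(Q, system, inputs = NULL) {
  stopifnot(inherits(system, "state_system"), is.matrix(Q))
  inputs <- canon_inputs(system, inputs %||% system$input_names)
  if (any(!is.finite(Q))) stop("energy has non-finite entries", call. = FALSE)
  if (nrow(Q) != n_configs(system, inputs) ||
      ncol(Q) != length(system$output_alphabet))
    stop("energy matrix has wrong dimensions", call. = FALSE)
  E <- exp(Q - apply(Q, 1, max))
  new_kernel(system, inputs, E / rowSums(E))
}

# energy of a modality: sum of all stored terms contained in J, lifted to X_J
energy_on <- function(phi, J) {
  sys <- phi$system
  Q <- matrix(0, n_configs(sys, J), length(sys$output_alphabet))
  for (key in names(phi$terms)) {
    A <- key_set(key)
    if (all(A %in% J))
      Q <- Q + phi$terms[[key]][project_index(sys, J, A), , drop = FALSE]
  }
  Q
}

#' Complete family of post-knockout kernels (functional modalities)
#'
#' @param system a [state_system()].
#' @param kernels named list of `"markov_kernel"` objects keyed by the
#'   comma-joined surviving node names in system order (`""` for the
#'   all-knocked-out kernel). The full-input kernel is the unperturbed
#'   function.
#' @return An object of class `"functional_modalities"`.
#' @export
functional_modalities <- function(system, kernels) {
  stopifnot(inherits(system, "state_system"))
  out <- list()
  for (key in names(kernels)) {
    kk <- kernels[[key]]
    stopifnot(inherits(kk, "markov_kernel"))
    check_same_system(system, kk$system)
    ck <- set_key(canon_inputs(system, key_set(key)))
    if (!identical(sort(kk$inputs), sort(key_set(ck))))
      stop("kernel stored under {", key, "} conditions on different inputs",
           call. = FALSE)
    out[[ck]] <- kk
  }
  structure(list(system = system, kernels = out),
            class = "functional_modalities")
}

#' @export
print.functional_modalities <- function(x, ...) {
  n <- length(x$system$input_names)
  cat("<functional_modalities>", length(x$kernels), "of", 2^n,
      "post-knockout kernels stored\n")
  invisible(x)
}

modality_complete <- function(mod) {
  keys <- vapply(all_subsets(mod$system$input_names), set_key, character(1))
  all(keys %in% names(mod$kernels))
}

#' All post-knockout kernels of an interaction family
#'
#' For every surviving subset `J` the post-knockout kernel is the
#' Boltzmann-Gibbs normalisation of the surviving energy
#' \eqn{\sum_{A \subseteq J} \phi_A(x_A; y)}: knocked-out nodes take all
#' their interaction terms with them.
#'
#' @param phi an [interaction_family()].
#' @return A `"functional_modalities"` object with all \eqn{2^n} kernels,
#'   each strictly positive.
#' @export
modalities_from_interactions <- function(phi) {
  stopifnot(inherits(phi, "interaction_family"))
  sys <- phi$system
  kernels <- list()
  for (J in all_subsets(sys$input_names)) {
    kernels[[set_key(J)]] <- kernel_from_energy(energy_on(phi, J), sys, J)
  }
  functional_modalities(sys, kernels)
}

#' Post-knockout kernel after removing a node set
#'
#' Convenience accessor: the modality that survives knocking out `remove`,
#' computed from an interaction family (term removal plus renormalisation)
#' or looked up in a stored modality family.
#'
#' @param x an [interaction_family()] or [functional_modalities()].
#' @param remove node names to knock out.
#' @return A `"markov_kernel"` on the surviving inputs.
#' @export
knockout <- function(x, remove) {
  sys <- x$system
  remove <- canon_inputs(sys, remove)
  J <- setdiff(sys$input_names, remove)
  if (inherits(x, "interaction_family"))
    return(kernel_from_energy(energy_on(x, J), sys, J))
  if (inherits(x, "functional_modalities")) {
    key <- set_key(J)
    if (!(key %in% names(x$kernels)))
      stop("modality for surviving set {", key, "} is not stored", call. = FALSE)
    return(x$kernels[[key]])
  }
  stop("`x` must be an interaction family or functional modalities", call. = FALSE)
}

#' Recover interaction terms from a complete modality family
#'
#' The subset-lattice Mobius inversion
#' \deqn{\phi_A(x_A; y) = \sum_{J \subseteq A} (-1)^{|A \setminus J|}
#'   \ln \kappa_J(x_J; y)}
#' recovers an interaction representation of any complete, strictly
#' positive family of post-knockout kernels;
#' [modalities_from_interactions()] of the result reproduces the family.
#'
#' @param modalities a complete [functional_modalities()]; every kernel
#'   entry must exceed `floor`.
#' @param floor strict-positivity floor for the logarithms (default
#'   `1e-12`); entries at or below it are an error, never clamped.
#' @return An [interaction_family()] with all \eqn{2^n} terms.
#' @export
mobius_invert <- function(modalities, floor = 1e-12) {
  stopifnot(inherits(modalities, "functional_modalities"))
  sys <- modalities$system
  if (!modality_complete(modalities))
    stop("Mobius inversion needs the complete family over all subsets", call. = FALSE)
  logs <- lapply(modalities$kernels, function(kk) {
    if (any(kk$prob <= floor))
      stop("modality entries must be strictly positive (> ", floor, ")",
           call. = FALSE)
    log(kk$prob)
  })
  terms <- list()
  for (A in all_subsets(sys$input_names)) {
    M <- matrix(0, n_configs(sys, A), length(sys$output_alphabet))
    for (J in all_subsets(A)) {
      sgn <- (-1)^(length(A) - length(J))
      M <- M + sgn * logs[[set_key(J)]][project_index(sys, A, J), , drop = FALSE]
    }
    terms[[set_key(A)]] <- M
  }
  fam <- interaction_family(sys)
  fam$terms <- terms
  fam
}

#' Gauge-normalise an interaction family
#'
#' Interaction representations are unique only up to adding input-only
#' functions to each term; all modalities are unchanged by such additions.
#' This picks the canonical representative with
#' \eqn{\sum_y \phi_A(x_A; y) = 0} for every `A` and \eqn{x_A} (zero mean
#' over the output). The projection is linear and idempotent.
#'
#' @param phi an [interaction_family()].
#' @return The gauge-fixed [interaction_family()].
#' @export
gauge_normalize <- function(phi) {
  stopifnot(inherits(phi, "interaction_family"))
  phi$terms <- lapply(phi$terms, function(M) M - rowMeans(M))
  phi
}

#' Output dependence of an interaction term
#'
#' The largest spread over outputs, \eqn{\max_{x_A} (\max_y - \min_y)} of
#' the term values: zero exactly when the term is an input-only function
#' (pure gauge), so this counts as "contributing" only terms that actually
#' shape the output distribution.
#'
#' @param x a term table (numeric matrix, rows = configurations of `A`,
#'   columns = outputs).
#' @return A non-negative number.
#' @export
output_dependence <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) == 0) return(0)
  max(apply(x, 1, max) - apply(x, 1, min))
}

#' Smooth a kernel towards uniform
#'
#' Convex mixture \eqn{(1 - \epsilon) \kappa + \epsilon\, u} with the
#' uniform kernel: the standard way to approximate a deterministic or
#' boundary kernel by a strictly positive one so that logarithm-based
#' machinery (Mobius inversion, identification) applies.
#'
#' @param kappa a `"markov_kernel"`.
#' @param eps mixing weight on the uniform kernel, in (0, 1).
#' @return A strictly positive `"markov_kernel"`.
#' @export
smooth_kernel <- function(kappa, eps) {
  stopifnot(inherits(kappa, "markov_kernel"), eps > 0, eps < 1)
  ny <- ncol(kappa$prob)
  new_kernel(kappa$system, kappa$inputs,
             (1 - eps) * kappa$prob + eps / ny)
}
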