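# Plain-text interfaces: UTF-8 tab-separated probability tables ('#' lines
# are comments) and JSON for structured objects.

read_tsv_table <- function(file) {
  readr::read_tsv(file, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read and write state systems as JSON
#'
#' Schema: `{"inputs": {name: [labels], ...}, "output": [labels]}`.
#'
#' @param file path to a JSON file.
#' @return `read_state_system()`: a [state_system()].
#' @export
read_state_system <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyMatrix = FALSE)
  state_system(as.list(j$inputs), j$output)
}

#' @rdname read_state_system
#' @param sys a [state_system()].
#' @export
write_state_system <- function(sys, file) {
  jsonlite::write_json(list(inputs = sys$input_alphabets,
                            output = sys$output_alphabet),
                       file, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(file)
}

# infer a state system from observed labels of a complete table; only used
# when no explicit system is given
infer_system <- function(tab, input_cols, ycol = NULL) {
  inputs <- lapply(input_cols, function(nm) sort(unique(as.character(tab[[nm]]))))
  names(inputs) <- input_cols
  output <- if (!is.null(ycol)) sort(unique(as.character(tab[[ycol]])))
            else c("0", "1")
  state_system(inputs, output)
}

#' Read and write input distributions as TSV
#'
#' One column per input node plus a final column `p`; sparse tables are
#' allowed (absent rows have mass zero). Lines starting with `#` are
#' ignored.
#'
#' @param file path to a tab-separated file.
#' @param system a [state_system()]; when `NULL` the alphabets are inferred
#'   from the observed labels (sorted), which is only safe for tables whose
#'   support touches every label.
#' @return `read_input_dist()`: an `"input_dist"`.
#' @export
read_input_dist <- function(file, system = NULL) {
  tab <- read_tsv_table(file)
  input_cols <- setdiff(names(tab), "p")
  if (is.null(system)) system <- infer_system(tab, input_cols)
  tab$p <- as.numeric(tab$p)
  as_input_dist(tab, system)
}

#' @rdname read_input_dist
#' @param mu an `"input_dist"`.
#' @param sparse write only positive-mass rows (default `TRUE`).
#' @export
write_input_dist <- function(mu, file, sparse = TRUE) {
  tab <- as_tibble(mu)
  if (sparse) tab <- dplyr::filter(tab, .data$p > 0)
  readr::write_tsv(tab, file)
  invisible(file)
}

#' Read and write Markov kernels as TSV
#'
#' One column per conditioning input node, a column `y` and a column `p`;
#' the table must be complete over the configurations of the inputs times
#' the output alphabet.
#'
#' @inheritParams read_input_dist
#' @param inputs conditioning subset; inferred from the columns by default.
#' @return `read_kernel()`: a `"markov_kernel"`.
#' @export
read_kernel <- function(file, system = NULL, inputs = NULL) {
  tab <- read_tsv_table(file)
  input_cols <- inputs %||% setdiff(names(tab), c("y", "p"))
  if (is.null(system)) system <- infer_system(tab, input_cols, "y")
  tab$p <- as.numeric(tab$p)
  as_markov_kernel(tab, system, inputs = input_cols)
}

#' @rdname read_kernel
#' @param kappa a `"markov_kernel"`.
#' @export
write_kernel <- function(kappa, file) {
  readr::write_tsv(as_tibble(kappa), file)
  invisible(file)
}

#' Read and write interaction families as JSON
#'
#' Schema: `{"terms": [{"set": [names], "values": [{"x": {name: label},
#' "y": label, "value": v}, ...]}, ...]}`; absent terms are zero.
#'
#' @param file path to a JSON file.
#' @param system a [state_system()]; required on read.
#' @return `read_interactions()`: an [interaction_family()].
#' @export
read_interactions <- function(file, system) {
  j <- jsonlite::read_json(file, simplifyVector = FALSE)
  terms <- list()
  for (tm in j$terms) {
    A <- canon_inputs(system, unlist(tm$set))
    rows <- lapply(tm$values, function(v) {
      c(as.list(v$x), list(y = v$y, value = v$value))
    })
    tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    terms[[set_key(A)]] <- as.data.frame(tab)
  }
  interaction_family(system, terms)
}

#' @rdname read_interactions
#' @param phi an [interaction_family()].
#' @export
write_interactions <- function(phi, file) {
  sys <- phi$system
  out <- lapply(names(phi$terms), function(key) {
    A <- key_set(key)
    grid <- configurations(sys, A)
    M <- phi$terms[[key]]
    vals <- list()
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
      vals[[length(vals) + 1]] <- list(
        x = as.list(grid[i, , drop = FALSE]),
        y = sys$output_alphabet[j],
        value = M[i, j])
    }
    list(set = as.list(A), values = vals)
  })
  jsonlite::write_json(list(terms = out), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read and write modality families as JSON
#'
#' Schema: an object mapping each comma-joined surviving subset (in system
#' order; `"{}"` for the empty set) to a list of kernel rows
#' `{<input>: label, ..., "y": label, "p": value}`.
#'
#' @param file path to a JSON file.
#' @param system a [state_system()]; required on read.
#' @return `read_modalities()`: a [functional_modalities()].
#' @export
read_modalities <- function(file, system) {
  j <- jsonlite::read_json(file, simplifyVector = FALSE)
  kernels <- list()
  for (key in names(j)) {
    J <- canon_inputs(system, key_set(key))
    tab <- dplyr::bind_rows(lapply(j[[key]], tibble::as_tibble))
    tab$p <- as.numeric(tab$p)
    kernels[[set_key(J)]] <- as_markov_kernel(as.data.frame(tab), system,
                                              inputs = J)
  }
  functional_modalities(system, kernels)
}

#' @rdname read_modalities
#' @param modalities a [functional_modalities()].
#' @export
write_modalities <- function(modalities, file) {
  out <- lapply(modalities$kernels, function(kk) {
    tab <- as_tibble(kk)
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, , drop = FALSE]))
  })
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read and write knockout protocols as JSON
#'
#' Schema: `{"experiments": [{"remaining": [names], "kernel": [rows]}],
#' "hypothesis": [[names], ...]}`, kernel rows as in [write_modalities()].
#'
#' @param file path to a JSON file.
#' @param system a [state_system()]; required on read.
#' @return `read_protocol()`: a [knockout_protocol()].
#' @export
read_protocol <- function(file, system) {
  j <- jsonlite::read_json(file, simplifyVector = FALSE)
  experiments <- lapply(j$experiments, function(e) {
    J <- canon_inputs(system, unlist(e$remaining))
    tab <- dplyr::bind_rows(lapply(e$kernel, tibble::as_tibble))
    tab$p <- as.numeric(tab$p)
    knockout_experiment(J, as_markov_kernel(as.data.frame(tab), system,
                                            inputs = J))
  })
  hypothesis <- lapply(j$hypothesis, unlist)
  knockout_protocol(experiments, hypothesis)
}

#' @rdname read_protocol
#' @param protocol a [knockout_protocol()].
#' @export
write_protocol <- function(protocol, file) {
  out <- list(
    experiments = lapply(protocol$experiments, function(e) {
      tab <- as_tibble(e$kernel)
      list(remaining = as.list(e$remaining),
           kernel = lapply(seq_len(nrow(tab)), function(i)
             as.list(tab[i, , drop = FALSE])))
    }),
    hypothesis = lapply(protocol$hypothesis, as.list))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a component report as JSON
#'
#' One entry per connected component: its name, member configurations and
#' (when an input distribution is supplied) the mass of each member.
#'
#' @param partition a [hamming_components()] result.
#' @param file path to write.
#' @param mu optional `"input_dist"` supplying masses.
#' @export
write_components <- function(partition, file, mu = NULL) {
  sys <- partition$system
  sup_idx <- config_index(sys, partition$support, sys$input_names)
  out <- lapply(names(partition$components), function(nm) {
    ix <- partition$components[[nm]]
    members <- lapply(ix, function(i)
      as.list(partition$support[i, , drop = FALSE]))
    ent <- list(component = nm, size = length(ix), members = members)
    if (!is.null(mu)) ent$mass <- mu$p[sup_idx[ix]]
    ent
  })
  jsonlite::write_json(list(k = partition$k, components = out), file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a neutral mixture as JSON
#'
#' Schema: `{"k": k, "alpha": {component: weight}, "mu_n": {component:
#' [{<input>: label, ..., "p": mass}]}, "lambda_n": {component: {label:
#' mass}}}`.
#'
#' @param mixture a [neutral_mixture()].
#' @param file path to write.
#' @export
write_mixture <- function(mixture, file) {
  part <- mixture$partition
  mu_n <- lapply(names(part$components), function(nm) {
    ix <- part$components[[nm]]
    lapply(seq_along(ix), function(i)
      c(as.list(part$support[ix[i], , drop = FALSE]),
        list(p = mixture$mu_n[[nm]][i])))
  })
  names(mu_n) <- names(part$components)
  lambda_n <- lapply(mixture$lambda_n, function(l)
    as.list(stats::setNames(as.numeric(l), part$system$output_alphabet)))
  jsonlite::write_json(list(k = part$k,
                            alpha = as.list(mixture$alpha),
                            mu_n = mu_n, lambda_n = lambda_n),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
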