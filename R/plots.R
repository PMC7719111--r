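# ggplot2 views of the main result types.

#' Plot the connected components of an input support
#'
#' For two-input systems, tiles the support on the plane of the two input
#' alphabets, coloured by connected component — the classic neutral-network
#' picture. Systems with more inputs are projected onto the first two
#' nodes (tiles then overlap and the projection is labelled as such).
#'
#' @param object a [hamming_components()] partition.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.component_partition <- function(object, ...) {
  sys <- object$system
  dat <- tidy(object)
  n1 <- sys$input_names[1]
  n2 <- if (length(sys$input_names) >= 2) sys$input_names[2] else n1
  dat[[n1]] <- factor(dat[[n1]], levels = sys$input_alphabets[[n1]])
  dat[[n2]] <- factor(dat[[n2]], levels = sys$input_alphabets[[n2]])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[n1]], y = .data[[n2]],
                                    fill = .data$component)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Support components at k = %d (%d component%s)",
                      object$k, length(object$components),
                      if (length(object$components) == 1) "" else "s"),
      subtitle = if (length(sys$input_names) > 2)
        "projection onto the first two inputs" else NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Markov kernel as a heat map
#'
#' Rows are input configurations (canonical order), columns output states,
#' fill the conditional probability.
#'
#' @param object a `"markov_kernel"`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.markov_kernel <- function(object, ...) {
  tab <- as_tibble(object)
  cfg <- apply(as.data.frame(tab[object$inputs]), 1, paste, collapse = ",")
  tab$configuration <- factor(cfg, levels = unique(cfg))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$y, y = .data$configuration,
                                    fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "output", fill = "probability",
                  y = paste0("(", paste(object$inputs, collapse = ", "), ")")) +
    ggplot2::theme_minimal()
}

#' Plot the output dependence of an interaction family
#'
#' Bar chart of [output_dependence()] per stored term, ordered by
#' interaction order: terms at zero are pure gauge (input-only) and do not
#' shape the output.
#'
#' @param object an [interaction_family()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.interaction_family <- function(object, ...) {
  dat <- tidy(object)
  dat$set <- factor(dat$set, levels = dat$set[order(dat$order, dat$set)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set,
                                    y = .data$output_dependence,
                                    fill = factor(.data$order))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "interaction support", y = "output dependence",
                  fill = "order") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
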