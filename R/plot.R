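#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

substitution_of <- function(class) {
  stringr::str_match(class, "\\[([CT]>[ACGT])\\]")[, 2]
}

#' Plot signature profiles as per-class bar charts
#'
#' One facet per signature; for SBS schemas bars are coloured by
#' substitution type in the conventional six-colour scheme.
#'
#' @param object a `signature_set`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot signature_set
#' @export
autoplot.signature_set <- function(object, ...) {
  df <- tidy(object)
  df$class <- factor(df$class, levels = rownames(object$W))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$weight))
  sub <- substitution_of(as.character(df$class))
  if (!anyNA(sub)) {
    df$substitution <- sub
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$weight,
                                          fill = .data$substitution)) +
      ggplot2::scale_fill_manual(values = c(
        "C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
        "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC5C4"))
  }
  p + ggplot2::geom_col() +
    ggplot2::facet_wrap(~signature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot per-sample spectra of a catalogue
#' @param object a `mutation_catalogue`.
#' @param samples samples to show (default: first 4).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mutation_catalogue
#' @export
autoplot.mutation_catalogue <- function(object,
                                        samples = utils::head(object$samples,
                                                              4L), ...) {
  df <- dplyr::filter(tidy(object), .data$sample_id %in% samples)
  df$class <- factor(df$class, levels = object$classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot the rank-selection diagnostics of an extraction
#'
#' Stability (mean silhouette) and reconstruction error against the
#' candidate rank; the advisory selected rank is highlighted.
#'
#' @param object a `signature_extraction`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot signature_extraction
#' @export
autoplot.signature_extraction <- function(object, ...) {
  df <- glance(object) |>
    dplyr::mutate(kl_scaled = .data$kl_error / max(.data$kl_error)) |>
    tidyr::pivot_longer(c("stability", "kl_scaled"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = object$k_range) +
    ggplot2::labs(x = "rank k", y = NULL,
                  title = "signature extraction model selection") +
    ggplot2::theme_minimal()
}

#' Plot exposures as stacked per-sample bars
#' @param object a `signature_attribution`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot signature_attribution
#' @export
autoplot.signature_attribution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$exposure,
                                   fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "attributed mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
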