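#' Plot observed vs fitted MIDs of an ISA fit
#'
#' @param object An `isa_fit` from [fit_isa()].
#' @param observed Optional observed MID vector/matrix to overlay (the fit
#'   does not retain its input).
#' @param ... Unused.
#' @return A ggplot of the fitted (and observed) mass-isotopomer
#'   distribution.
#' @export
autoplot.isa_fit <- function(object, observed = NULL, ...) {
  d <- tibble::tibble(shift = seq_along(object$fitted) - 1L,
                      abundance = object$fitted, what = "fitted")
  if (!is.null(observed)) {
    if (is.null(dim(observed))) observed <- matrix(observed, ncol = 1)
    od <- purrr::map_dfr(seq_len(ncol(observed)), function(j) {
      tibble::tibble(shift = seq_len(nrow(observed)) - 1L,
                     abundance = normalize_mid(observed[, j]),
                     what = "observed")
    })
    d <- dplyr::bind_rows(d, od)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$shift, .data$abundance,
                                  fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mass shift", y = "fractional abundance", fill = NULL,
                  subtitle = sprintf("D = %.3f, g = %.3f", object$D,
                                     object$g)) +
    ggplot2::theme_minimal()
}

#' Bar plot of a tidy MID table
#'
#' @param tbl MID tibble (columns `metabolite`, `shift`, `abundance`,
#'   optionally `sample`); replicates are averaged.
#' @param metabolites Optional subset of metabolites to show.
#' @return A ggplot faceted by metabolite.
#' @export
plot_mid_table <- function(tbl, metabolites = NULL) {
  if (!is.null(metabolites)) {
    tbl <- dplyr::filter(tbl, .data$metabolite %in% metabolites)
  }
  d <- tbl |>
    dplyr::summarise(abundance = mean(.data$abundance),
                     .by = c("metabolite", "shift"))
  ggplot2::ggplot(d, ggplot2::aes(.data$shift, .data$abundance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metabolite, scales = "free_x") +
    ggplot2::labs(x = "mass shift", y = "fractional abundance") +
    ggplot2::theme_minimal()
}
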