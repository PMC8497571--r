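#' Plot a metagene profile with an optional null band
#'
#' Column-mean profiles of one or more metagene matrices (or gene subsets
#' of one matrix), with the resampling null band drawn as a grey ribbon.
#'
#' @param profiles named list of numeric profile vectors (e.g. column means
#'   of a metagene matrix per DE class), all the same length.
#' @param band optional [resample_null_band()] result.
#' @param xlab,ylab axis labels.
#' @return A ggplot object.
#' @export
plot_metagene <- function(profiles, band = NULL, xlab = "bin",
                          ylab = "mean signal") {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  df <- do.call(rbind, lapply(names(profiles), function(nm)
    data.frame(set = nm, bin = seq_along(profiles[[nm]]),
               signal = profiles[[nm]])))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$signal,
                                        colour = .data$set))
  if (!is.null(band)) {
    bd <- data.frame(bin = seq_along(band$lower), lower = band$lower,
                     upper = band$upper)
    p <- p + ggplot2::geom_ribbon(
      data = bd, ggplot2::aes(x = .data$bin, ymin = .data$lower,
                              ymax = .data$upper),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.8)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ylab, colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot expression ECDF curves
#'
#' @param ecdfs result of [expression_ecdf()].
#' @return A ggplot object.
#' @export
plot_expression_ecdf <- function(ecdfs) {
  df <- do.call(rbind, lapply(names(ecdfs$curves), function(nm)
    cbind(set = nm, ecdfs$curves[[nm]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_count, y = .data$cum_freq,
                                   colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log10(count + 1)", y = "cumulative relative frequency",
                  colour = NULL) +
    ggplot2::theme_classic()
}
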