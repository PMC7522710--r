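#' Bar plot of a size spectrum
#'
#' A view over [size_spectrum()] output: counts are plotted exactly as
#' tabulated, never recomputed. Negative-strand counts are drawn downwards,
#' matching the usual strand-resolved small-RNA profile figure.
#'
#' @param spectrum output of [size_spectrum()].
#' @return a ggplot object.
#' @export
plot_size_spectrum <- function(spectrum) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- spectrum
  df$signed <- ifelse(df$strand == "+", df$count, -df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = length, y = signed, fill = strand)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "read length (nt)", y = "weighted count",
                  fill = "strand") +
    ggplot2::theme_minimal()
}

#' Bar plot of an overlap spectrum (z-scores by overlap distance)
#'
#' @param spectrum output of [overlap_spectrum()].
#' @return a ggplot object.
#' @export
plot_overlap_spectrum <- function(spectrum) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- as.data.frame(spectrum)
  ggplot2::ggplot(df, ggplot2::aes(x = d, y = z)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "5' overlap (nt)", y = "z-score") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("length", "signed", "strand", "d", "z"))
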