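# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_line geom_point
#'   geom_col labs theme_minimal facet_wrap
NULL

#' Plot a centroid spectrum
#'
#' @param object A `maldi_spectrum`.
#' @param ... Unused.
#' @return A ggplot object (peaks as vertical segments).
#' @exportS3Method ggplot2::autoplot
autoplot.maldi_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$mz, xend = .data$mz,
                     y = 0, yend = .data$intensity)) +
    geom_segment() +
    labs(x = "m/z", y = "intensity") +
    theme_minimal()
}

#' Plot a digestion time course
#'
#' @param timecourse Output of [simulate_timecourse()].
#' @return A ggplot object, one line per species.
#' @export
plot_timecourse <- function(timecourse) {
  ggplot(timecourse, aes(x = .data$time, y = .data$conc,
                         colour = .data$species)) +
    geom_line() + geom_point() +
    labs(x = "time (min)", y = "concentration (uM)", colour = NULL) +
    theme_minimal()
}

#' Plot an RMSD series
#'
#' @param series Output of [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd_series <- function(series) {
  ggplot(series, aes(x = .data$frame, y = .data$rmsd)) +
    geom_line() +
    labs(x = "frame", y = "RMSD (Å)") +
    theme_minimal()
}

#' Plot hydrogen-bond contact populations
#'
#' @param populations Output of [hbond_populations()].
#' @return A ggplot bar chart.
#' @export
plot_contact_populations <- function(populations) {
  ggplot(populations, aes(x = .data$label, y = .data$population)) +
    geom_col() +
    labs(x = NULL, y = "population (fraction of frames)") +
    theme_minimal()
}

#' Plot the envelope-deconvolution fit of a quantitation
#'
#' @param estimate A `quant_estimate` from [quantify_analyte()].
#' @return A ggplot object comparing observed and fitted envelopes.
#' @export
plot_quant_fit <- function(estimate) {
  g <- estimate$grid
  fitted <- estimate$ratio * estimate$grid$standard * 0 +
    g$analyte * estimate$ratio + g$standard
  df <- tibble(
    mz = rep(g$mz, 2),
    intensity = c(g$observed / sum(g$observed),
                  fitted / sum(fitted)),
    which = rep(c("observed", "fitted"), each = nrow(g))
  )
  ggplot(df, aes(x = .data$mz, y = .data$intensity, fill = .data$which)) +
    geom_col(position = "dodge") +
    labs(x = "m/z", y = "normalized intensity", fill = NULL) +
    theme_minimal()
}
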