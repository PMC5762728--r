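# Absolute quantitation from overlapping isotope envelopes of an unlabeled
# analyte and its 18O-labeled internal standard. Because heavy-water
# enrichment is partial (95-98%), the standard's envelope leaks intensity
# into the analyte's +2 Da region; a simple first-peak height ratio is biased,
# so the default estimator deconvolves the two predicted envelopes from the
# mixture by nonnegative least squares. The classical calibration-line method
# (peak-height ratio vs sample load) is provided as an alternative.

#' Deconvolve analyte and standard envelopes from a mixture region
#'
#' Builds a common mass grid (peaks within `merge_tol` Da pooled) over the
#' union of the two predicted pattern supports and solves
#' `mixture ~ cA * analyte + cS * standard` by nonnegative least squares
#' (`pracma::lsqnonneg`).
#'
#' @param mixture A `maldi_spectrum` (or tibble with `mz`, `intensity`)
#'   restricted to or containing the envelope region. Pattern masses and
#'   spectrum `mz` must be on the same axis (shift neutral patterns by the
#'   proton mass first; [quantify_analyte()] does this).
#' @param analyte_pattern,standard_pattern Pattern tibbles (`mass`,
#'   `abundance`).
#' @param merge_tol Grid width in Da.
#' @return A list with `cA`, `cS` (nonnegative coefficients), `residual`
#'   (residual norm), and `grid` (the design used).
#' @export
fit_envelopes <- function(mixture, analyte_pattern, standard_pattern,
                          merge_tol = acecleave_defaults()$merge_tol) {
  all_mass <- c(analyte_pattern$mass, standard_pattern$mass)
  grp <- cluster_masses(all_mass, merge_tol)
  centers <- as.numeric(tapply(all_mass, grp, mean))
  a_col <- sum_into_bins(analyte_pattern, centers, merge_tol)
  s_col <- sum_into_bins(standard_pattern, centers, merge_tol)
  if (sqrt(sum((a_col / max(a_col) - s_col / max(s_col))^2)) < 1e-9)
    abort("degenerate fit: analyte and standard patterns are identical")
  y <- sum_into_bins(tibble(mass = mixture$mz, abundance = mixture$intensity),
                     centers, merge_tol)
  X <- cbind(analyte = a_col, standard = s_col)
  fit <- pracma::lsqnonneg(X, y)
  list(cA = fit$x[1], cS = fit$x[2],
       residual = sqrt(sum((y - X %*% fit$x)^2)),
       grid = tibble(mz = centers, observed = y,
                     analyte = a_col, standard = s_col))
}

cluster_masses <- function(mass, tol) {
  o <- order(mass)
  grp <- integer(length(mass))
  grp[o] <- cumsum(c(1, diff(mass[o]) > tol))
  grp
}

sum_into_bins <- function(pattern, centers, tol) {
  out <- numeric(length(centers))
  if (nrow(pattern) == 0) return(out)
  for (i in seq_len(nrow(pattern))) {
    d <- abs(centers - pattern$mass[i])
    j <- which.min(d)
    if (d[j] <= tol) out[j] <- out[j] + pattern$abundance[i]
  }
  out
}

#' Absolute analyte concentration from an \eqn{^{18}}O internal standard
#'
#' Predicts the analyte and labeled-standard envelopes at `[M+H]+`,
#' recalibrates the mixture region against them (intensity-weighted median
#' offset of observed peaks to their nearest predicted position, absorbing
#' the external-calibration error), deconvolves with [fit_envelopes()], and
#' scales the coefficient ratio by the known standard concentration.
#'
#' @param mixture A `maldi_spectrum` of the analyte/standard mixture.
#' @param analyte A one-row peptide tibble.
#' @param lm A [labeling_model()] describing the standard.
#' @param standard_conc Known standard concentration (uM), > 0.
#' @param window Da padding around the predicted envelope support used to
#'   select mixture peaks.
#' @return A `quant_estimate`: `analyte_conc` (uM), `ratio` (cA/cS),
#'   `residual`, `method = "deconvolution"`, plus the fitted grid.
#' @examples
#' an <- parse_peptide("[Acetyl]-DAEFGHDSGFEVR")
#' lm <- labeling_model(2, 0.95)
#' std <- make_standard_spectrum(an, lm, conc = 10,
#'   spectrum_params(noise_cv = 0, calibration_offset = 0))
#' mixed <- mutate(an, conc = 5)
#' spec <- render_spectrum(bind_rows(mixed, mutate(an, conc = 10)),
#'   spectrum_params(noise_cv = 0, calibration_offset = 0),
#'   labeling = list(NULL, lm))
#' quantify_analyte(spec, an, lm, standard_conc = 10)
#' @export
quantify_analyte <- function(mixture, analyte, lm, standard_conc,
                             window = 1.0) {
  if (standard_conc <= 0) abort("standard_conc must be > 0")
  comp <- composition_of(analyte)
  a_pat <- isotope_pattern(comp)
  s_pat <- labeled_pattern(comp, lm)
  a_pat$mass <- a_pat$mass + PROTON_MASS
  s_pat$mass <- s_pat$mass + PROTON_MASS
  support <- range(c(a_pat$mass, s_pat$mass))
  region <- mixture[mixture$mz >= support[1] - window &
                    mixture$mz <= support[2] + window, , drop = FALSE]
  if (nrow(region) == 0) abort("no mixture peaks in the envelope region")
  # recalibrate: intensity-weighted median shift to nearest predicted peak
  pred <- sort(c(a_pat$mass, s_pat$mass))
  shifts <- map_dbl(region$mz, ~ .x - pred[which.min(abs(pred - .x))])
  near <- abs(shifts) <= 0.5
  if (any(near)) {
    offset <- weighted_median(shifts[near], region$intensity[near])
    region$mz <- region$mz - offset
  } else offset <- 0
  fit <- fit_envelopes(region, a_pat, s_pat)
  if (fit$cS <= 1e-9 * (fit$cA + fit$cS))
    abort("standard envelope not detected in the mixture")
  ratio <- fit$cA / fit$cS
  structure(
    list(analyte = analyte, analyte_conc = ratio * standard_conc,
         ratio = ratio, residual = fit$residual, method = "deconvolution",
         standard_conc = standard_conc, calibration_offset = offset,
         grid = fit$grid),
    class = "quant_estimate"
  )
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Calibration line: peak-height ratio vs sample load
#'
#' The alternative quantitation route: a least-squares line through
#' analyte/standard peak-height ratios measured at known analyte loads, with
#' an inverse predictor mapping a new ratio to a load.
#'
#' @param ratios Numeric vector of peak-height ratios.
#' @param loads Numeric vector of known analyte loads (>= 2 distinct values).
#' @return A `calibration_fit` with `slope`, `intercept`, `predict(ratio)`,
#'   and the underlying `lm` fit.
#' @examples
#' cal <- calibration_line(c(0.5, 1.0, 2.0), c(5, 10, 20))
#' cal$predict(1.5)
#' @export
calibration_line <- function(ratios, loads) {
  if (length(ratios) != length(loads)) abort("ratios and loads lengths differ")
  if (length(unique(loads)) < 2) abort("need >= 2 distinct loads")
  fit <- lm(ratios ~ loads)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  structure(
    list(slope = slope, intercept = intercept, fit = fit,
         predict = function(ratio) (ratio - intercept) / slope,
         method = "calibration"),
    class = "calibration_fit"
  )
}

#' @export
print.quant_estimate <- function(x, ...) {
  cat(sprintf("<quant_estimate> %s: %.3f uM (ratio %.4f vs %.3g uM standard, residual %.3g)\n",
              format_peptide(x$analyte), x$analyte_conc, x$ratio,
              x$standard_conc, x$residual))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quant_estimate <- function(x, ...) {
  tibble(analyte = format_peptide(x$analyte), analyte_conc = x$analyte_conc,
         ratio = x$ratio, residual = x$residual, method = x$method,
         standard_conc = x$standard_conc)
}

#' @exportS3Method generics::glance
glance.quant_estimate <- function(x, ...) tidy(x)

#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = s$r.squared, sigma = s$sigma,
         n = length(x$fit$residuals))
}
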