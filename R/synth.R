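# Synthetic-data generator: first-order digestion time courses and MALDI-like
# centroid spectra (isotope envelopes scaled by concentration, calibration
# offset, multiplicative intensity noise, low-mass matrix suppression). It
# stands in for the instrument so the matching, inference and quantitation
# stages are testable end to end.

new_spectrum <- function(mz, intensity, meta = list()) {
  o <- order(mz)
  out <- tibble(mz = mz[o], intensity = intensity[o])
  attr(out, "meta") <- meta
  class(out) <- c("maldi_spectrum", class(tibble()))
  out
}

#' Assemble a centroid spectrum from peak vectors
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param meta Optional metadata list (instrument mode, provenance).
#' @return A `maldi_spectrum` tibble with columns `mz`, `intensity`.
#' @export
spectrum_from_peaks <- function(mz, intensity, meta = list()) {
  if (length(mz) != length(intensity)) abort("mz and intensity lengths differ")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    abort("intensities must be finite and >= 0")
  new_spectrum(mz, intensity, meta)
}

#' Spectrum-rendering parameters
#'
#' @param mz_window Length-2 numeric, the acquired m/z range.
#' @param suppression_cutoff m/z below which peaks are removed (MALDI matrix
#'   suppression region).
#' @param calibration_offset Constant m/z offset in Da applied to every peak;
#'   `NULL` draws one offset per spectrum from `N(0, calibration_sd)`.
#' @param calibration_sd SD (Da) of the drawn offset, emulating the <= 0.2 Da
#'   calculated-vs-observed discrepancies of external calibration.
#' @param noise_cv CV of the multiplicative lognormal intensity noise.
#' @param response Per-spectrum intensity scale (counts per concentration
#'   unit).
#' @param seed Optional RNG seed giving bit-reproducible spectra.
#' @return A list of class `spectrum_params`.
#' @export
spectrum_params <- function(mz_window = c(400, 2500),
                            suppression_cutoff = acecleave_defaults()$suppression_cutoff,
                            calibration_offset = NULL,
                            calibration_sd = acecleave_defaults()$calibration_sd,
                            noise_cv = acecleave_defaults()$noise_cv,
                            response = 1000,
                            seed = NULL) {
  if (length(mz_window) != 2 || mz_window[1] >= mz_window[2])
    abort("mz_window must be (low, high) with low < high")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  structure(list(mz_window = mz_window, suppression_cutoff = suppression_cutoff,
                 calibration_offset = calibration_offset,
                 calibration_sd = calibration_sd, noise_cv = noise_cv,
                 response = response, seed = seed),
            class = "spectrum_params")
}

#' First-order limited-digestion time course
#'
#' Each cleavable bond carries an independent first-order rate constant; the
#' substrate decays with the total rate and each bond's complementary product
#' pair accrues in proportion to its rate share (closed-form solution, no ODE
#' integration). Chain count is conserved.
#'
#' @param substrate A one-row peptide tibble.
#' @param rates Named numeric vector of per-bond rate constants (1/min);
#'   names are local bond indices i for the bond i-(i+1).
#' @param times Increasing numeric vector of sampling times (min).
#' @param c0 Initial substrate concentration (uM).
#' @return A tibble with one row per species per time: columns `time`,
#'   `species`, `conc`, plus the peptide columns of the species.
#' @examples
#' s <- abeta_substrates("Ac-Abeta1-16-amide")
#' simulate_timecourse(s, c(`5` = 0.05), times = c(10, 20, 40))
#' @export
simulate_timecourse <- function(substrate, rates, times, c0 = 40) {
  stopifnot(nrow(substrate) == 1)
  if (any(rates < 0)) abort("rate constants must be >= 0")
  if (any(times < 0) || is.unsorted(times)) abort("times must be >= 0 and increasing")
  n <- nchar(substrate$sequence)
  bonds <- as.integer(names(rates))
  if (any(is.na(bonds)) || any(bonds < 1) || any(bonds >= n))
    abort("rate names must be valid bond indices")
  ktot <- sum(rates)
  species <- list(mutate(substrate, role = "substrate", bond = NA_integer_))
  for (b in seq_along(bonds)) {
    i <- bonds[b]
    species <- c(species, list(
      mutate(subpeptide(substrate, 1L, i), role = "product", bond = i),
      mutate(subpeptide(substrate, i + 1L, n), role = "product", bond = i)
    ))
  }
  sp <- bind_rows(species)
  rows <- map(seq_along(times), function(ti) {
    t <- times[ti]
    depleted <- if (ktot > 0) c0 * (1 - exp(-ktot * t)) else 0
    conc <- numeric(nrow(sp))
    conc[1] <- c0 - depleted
    if (nrow(sp) > 1) {
      share <- rates[match(sp$bond[-1], bonds)] / ifelse(ktot > 0, ktot, 1)
      conc[-1] <- depleted * share
    }
    mutate(sp, time = t, conc = conc)
  })
  out <- bind_rows(rows)
  out <- mutate(out, species = .data$label, .before = 1)
  select(out, "time", "species", "conc", everything(), -"label")
}

# run expr with a temporarily seeded RNG, restoring the previous state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a MALDI-like centroid spectrum of a peptide mixture
#'
#' Each species contributes its (optionally \eqn{^{18}}O-labeled) isotope
#' envelope at `[M+H]+`, scaled by concentration x response; all peaks are
#' shifted by the calibration offset, multiplied by lognormal noise of CV
#' `noise_cv`, summed within 0.2 Da, and removed below the matrix-suppression
#' cutoff or outside the acquisition window.
#'
#' @param mixture A peptide tibble with a `conc` column (uM), e.g. one time
#'   slice of [simulate_timecourse()].
#' @param sp A [spectrum_params()] object.
#' @param labeling Optional: a single [labeling_model()] applied to every
#'   species, or a list of models (NULL entries = unlabeled) parallel to the
#'   mixture rows.
#' @return A `maldi_spectrum` tibble; metadata records the parameters and the
#'   realized calibration offset.
#' @examples
#' mix <- mutate(abeta_substrates("Abeta1-16"), conc = 40)
#' render_spectrum(mix, spectrum_params(noise_cv = 0, calibration_offset = 0))
#' @export
render_spectrum <- function(mixture, sp = spectrum_params(), labeling = NULL) {
  if (nrow(mixture) == 0)
    return(new_spectrum(numeric(0), numeric(0), meta = list(params = sp)))
  if (!"conc" %in% names(mixture)) abort("mixture needs a 'conc' column")
  if (any(mixture$conc < 0)) abort("concentrations must be >= 0")
  if (inherits(labeling, "labeling_model"))
    labeling <- rep(list(labeling), nrow(mixture))
  with_seed(sp$seed, {
    offset <- sp$calibration_offset %||% rnorm(1, 0, sp$calibration_sd)
    peaks <- map(seq_len(nrow(mixture)), function(i) {
      if (mixture$conc[i] <= 0) return(NULL)
      comp <- composition_of(mixture[i, ])
      lmi <- if (!is.null(labeling)) labeling[[i]] else NULL
      pat <- if (is.null(lmi)) isotope_pattern(comp) else labeled_pattern(comp, lmi)
      tibble(mz = pat$mass + PROTON_MASS,
             intensity = pat$abundance * mixture$conc[i] * sp$response)
    })
    pk <- bind_rows(peaks)
    if (nrow(pk) == 0)
      return(new_spectrum(numeric(0), numeric(0),
                          meta = list(params = sp, calibration_offset = offset)))
    merged <- compact_pattern(pk$mz, pk$intensity, tol = acecleave_defaults()$merge_tol)
    mz <- merged$mass + offset
    int <- merged$abundance
    if (sp$noise_cv > 0) {
      sdlog <- sqrt(log(1 + sp$noise_cv^2))
      int <- int * rlnorm(length(int), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    keep <- mz >= sp$suppression_cutoff & mz >= sp$mz_window[1] & mz <= sp$mz_window[2]
    new_spectrum(mz[keep], int[keep],
                 meta = list(instrument = "synthetic MALDI-TOF reflector positive",
                             params = sp, calibration_offset = offset))
  })
}

#' Spectrum of an \eqn{^{18}}O-labeled internal standard alone
#'
#' @param analyte A one-row peptide tibble.
#' @param lm A [labeling_model()].
#' @param conc Standard concentration (uM).
#' @param sp A [spectrum_params()] object.
#' @return A `maldi_spectrum` tibble.
#' @export
make_standard_spectrum <- function(analyte, lm, conc, sp = spectrum_params()) {
  mixture <- mutate(analyte, conc = conc)
  render_spectrum(mixture, sp, labeling = lm)
}

#' Write / read a centroid spectrum as CSV
#'
#' Two columns (mz, intensity); `#`-prefixed metadata lines are preserved as
#' a `meta` attribute on read.
#'
#' @param spectrum A `maldi_spectrum` or any tibble with `mz`, `intensity`.
#' @param path File path.
#' @param meta Named character vector of metadata lines.
#' @return The path (write) or a `maldi_spectrum` (read).
#' @export
write_spectrum_csv <- function(spectrum, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", names(meta), ": ", meta), con)
  writeLines("mz,intensity", con)
  writeLines(sprintf("%.6f,%.8g", spectrum$mz, spectrum$intensity), con)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  body <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = ",")
  spectrum_from_peaks(body$mz, body$intensity)
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat("<maldi_spectrum>", nrow(x), "peaks")
  if (nrow(x)) cat(sprintf(", m/z %.2f-%.2f", min(x$mz), max(x$mz)))
  cat("\n")
  NextMethod()
}
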