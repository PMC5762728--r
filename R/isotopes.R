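# Isotope-envelope prediction by elemental convolution.
#
# A pattern is a tibble(mass, abundance) sorted by mass. Envelopes are built
# by convolving per-element isotope distributions (binary exponentiation over
# atom counts), then merged on a coarse grid to mirror reflector-TOF
# resolution: isotopomers are resolved, fine structure is not.

# convolve two (mass, abundance) tables; compact near-identical masses and
# drop negligible terms to bound growth
conv_patterns <- function(a, b, eps = 1e-15) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance)
  out <- compact_pattern(as.vector(mass), as.vector(ab), tol = 1e-9)
  out[out$abundance > eps, , drop = FALSE]
}

# merge peaks closer than tol (abundance-weighted centroid)
compact_pattern <- function(mass, abundance, tol) {
  o <- order(mass)
  mass <- mass[o]; abundance <- abundance[o]
  if (length(mass) > 1) {
    grp <- cumsum(c(1, diff(mass) > tol))
  } else grp <- rep(1, length(mass))
  m <- tapply(mass * abundance, grp, sum) / tapply(abundance, grp, sum)
  a <- tapply(abundance, grp, sum)
  tibble(mass = as.numeric(m), abundance = as.numeric(a))
}

# natural pattern of n atoms of one element (binary exponentiation)
element_pattern <- function(element, n) {
  base <- tibble(mass = ISOTOPE_TABLE[[element]]$mass,
                 abundance = ISOTOPE_TABLE[[element]]$abundance)
  acc <- tibble(mass = 0, abundance = 1)
  while (n > 0) {
    if (n %% 2 == 1) acc <- conv_patterns(acc, base)
    n <- n %/% 2
    if (n > 0) base <- conv_patterns(base, base)
  }
  acc
}

#' Predict an isotope envelope from an elemental composition
#'
#' Convolves the per-element natural isotope distributions of a composition,
#' merges peaks within `merge_tol` Da into abundance-weighted centroids (the
#' reflector-TOF view: isotopomer spacing is resolved, isotopic fine structure
#' is not), and truncates peaks below a relative-abundance threshold.
#' Abundances sum to 1 before truncation.
#'
#' @param composition One-row composition tibble from [composition_of()], or a
#'   named numeric vector of element counts.
#' @param truncate Relative-abundance threshold in (0, 1); peaks below it are
#'   dropped after the envelope is assembled.
#' @param merge_tol Peaks closer than this (Da) are merged.
#' @return A tibble with columns `mass` (Da, neutral) and `abundance`
#'   (fractions of the untruncated envelope), masses strictly increasing.
#' @examples
#' isotope_pattern(c(C = 1))
#' isotope_pattern(composition_of(peptide("DAEFR")))
#' @export
isotope_pattern <- function(composition, truncate = acecleave_defaults()$truncate,
                            merge_tol = acecleave_defaults()$merge_tol) {
  if (truncate <= 0 || truncate >= 1) abort("truncate must be in (0, 1)")
  if (is.numeric(composition) && !is.null(names(composition)))
    composition <- as_tibble(as.list(composition))
  stopifnot(nrow(composition) == 1)
  unknown <- setdiff(names(composition), names(ISOTOPE_TABLE))
  if (length(unknown)) abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  pat <- tibble(mass = 0, abundance = 1)
  for (el in names(composition)) {
    n <- as.integer(composition[[el]][1])
    if (n > 0) pat <- conv_patterns(pat, element_pattern(el, n))
  }
  finish_pattern(pat, truncate, merge_tol)
}

finish_pattern <- function(pat, truncate, merge_tol) {
  pat <- compact_pattern(pat$mass, pat$abundance, tol = merge_tol)
  pat[pat$abundance >= truncate, , drop = FALSE]
}

#' \eqn{^{18}}O labeling model for internal standards
#'
#' Describes heavy-oxygen incorporation at the exchangeable C-terminal
#' carboxyl oxygens of a tryptically prepared internal standard: `n_sites`
#' oxygens (0-2) each carry \eqn{^{18}}O independently with probability
#' `p_inc` (the heavy-water enrichment, typically 0.95-0.98).
#'
#' @param n_sites Number of exchangeable oxygens, 0, 1 or 2.
#' @param p_inc Per-site incorporation probability in `[0, 1]`.
#' @return A list of class `labeling_model`.
#' @examples
#' labeling_model(n_sites = 2, p_inc = 0.95)
#' @export
labeling_model <- function(n_sites = acecleave_defaults()$n_sites,
                           p_inc = acecleave_defaults()$p_inc) {
  if (!n_sites %in% 0:2) abort("n_sites must be 0, 1 or 2")
  if (p_inc < 0 || p_inc > 1) abort("p_inc must be in [0, 1]")
  structure(list(n_sites = as.integer(n_sites), p_inc = p_inc),
            class = "labeling_model")
}

#' Isotope envelope of an \eqn{^{18}}O-labeled peptide
#'
#' Convolves the natural envelope of the composition minus `n_sites` oxygens
#' with the binomial mixture over the labeled sites: each site carries
#' \eqn{^{18}}O (+2.00425 Da) with probability `p_inc` and remains a
#' natural-abundance oxygen otherwise (the unexchanged fraction comes from
#' ordinary water), so `p_inc = 0` reproduces the natural envelope exactly.
#'
#' @inheritParams isotope_pattern
#' @param lm A [labeling_model()].
#' @return A pattern tibble as in [isotope_pattern()].
#' @examples
#' comp <- composition_of(peptide("DAEFR"))
#' labeled_pattern(comp, labeling_model(2, 0.95))
#' @export
labeled_pattern <- function(composition, lm,
                            truncate = acecleave_defaults()$truncate,
                            merge_tol = acecleave_defaults()$merge_tol) {
  stopifnot(inherits(lm, "labeling_model"))
  if (is.numeric(composition) && !is.null(names(composition)))
    composition <- as_tibble(as.list(composition))
  if (lm$n_sites == 0)
    return(isotope_pattern(composition, truncate, merge_tol))
  if (!"O" %in% names(composition) || composition$O[1] < lm$n_sites)
    abort("composition has fewer oxygen atoms than labeling sites")
  base <- composition
  base$O <- base$O - lm$n_sites
  if (truncate <= 0 || truncate >= 1) abort("truncate must be in (0, 1)")
  pat <- tibble(mass = 0, abundance = 1)
  for (el in names(base)) {
    n <- as.integer(base[[el]][1])
    if (n > 0) pat <- conv_patterns(pat, element_pattern(el, n))
  }
  site_ab <- (1 - lm$p_inc) * ISOTOPE_TABLE$O$abundance
  site_ab[3] <- site_ab[3] + lm$p_inc
  site <- tibble(mass = ISOTOPE_TABLE$O$mass, abundance = site_ab)
  site <- site[site$abundance > 0, ]
  for (k in seq_len(lm$n_sites)) pat <- conv_patterns(pat, site)
  finish_pattern(pat, truncate, merge_tol)
}

#' Write / read an isotope pattern as TSV
#'
#' Two columns (mass, abundance) with `#`-prefixed header lines carrying
#' free-form metadata (composition, labeling parameters).
#'
#' @param pattern A pattern tibble.
#' @param path File path.
#' @param meta Named character vector written as `# key: value` lines.
#' @return `write_pattern_tsv` returns `path` invisibly; `read_pattern_tsv`
#'   returns the pattern tibble with a `meta` attribute.
#' @export
write_pattern_tsv <- function(pattern, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), ": ", meta), con)
  writeLines("mass\tabundance", con)
  writeLines(sprintf("%.7f\t%.10g", pattern$mass, pattern$abundance), con)
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @export
read_pattern_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  meta <- NULL
  if (length(meta_lines)) {
    kv <- str_split(sub("^#\\s*", "", meta_lines), ":\\s*", n = 2)
    meta <- setNames(map_chr(kv, 2), map_chr(kv, 1))
  }
  out <- as_tibble(body)
  attr(out, "meta") <- meta
  out
}
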