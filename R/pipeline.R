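# Scenario configuration and end-to-end orchestration:
# digest -> time course -> spectrum -> match -> infer -> validate -> quant.

#' Define a pipeline scenario
#'
#' Collects everything one in-silico digestion experiment needs: the
#' substrate, the enzyme and rule set, optional inhibitor, per-bond kinetic
#' rates and sampling times, spectrum parameters, the labeling model and
#' standard concentration for quantitation, and a seed.
#'
#' @param substrate A substrate name from [abeta_substrates()], a bracket
#'   notation string, or a one-row peptide tibble.
#' @param enzyme Enzyme identifier in `rules`.
#' @param rules A cleavage-rule tibble (default [ace_rules()]).
#' @param inhibitor Optional inhibitor identifier.
#' @param rates Named per-bond first-order rate constants (1/min); default
#'   0.05/min at every bond the rules cleave.
#' @param times Sampling times (min).
#' @param c0 Initial substrate concentration (uM).
#' @param params A [spectrum_params()] object.
#' @param labeling A [labeling_model()] for the internal standard.
#' @param quant_analyte Optional: peptide tibble / notation of the product to
#'   quantify; `NULL` quantifies the first product.
#' @param standard_conc Internal-standard concentration (uM).
#' @param tol Peak-matching tolerance (Da).
#' @param seed Seed for all stochastic stages.
#' @param out_dir Optional directory to which per-stage TSV/CSV artifacts are
#'   written.
#' @return A list of class `scenario`.
#' @export
scenario <- function(substrate, enzyme, rules = ace_rules(), inhibitor = NULL,
                     rates = NULL, times = c(10, 20, 40), c0 = 40,
                     params = spectrum_params(), labeling = labeling_model(),
                     quant_analyte = NULL, standard_conc = 10,
                     tol = acecleave_defaults()$match_tol,
                     seed = NULL, out_dir = NULL) {
  substrate <- resolve_substrate(substrate)
  if (!is.null(quant_analyte) && is.character(quant_analyte))
    quant_analyte <- parse_peptide(quant_analyte)
  sc <- structure(
    list(substrate = substrate, enzyme = enzyme, rules = rules,
         inhibitor = inhibitor, rates = rates, times = times, c0 = c0,
         params = params, labeling = labeling, quant_analyte = quant_analyte,
         standard_conc = standard_conc, tol = tol, seed = seed,
         out_dir = out_dir),
    class = "scenario"
  )
  validate_scenario(sc)
  sc
}

resolve_substrate <- function(substrate) {
  if (is.character(substrate)) {
    reg <- abeta_substrates()
    if (substrate %in% reg$name)
      return(select(abeta_substrates(substrate), -"name"))
    return(parse_peptide(substrate))
  }
  stopifnot(is.data.frame(substrate), nrow(substrate) == 1)
  substrate
}

validate_scenario <- function(sc) {
  if (!sc$enzyme %in% sc$rules$enzyme)
    abort(paste0("scenario invalid: no rules for enzyme '", sc$enzyme, "'"))
  if (any(sc$times < 0) || is.unsorted(sc$times))
    abort("scenario invalid: times must be >= 0 and increasing")
  if (!is.null(sc$rates) && any(sc$rates < 0))
    abort("scenario invalid: negative rate constant")
  if (sc$standard_conc <= 0)
    abort("scenario invalid: standard_conc must be > 0")
  invisible(sc)
}

#' Read a scenario from a YAML file
#'
#' Recognized keys: `substrate`, `enzyme`, `inhibitor`, `rates` (map of bond
#' index to 1/min), `times`, `c0`, `standard_conc`, `tol`, `seed`,
#' `spectrum` (map of [spectrum_params()] fields), `labeling` (map with
#' `n_sites`, `p_inc`), `out_dir`.
#'
#' @param path Path to a YAML scenario file.
#' @return A `scenario` object.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$substrate) || is.null(cfg$enzyme))
    abort("scenario file must define 'substrate' and 'enzyme'")
  sp_args <- cfg$spectrum %||% list()
  if (!is.null(sp_args$mz_window)) sp_args$mz_window <- unlist(sp_args$mz_window)
  lm_args <- cfg$labeling %||% list()
  rates <- if (!is.null(cfg$rates)) unlist(cfg$rates) else NULL
  scenario(
    substrate = cfg$substrate, enzyme = cfg$enzyme,
    inhibitor = cfg$inhibitor,
    rates = rates,
    times = unlist(cfg$times %||% c(10, 20, 40)),
    c0 = cfg$c0 %||% 40,
    params = do.call(spectrum_params, sp_args),
    labeling = do.call(labeling_model, lm_args),
    quant_analyte = cfg$quant_analyte,
    standard_conc = cfg$standard_conc %||% 10,
    tol = cfg$tol %||% acecleave_defaults()$match_tol,
    seed = cfg$seed, out_dir = cfg$out_dir
  )
}

#' Run the full in-silico pipeline for a scenario
#'
#' Executes digestion, the kinetic time course, spectrum rendering at the
#' final time point, peak matching, cleavage-map inference, inhibitor-control
#' validation (a control spectrum is always rendered with the inhibitor
#' applied), and -- when a digestion product exists -- quantitation against
#' the \eqn{^{18}}O-labeled internal standard. With a fixed scenario seed
#' every numeric output is reproducible.
#'
#' @param sc A [scenario()].
#' @return A list of class `pipeline_report`: `digest`, `timecourse`,
#'   `spectrum`, `matches`, `map` (validated `cleavage_map`), `quant`
#'   (a `quant_estimate` or `NULL`), and `scenario`.
#' @examples
#' rep <- run_pipeline(scenario("Ac-Abeta1-16-amide", "N-ACE",
#'   params = spectrum_params(noise_cv = 0, calibration_offset = 0)))
#' rep$map
#' @export
run_pipeline <- function(sc) {
  validate_scenario(sc)
  dg <- digest_with_rules(sc$substrate, sc$enzyme, sc$rules, sc$inhibitor)
  rates <- sc$rates
  if (is.null(rates)) {
    rates <- setNames(rep(0.05, nrow(dg$bonds)), dg$bonds$bond)
  }
  tc <- if (length(rates)) {
    simulate_timecourse(sc$substrate, rates, sc$times, c0 = sc$c0)
  } else {
    mutate(tidyr::expand_grid(time = sc$times, sc$substrate),
           species = .data$label, conc = sc$c0)
  }
  final <- filter(tc, .data$time == max(sc$times))
  sp <- sc$params
  if (!is.null(sc$seed)) sp$seed <- sc$seed
  spec <- render_spectrum(final, sp)
  # control spectrum: same scenario with the inhibitor applied
  ctrl_dg <- digest_with_rules(sc$substrate, sc$enzyme, sc$rules,
                               inhibitor = "lisinopril")
  ctrl_mix <- mutate(sc$substrate, conc = sc$c0)
  ctrl_sp <- sp
  if (!is.null(ctrl_sp$seed)) ctrl_sp$seed <- ctrl_sp$seed + 1L
  control <- render_spectrum(ctrl_mix, ctrl_sp)
  cands <- enumerate_candidate_fragments(sc$substrate, min_length = 1L)
  matches <- match_peaks(spec, cands, tol = sc$tol)
  map <- infer_cleavage_map(matches, sc$substrate,
                            suppression_cutoff = sp$suppression_cutoff)
  map <- validate_with_inhibitor(map, control, tol = sc$tol)
  qn <- NULL
  if (nrow(dg$products) > 0 && !dg$inhibited) {
    analyte <- sc$quant_analyte %||% dg$products[1, ]
    std_conc <- sc$standard_conc
    mix <- bind_rows(
      mutate(analyte, conc = filter(final, .data$species == analyte$label)$conc[1] %||% NA),
      mutate(analyte, conc = std_conc)
    )
    if (!is.na(mix$conc[1]) && mix$conc[1] > 0) {
      qsp <- sp
      if (!is.null(qsp$seed)) qsp$seed <- qsp$seed + 2L
      qspec <- render_spectrum(mix, qsp, labeling = list(NULL, sc$labeling))
      qn <- tryCatch(
        quantify_analyte(qspec, analyte, sc$labeling, std_conc),
        error = function(e) NULL
      )
    }
  }
  report <- structure(
    list(digest = dg, timecourse = tc, spectrum = spec, control = control,
         matches = matches, map = map, quant = qn, scenario = sc),
    class = "pipeline_report"
  )
  if (!is.null(sc$out_dir)) write_report(report, sc$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_report(report$timecourse[, c("time", "species", "conc")],
                   file.path(dir, "timecourse.tsv"))
  write_spectrum_csv(report$spectrum, file.path(dir, "spectrum.csv"))
  write_spectrum_csv(report$control, file.path(dir, "control.csv"))
  write_tsv_report(report$matches, file.path(dir, "matches.tsv"))
  write_tsv_report(tidy(report$map), file.path(dir, "cleavage_map.tsv"))
  summary_lines <- c(
    paste("substrate:", format_peptide(report$map$substrate)),
    paste("enzyme:", report$scenario$enzyme),
    paste("mode:", report$map$mode_call),
    paste("bonds:", paste(report$map$bonds$label, collapse = ", ")),
    paste("control_validated:", report$map$control_validated),
    if (!is.null(report$quant))
      paste("analyte_conc_uM:", format(report$quant$analyte_conc))
  )
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", format_peptide(x$scenario$substrate), "+",
      x$scenario$enzyme,
      if (!is.null(x$scenario$inhibitor)) paste0("(+", x$scenario$inhibitor, ")"),
      "\n")
  print(x$map)
  if (!is.null(x$quant)) print(x$quant)
  invisible(x)
}
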