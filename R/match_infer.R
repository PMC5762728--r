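# Peak matching and cleavage-map inference: assign centroid peaks to
# candidate fragments by exact mass, derive the set of cleaved bonds from the
# matched fragment boundaries, classify the enzyme mode from the product
# geometry, and validate against an inhibitor-control spectrum.

#' Match spectrum peaks to candidate fragments
#'
#' For every peak, every candidate whose calculated `[M+H]+` lies within
#' `tol` is reported, nearest first. Peaks matching the substrate interval
#' itself are flagged `is_parent`.
#'
#' @param spectrum A `maldi_spectrum` or tibble with `mz`, `intensity`.
#' @param candidates A peptide tibble, typically
#'   [enumerate_candidate_fragments()] output (its `is_parent` flag is used
#'   when present).
#' @param tol Matching tolerance in Da (> 0). The default 0.3 Da covers
#'   external-calibration MALDI mass errors with margin while the nearest
#'   alternative fragment assignments for these substrates sit > 0.9 Da away.
#' @param monoisotopic_only When `TRUE` (default), only envelope-head peaks
#'   are assigned: a peak with a substantial neighbour one isotopomer spacing
#'   (1.003 Da) below it is part of a higher envelope, not a monoisotopic
#'   peak, and is skipped. Calculated masses are monoisotopic, so matching
#'   a non-head peak would be a misassignment.
#' @return A tibble of matches: `peak_mz`, `intensity`, candidate peptide
#'   columns, `calc_mz`, `mass_error` (observed - calculated), `is_parent`,
#'   and `rank` (1 = nearest candidate for that peak).
#' @examples
#' s <- abeta_substrates("Abeta1-16")
#' cand <- enumerate_candidate_fragments(s, min_length = 2)
#' spec <- spectrum_from_peaks(c(1698.6, 1954.8), c(40, 100))
#' match_peaks(spec, cand)
#' @export
match_peaks <- function(spectrum, candidates, tol = acecleave_defaults()$match_tol,
                        monoisotopic_only = TRUE) {
  if (tol <= 0) abort("tol must be > 0")
  empty <- tibble(peak_mz = numeric(), intensity = numeric(),
                  label = character(), sequence = character(),
                  n_mod = character(), c_mod = character(),
                  parent = character(), start = integer(), end = integer(),
                  is_parent = logical(), calc_mz = numeric(),
                  mass_error = numeric(), rank = integer())
  if (nrow(candidates) == 0 || nrow(spectrum) == 0) return(empty)
  if (!"is_parent" %in% names(candidates)) candidates$is_parent <- FALSE
  candidates$calc_mz <- mz_of(candidates)
  if (monoisotopic_only && nrow(spectrum) > 1) {
    is_head <- map_lgl(seq_len(nrow(spectrum)), function(p) {
      below <- abs(spectrum$mz - (spectrum$mz[p] - 1.00335)) <= 0.25
      !any(below & spectrum$intensity >= 0.2 * spectrum$intensity[p])
    })
    spectrum <- spectrum[is_head, , drop = FALSE]
  }
  rows <- map(seq_len(nrow(spectrum)), function(p) {
    err <- spectrum$mz[p] - candidates$calc_mz
    hit <- which(abs(err) <= tol)
    if (!length(hit)) return(NULL)
    out <- candidates[hit, ]
    out$peak_mz <- spectrum$mz[p]
    out$intensity <- spectrum$intensity[p]
    out$mass_error <- err[hit]
    out <- out[order(abs(out$mass_error)), ]
    out$rank <- seq_len(nrow(out))
    out
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) return(empty)
  select(res, "peak_mz", "intensity", "label", "sequence", "n_mod", "c_mod",
         "parent", "start", "end", "is_parent", "calc_mz", "mass_error", "rank")
}

new_cleavage_map <- function(substrate, bonds, products, mode_call,
                             control_validated = NA) {
  structure(
    list(substrate = substrate, bonds = bonds, products = products,
         mode_call = mode_call, control_validated = control_validated),
    class = "cleavage_map"
  )
}

#' Infer the cleavage map from matched peaks
#'
#' Every matched non-parent fragment implies the bond(s) at its boundaries
#' (in local substrate coordinates). A bond corroborated from both sides by
#' a complementary fragment pair is accepted; a bond supported on one side
#' only is accepted when the missing complement's `[M+H]+` falls below the
#' matrix-suppression cutoff (it could not have been observed), otherwise it
#' is kept but flagged `tentative`. The enzyme mode is then classified with
#' [classify_mode()].
#'
#' @param matches Output of [match_peaks()] for candidates of this substrate.
#' @param substrate The one-row peptide tibble the candidates came from.
#' @param suppression_cutoff m/z below which a missing complementary fragment
#'   is excused.
#' @return A `cleavage_map`: substrate, `bonds` tibble (`bond`, `label`,
#'   `status` accepted/tentative, `support`), matched `products`, `mode_call`,
#'   `control_validated` (NA until [validate_with_inhibitor()]).
#' @export
infer_cleavage_map <- function(matches, substrate,
                               suppression_cutoff = acecleave_defaults()$suppression_cutoff) {
  stopifnot(nrow(substrate) == 1)
  n <- nchar(substrate$sequence)
  if (nrow(matches) > 0) {
    same_parent <- is.na(substrate$parent) | is.na(matches$parent) |
      matches$parent == substrate$parent
    inside <- matches$start >= substrate$start & matches$end <= substrate$end
    if (any(!same_parent | !inside))
      abort("matches reference fragments outside this substrate")
  }
  frags <- matches[!matches$is_parent, , drop = FALSE]
  frags <- distinct(frags, .data$sequence, .data$n_mod, .data$c_mod,
                    .data$start, .data$end, .keep_all = TRUE)
  bond_rows <- list()
  for (f in seq_len(nrow(frags))) {
    lo <- frags$start[f] - substrate$start + 1L   # local coords
    hi <- frags$end[f] - substrate$start + 1L
    if (lo > 1L)
      bond_rows <- c(bond_rows, list(tibble(bond = lo - 1L, side = "C",
                                            fragment = frags$label[f])))
    if (hi < n)
      bond_rows <- c(bond_rows, list(tibble(bond = hi, side = "N",
                                            fragment = frags$label[f])))
  }
  if (!length(bond_rows)) {
    return(new_cleavage_map(substrate,
                            tibble(bond = integer(), label = character(),
                                   status = character(), support = character()),
                            frags, mode_call = "none"))
  }
  ev <- bind_rows(bond_rows)
  bonds <- ev |>
    group_by(.data$bond) |>
    summarise(sides = paste(sort(unique(.data$side)), collapse = ""),
              support = paste(unique(.data$fragment), collapse = "; "),
              .groups = "drop")
  status <- map_chr(seq_len(nrow(bonds)), function(b) {
    i <- bonds$bond[b]
    if (bonds$sides[b] == "CN") return("accepted")
    # which side is missing? N side missing => complement is (1..i);
    # C side missing => complement is (i+1..n)
    missing_frag <- if (grepl("N", bonds$sides[b]))
      subpeptide(substrate, i + 1L, n) else subpeptide(substrate, 1L, i)
    if (mz_of(missing_frag) < suppression_cutoff) "accepted" else "tentative"
  })
  bonds <- mutate(bonds,
                  label = map_chr(.data$bond, ~ bond_label(substrate, .x)),
                  status = status) |>
    select("bond", "label", "status", "support") |>
    arrange(.data$bond)
  map <- new_cleavage_map(substrate, bonds, frags, mode_call = "ambiguous")
  map$mode_call <- classify_mode(map)
  map
}

#' Classify the enzyme mode from a cleavage map
#'
#' Decides among the three proteolytic modes from the product geometry:
#' \itemize{
#'   \item a single N-anchored truncation shortened by exactly two residues
#'     (the canonical ACE action) is a dipeptidyl carboxypeptidase;
#'   \item N-anchored truncations at two or more depths within the last three
#'     residues are a processive carboxypeptidase;
#'   \item a single cleavage deeper in the chain -- corroborated by a
#'     complementary pair, a suppressed complement, or a single anchored
#'     fragment -- is an endopeptidase (this includes a lone specific cut
#'     releasing a C-terminal tripeptide, which no processive trimmer would
#'     produce without the shallower products);
#'   \item anything else is ambiguous; no bonds means no activity.
#' }
#'
#' @param map A `cleavage_map`.
#' @return One of `"endopeptidase"`, `"dipeptidyl_carboxypeptidase"`,
#'   `"processive_carboxypeptidase"`, `"none"`, `"ambiguous"`.
#' @export
classify_mode <- function(map) {
  bonds <- map$bonds$bond
  n <- nchar(map$substrate$sequence)
  if (length(bonds) == 0) return("none")
  depths <- n - bonds            # residues removed from the C-terminus
  if (length(bonds) == 1) {
    if (depths == 2) return("dipeptidyl_carboxypeptidase")
    if (depths >= 3) return("endopeptidase")
    return("ambiguous")
  }
  if (all(depths %in% 1:3) && length(unique(depths)) >= 2)
    return("processive_carboxypeptidase")
  "ambiguous"
}

#' Validate a cleavage map against an inhibitor-control spectrum
#'
#' The map is validated when none of its non-parent product peaks appears in
#' the control spectrum above an intensity floor; otherwise the bonds are
#' retained but flagged unvalidated. An empty control validates vacuously.
#'
#' @param map A `cleavage_map`.
#' @param control A `maldi_spectrum` acquired with the inhibitor present.
#' @param tol Matching tolerance in Da.
#' @param floor Intensity floor above which a control peak counts as present;
#'   default 3 x the median control intensity.
#' @return The map with `control_validated` set.
#' @export
validate_with_inhibitor <- function(map, control,
                                    tol = acecleave_defaults()$match_tol,
                                    floor = NULL) {
  if (nrow(control) == 0 || nrow(map$products) == 0) {
    map$control_validated <- TRUE
    return(map)
  }
  floor <- floor %||%
    (acecleave_defaults()$intensity_floor_factor * median(control$intensity))
  prod_mz <- mz_of(map$products)
  present <- map_lgl(prod_mz, function(m)
    any(abs(control$mz - m) <= tol & control$intensity > floor))
  map$control_validated <- !any(present)
  map
}

#' @export
print.cleavage_map <- function(x, ...) {
  cat("<cleavage_map>", format_peptide(x$substrate), "\n")
  cat("  mode:", x$mode_call, "\n")
  if (nrow(x$bonds)) {
    cat("  bonds:", paste0(x$bonds$label, " (", x$bonds$status, ")",
                           collapse = ", "), "\n")
    cat("  products:", paste(unique(x$products$label), collapse = ", "), "\n")
  } else cat("  no cleavage detected\n")
  if (!is.na(x$control_validated))
    cat("  inhibitor control:",
        if (x$control_validated) "validated" else "NOT validated", "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cleavage_map <- function(x, ...) x$bonds

#' @exportS3Method generics::glance
glance.cleavage_map <- function(x, ...) {
  tibble(
    substrate = format_peptide(x$substrate),
    mode_call = x$mode_call,
    n_bonds = nrow(x$bonds),
    n_products = nrow(x$products),
    control_validated = x$control_validated
  )
}
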