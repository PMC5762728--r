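# Rule-based limited-proteolysis engine.
#
# A rule set is a tibble; each row is one enzyme activity with its mode
# (endopeptidase / dipeptidyl_carboxypeptidase / processive_carboxypeptidase),
# residue specificity, substrate conditions and inhibitors. The shipped
# preset encodes the observed domain-specific behavior of the two ACE
# catalytic domains on the amyloid-beta metal-binding domain: it describes
# what each domain was seen to do on each terminal-modification state, not a
# mechanistic model.

CLEAVAGE_MODES <- c("endopeptidase", "dipeptidyl_carboxypeptidase",
                    "processive_carboxypeptidase")

#' Build a cleavage-rule table
#'
#' @param enzyme Enzyme identifier (e.g. `"N-ACE"`).
#' @param mode One of `"endopeptidase"`, `"dipeptidyl_carboxypeptidase"`,
#'   `"processive_carboxypeptidase"`.
#' @param p1 Allowed residues on the N-side of the scissile bond as a string
#'   of one-letter codes; `"*"` for any. Used by the endopeptidase mode.
#' @param p1prime Allowed residues on the C-side; `"*"` for any.
#' @param requires_c_mod,forbids_c_mod Condition on the substrate C-terminal
#'   modification (`NA` = no condition).
#' @param requires_sequence Exact substrate sequence condition (`NA` = any);
#'   used to scope a rule to one substrate chain.
#' @param trim_depths Integer vector of C-terminal truncation depths for the
#'   carboxypeptidase modes (a `max_trim` of m corresponds to `1:m`).
#' @param inhibitable_by Character vector of inhibitor identifiers that
#'   abolish the activity.
#' @return A one-row rule tibble; combine rows with [dplyr::bind_rows()].
#' @examples
#' cleavage_rule("N-ACE", "endopeptidase", p1 = "R", p1prime = "H",
#'               requires_c_mod = "amide")
#' @export
cleavage_rule <- function(enzyme, mode, p1 = "*", p1prime = "*",
                          requires_c_mod = NA_character_,
                          forbids_c_mod = NA_character_,
                          requires_sequence = NA_character_,
                          trim_depths = integer(),
                          inhibitable_by = character()) {
  if (!mode %in% CLEAVAGE_MODES)
    abort(paste0("unknown cleavage mode '", mode, "'"))
  if (mode == "endopeptidase" && !nzchar(p1))
    abort("endopeptidase rule needs a non-empty p1 residue set")
  tibble(
    enzyme = enzyme, mode = mode, p1 = p1, p1prime = p1prime,
    requires_c_mod = requires_c_mod, forbids_c_mod = forbids_c_mod,
    requires_sequence = requires_sequence,
    trim_depths = list(as.integer(trim_depths)),
    inhibitable_by = list(inhibitable_by)
  )
}

#' Observed ACE domain specificity on the amyloid-beta metal-binding domain
#'
#' The default rule set:
#' \itemize{
#'   \item N-ACE acts as an arginine-specific endopeptidase (Arg-His scissile
#'     bond) on C-amidated substrates, and as a dipeptidyl carboxypeptidase
#'     on substrates with a free carboxyl terminus.
#'   \item C-ACE acts as a carboxypeptidase, removing C-terminal di- and
#'     tripeptides from the free-acid human domain; it does not touch the
#'     amidated human domain but trims the amidated rat domain at depths
#'     1-3 (a substrate-scoped exception).
#' }
#' All activities are abolished by lisinopril.
#'
#' @return A rule tibble for [digest_with_rules()].
#' @examples
#' ace_rules()
#' @export
ace_rules <- function() {
  bind_rows(
    cleavage_rule("N-ACE", "endopeptidase", p1 = "R", p1prime = "H",
                  requires_c_mod = "amide", inhibitable_by = "lisinopril"),
    cleavage_rule("N-ACE", "dipeptidyl_carboxypeptidase",
                  requires_c_mod = "free", trim_depths = 2L,
                  inhibitable_by = "lisinopril"),
    cleavage_rule("C-ACE", "processive_carboxypeptidase",
                  requires_c_mod = "free", trim_depths = c(2L, 3L),
                  inhibitable_by = "lisinopril"),
    cleavage_rule("C-ACE", "processive_carboxypeptidase",
                  requires_c_mod = "amide",
                  requires_sequence = PARENT_CHAINS[["rat-Abeta"]],
                  trim_depths = c(1L, 2L, 3L),
                  inhibitable_by = "lisinopril")
  )
}

rule_applies <- function(rule, substrate) {
  (is.na(rule$requires_c_mod) || substrate$c_mod == rule$requires_c_mod) &&
    (is.na(rule$forbids_c_mod) || substrate$c_mod != rule$forbids_c_mod) &&
    (is.na(rule$requires_sequence) || substrate$sequence == rule$requires_sequence)
}

new_digest_result <- function(substrate, products, bonds, rules_fired,
                              inhibited = FALSE, warning_flag = FALSE) {
  structure(
    list(substrate = substrate, products = products, bonds = bonds,
         rules_fired = rules_fired, inhibited = inhibited,
         warning_flag = warning_flag),
    class = "digest_result"
  )
}

#' In-silico limited proteolysis under a rule set
#'
#' Applies every rule of `enzyme` whose substrate condition holds. The
#' endopeptidase mode cleaves each bond i with residue i in `p1` and residue
#' i+1 in `p1prime`, emitting both complementary fragments; the dipeptidyl
#' carboxypeptidase mode removes the C-terminal dipeptide; the processive
#' carboxypeptidase mode emits the N-terminal truncation at each configured
#' depth. Products inherit terminal modifications via [subpeptide()]. A
#' matching inhibitor abolishes all products. Cleavage is limited: products
#' are not re-digested within one call.
#'
#' @param substrate A one-row peptide tibble.
#' @param enzyme Enzyme identifier present in `rules`.
#' @param rules A rule tibble, by default [ace_rules()].
#' @param inhibitor Optional inhibitor identifier (e.g. `"lisinopril"`).
#' @return A `digest_result` with fields `substrate`, `products` (peptide
#'   tibble with a `bond` column, local coordinates), `bonds` (tibble of
#'   cleaved bonds with labels and provenance), `rules_fired`, `inhibited`.
#' @examples
#' digest_with_rules(abeta_substrates("Ac-Abeta1-16-amide"), "N-ACE")
#' @export
digest_with_rules <- function(substrate, enzyme, rules = ace_rules(),
                              inhibitor = NULL) {
  stopifnot(nrow(substrate) == 1)
  er <- rules[rules$enzyme == enzyme, , drop = FALSE]
  if (nrow(er) == 0) abort(paste0("no rules for enzyme '", enzyme, "'"))
  if (!is.null(inhibitor) &&
      any(map_lgl(er$inhibitable_by, ~ inhibitor %in% .x))) {
    return(new_digest_result(substrate, products = peptide("G")[0, ],
                             bonds = empty_bonds(), rules_fired = character(),
                             inhibited = TRUE))
  }
  n <- nchar(substrate$sequence)
  aa <- strsplit(substrate$sequence, "")[[1]]
  products <- list(); bonds <- list(); fired <- character()
  warning_flag <- FALSE
  for (r in seq_len(nrow(er))) {
    rule <- er[r, ]
    if (!rule_applies(rule, substrate)) next
    rid <- paste0(enzyme, ":", rule$mode, ":", r)
    if (rule$mode == "endopeptidase") {
      p1 <- strsplit(rule$p1, "")[[1]]
      p1p <- strsplit(rule$p1prime, "")[[1]]
      for (i in seq_len(n - 1)) {
        ok1 <- rule$p1 == "*" || aa[i] %in% p1
        ok2 <- rule$p1prime == "*" || aa[i + 1] %in% p1p
        if (ok1 && ok2) {
          products <- c(products, list(subpeptide(substrate, 1L, i),
                                       subpeptide(substrate, i + 1L, n)))
          bonds <- c(bonds, list(tibble(bond = i, label = bond_label(substrate, i),
                                        mode = rule$mode, rule = rid)))
          fired <- c(fired, rid)
        }
      }
    } else if (rule$mode %in% c("dipeptidyl_carboxypeptidase",
                                "processive_carboxypeptidase")) {
      if (n < 3) { warning_flag <- TRUE; next }
      depths <- if (rule$mode == "dipeptidyl_carboxypeptidase") 2L
                else rule$trim_depths[[1]]
      for (k in depths) {
        if (k >= n) next
        i <- n - k
        products <- c(products, list(subpeptide(substrate, 1L, i)))
        if (rule$mode == "dipeptidyl_carboxypeptidase")
          products <- c(products, list(subpeptide(substrate, i + 1L, n)))
        bonds <- c(bonds, list(tibble(bond = i, label = bond_label(substrate, i),
                                      mode = rule$mode, rule = rid)))
        fired <- c(fired, rid)
      }
    }
  }
  prod_tbl <- if (length(products)) distinct(bind_rows(products)) else peptide("G")[0, ]
  bond_tbl <- if (length(bonds)) distinct(bind_rows(bonds)) else empty_bonds()
  bond_tbl <- arrange(bond_tbl, .data$bond)
  new_digest_result(substrate, prod_tbl, bond_tbl, unique(fired),
                    warning_flag = warning_flag)
}

empty_bonds <- function() {
  tibble(bond = integer(), label = character(), mode = character(),
         rule = character())
}

#' Complete tryptic digestion
#'
#' Cleaves after every Lys or Arg not followed by Pro (complete hydrolysis,
#' as used to prepare \eqn{^{18}}O-labeled internal standards by 48-h
#' digestion in heavy water).
#'
#' @param substrate A one-row peptide tibble.
#' @return A `digest_result`; products are the consecutive tryptic segments
#'   with terminal-modification inheritance.
#' @examples
#' trypsin_digest(abeta_substrates("Ac-ratAbeta1-16-amide"))
#' @export
trypsin_digest <- function(substrate) {
  stopifnot(nrow(substrate) == 1)
  n <- nchar(substrate$sequence)
  aa <- strsplit(substrate$sequence, "")[[1]]
  cuts <- which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  bond_tbl <- if (length(cuts)) {
    bind_rows(map(cuts, ~ tibble(bond = .x, label = bond_label(substrate, .x),
                                 mode = "trypsin", rule = "trypsin")))
  } else empty_bonds()
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  prods <- bind_rows(map2(starts, ends, ~ subpeptide(substrate, .x, .y)))
  new_digest_result(substrate, prods, bond_tbl,
                    rules_fired = rep("trypsin", length(cuts)))
}

#' Enumerate all contiguous candidate fragments
#'
#' All subpeptides (i..j) of a substrate with terminal-modification
#' inheritance, deduplicated; the candidate space searched during peak
#' matching.
#'
#' @param substrate A one-row peptide tibble.
#' @param min_length Minimum fragment length kept.
#' @return A peptide tibble with logical column `is_parent` marking the full
#'   interval.
#' @examples
#' nrow(enumerate_candidate_fragments(abeta_substrates("Abeta1-16")))  # 136
#' @export
enumerate_candidate_fragments <- function(substrate, min_length = 1L) {
  stopifnot(nrow(substrate) == 1)
  n <- nchar(substrate$sequence)
  idx <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$j - idx$i + 1L >= min_length & idx$i <= idx$j, ]
  out <- bind_rows(map2(idx$i, idx$j, ~ subpeptide(substrate, .x, .y)))
  out <- distinct(out)
  out$is_parent <- out$start == substrate$start & out$end == substrate$end &
    out$n_mod == substrate$n_mod & out$c_mod == substrate$c_mod
  out
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result>", format_peptide(x$substrate), "\n")
  if (x$inhibited) {
    cat("  inhibited: no products\n")
  } else if (nrow(x$bonds) == 0) {
    cat("  no bonds cleaved\n")
  } else {
    cat("  bonds cleaved:", paste(x$bonds$label, collapse = ", "), "\n")
    cat("  products:", paste(x$products$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.digest_result <- function(x, ...) {
  if (nrow(x$products) == 0) return(mutate(x$products, mz = numeric(0)))
  mutate(x$products, mz = mz_of(x$products))
}

#' @exportS3Method generics::glance
glance.digest_result <- function(x, ...) {
  tibble(
    substrate = format_peptide(x$substrate),
    n_products = nrow(x$products),
    n_bonds = nrow(x$bonds),
    inhibited = x$inhibited,
    modes = paste(unique(x$bonds$mode), collapse = ";")
  )
}
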