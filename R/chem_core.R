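# Peptide representation and exact-mass arithmetic.
#
# Peptides are rows of an ordinary tibble so sets of candidates, products and
# matches chain through dplyr verbs. The canonical columns are:
#   sequence (chr), n_mod ("free"/"acetyl"), c_mod ("free"/"amide"),
#   parent (chr or NA), start, end (1-based inclusive positions in the parent),
#   label (chr, display name).

MOD_N <- c("free", "acetyl")
MOD_C <- c("free", "amide")

#' Build a peptide tibble
#'
#' Constructs one row per peptide with the canonical columns used throughout
#' the package. All arguments are vectorized and recycled.
#'
#' @param sequence Residue string(s) in one-letter code.
#' @param n_mod N-terminal modification, `"free"` or `"acetyl"`.
#' @param c_mod C-terminal modification, `"free"` or `"amide"`.
#' @param parent Optional parent-chain identifier (e.g. `"human-Abeta"`).
#' @param start,end 1-based inclusive residue positions within the parent.
#'   Default to 1 and `nchar(sequence)`.
#' @param label Optional display name; defaults to the bracket notation.
#' @return A tibble with columns `label`, `sequence`, `n_mod`, `c_mod`,
#'   `parent`, `start`, `end`.
#' @examples
#' peptide("DAEFR", n_mod = "acetyl")
#' @export
peptide <- function(sequence, n_mod = "free", c_mod = "free",
                    parent = NA_character_, start = 1L,
                    end = nchar(sequence), label = NULL) {
  sequence <- toupper(str_trim(sequence))
  bad <- str_detect(sequence, paste0("[^", paste(rownames(RESIDUE_FORMULA), collapse = ""), "]"))
  if (any(bad)) {
    offending <- unique(unlist(str_split(gsub(paste0("[", paste(rownames(RESIDUE_FORMULA), collapse = ""), "]"), "", sequence[bad]), "")))
    abort(paste0("unknown residue letter(s): ", paste(offending, collapse = ", ")))
  }
  if (!all(n_mod %in% MOD_N)) abort("n_mod must be 'free' or 'acetyl'")
  if (!all(c_mod %in% MOD_C)) abort("c_mod must be 'free' or 'amide'")
  out <- tibble(
    sequence = sequence, n_mod = n_mod, c_mod = c_mod,
    parent = parent, start = as.integer(start), end = as.integer(end)
  )
  if (any(out$start < 1L | out$start > out$end))
    abort("require 1 <= start <= end")
  if (any(nchar(out$sequence) != out$end - out$start + 1L))
    abort("sequence length must equal end - start + 1")
  out$label <- label %||% format_peptide(out)
  out[, c("label", "sequence", "n_mod", "c_mod", "parent", "start", "end")]
}

#' Parse bracket peptide notation
#'
#' Reads strings like `"[Acetyl]-DAEFR"`, `"DAEFRHDSGYEVHHQK-[Amide]"` or a
#' plain residue string into a peptide tibble. Whitespace-tolerant; the
#' notation round-trips through [format_peptide()].
#'
#' @param text Character vector of annotated peptide strings.
#' @inheritParams peptide
#' @return A peptide tibble, one row per input string.
#' @examples
#' parse_peptide("[Acetyl]-DAEFR")
#' parse_peptide("DAEFRHDSGYEVHHQK-[Amide]")
#' @export
parse_peptide <- function(text, parent = NA_character_, start = 1L) {
  text <- gsub("[[:space:]]+", "", text)
  n_mod <- ifelse(grepl("^\\[acetyl\\]-?", text, ignore.case = TRUE), "acetyl", "free")
  c_mod <- ifelse(grepl("-?\\[amide\\]$", text, ignore.case = TRUE), "amide", "free")
  seqs <- gsub("^\\[acetyl\\]-?", "", text, ignore.case = TRUE)
  seqs <- gsub("-?\\[amide\\]$", "", seqs, ignore.case = TRUE)
  if (any(!nzchar(seqs))) abort("empty residue string")
  peptide(seqs, n_mod = n_mod, c_mod = c_mod, parent = parent,
          start = start, end = start + nchar(seqs) - 1L)
}

#' Format peptides in bracket notation
#'
#' @param peptides A peptide tibble.
#' @return Character vector like `"[Acetyl]-DAEFR"`.
#' @export
format_peptide <- function(peptides) {
  paste0(
    ifelse(peptides$n_mod == "acetyl", "[Acetyl]-", ""),
    peptides$sequence,
    ifelse(peptides$c_mod == "amide", "-[Amide]", "")
  )
}

#' Elemental composition of peptides
#'
#' Sums the dehydrated residue formulas, adds one water per chain, and applies
#' the terminal-modification deltas (+C2H2O for N-acetyl; +NH -O for C-amide).
#'
#' @param peptides A peptide tibble (or the output of [parse_peptide()]).
#' @return A tibble with one row per peptide and integer columns
#'   `C`, `H`, `N`, `O`, `S`.
#' @examples
#' composition_of(peptide("GG"))   # C4 H8 N2 O3
#' @export
composition_of <- function(peptides) {
  rows <- map(seq_len(nrow(peptides)), function(i) {
    aa <- strsplit(peptides$sequence[i], "")[[1]]
    v <- colSums(RESIDUE_FORMULA[aa, , drop = FALSE])
    v <- v + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + H2O
    v <- v + TERMINAL_DELTA[[peptides$n_mod[i]]]
    v + TERMINAL_DELTA[[peptides$c_mod[i]]]
  })
  comp <- as_tibble(do.call(rbind, rows))
  if (any(unlist(comp) < 0)) abort("negative element count in composition")
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition A tibble/data frame with element-count columns, or a
#'   named numeric vector, over elements in [ATOMIC_MASS].
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1))  # water, 18.010565
#' @export
monoisotopic_mass <- function(composition) {
  if (is.numeric(composition) && !is.null(names(composition)))
    composition <- as_tibble(as.list(composition))
  elems <- names(composition)
  unknown <- setdiff(elems, names(ATOMIC_MASS))
  if (length(unknown)) abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  if (nrow(composition) == 0) return(numeric(0))
  as.numeric(as.matrix(composition) %*% ATOMIC_MASS[elems])
}

#' Monoisotopic mass of peptides
#'
#' @inheritParams composition_of
#' @return Numeric vector, Da.
#' @export
peptide_mass <- function(peptides) {
  monoisotopic_mass(composition_of(peptides))
}

#' Singly or multiply protonated m/z of peptides
#'
#' Computes `(M + z * m_proton) / z` from the monoisotopic mass.
#'
#' @inheritParams composition_of
#' @param charge Positive integer charge state (MALDI work uses 1).
#' @return Numeric vector of m/z values.
#' @examples
#' mz_of(parse_peptide("DAEFRHDSGYEVHHQK"))  # 1954.87906
#' @export
mz_of <- function(peptides, charge = 1L) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    abort("charge must be a positive integer")
  (peptide_mass(peptides) + charge * PROTON_MASS) / charge
}

# parent chains of the built-in substrates
PARENT_CHAINS <- c(
  "human-Abeta" = "DAEFRHDSGYEVHHQK",
  "rat-Abeta"   = "DAEFGHDSGFEVRHQK"
)

#' Built-in amyloid-beta metal-binding-domain substrates
#'
#' The four synthetic analogs of the amyloid-beta metal-binding domain
#' (residues 1-16; human `DAEFRHDSGYEVHHQK`, rat `DAEFGHDSGFEVRHQK`) with
#' free, C-amidated, or N-acetylated + C-amidated termini. C-terminal
#' amidation mimics continuation of the chain in full-length amyloid-beta.
#'
#' @param name Optional substrate name (one of `"Abeta1-16"`,
#'   `"Abeta1-16-amide"`, `"Ac-Abeta1-16-amide"`, `"Ac-ratAbeta1-16-amide"`);
#'   when given, only that row is returned.
#' @return A peptide tibble with an extra `name` column.
#' @examples
#' abeta_substrates()
#' mz_of(abeta_substrates("Ac-Abeta1-16-amide"))
#' @export
abeta_substrates <- function(name = NULL) {
  reg <- bind_rows(
    peptide(PARENT_CHAINS[["human-Abeta"]], "free",   "free",  "human-Abeta"),
    peptide(PARENT_CHAINS[["human-Abeta"]], "free",   "amide", "human-Abeta"),
    peptide(PARENT_CHAINS[["human-Abeta"]], "acetyl", "amide", "human-Abeta"),
    peptide(PARENT_CHAINS[["rat-Abeta"]],   "acetyl", "amide", "rat-Abeta")
  )
  reg <- mutate(reg, name = c("Abeta1-16", "Abeta1-16-amide",
                              "Ac-Abeta1-16-amide", "Ac-ratAbeta1-16-amide"),
                .before = 1)
  if (is.null(name)) return(reg)
  hit <- reg[reg$name == name, ]
  if (nrow(hit) == 0)
    abort(paste0("unknown substrate '", name, "'; see abeta_substrates()"))
  hit
}

#' Read parent chains from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a named
#' character vector usable as the `parent` registry for [subpeptide()].
#'
#' @param path Path to an amino-acid FASTA file.
#' @return Named character vector of sequences.
#' @export
read_parent_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort("read_parent_fasta() requires the Biostrings package")
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Extract a subpeptide with terminal-modification inheritance
#'
#' Returns the fragment `[from, to]` of a substrate. An N-terminal fragment
#' keeps the substrate's N-modification and gets a free carboxyl terminus;
#' a C-terminal fragment keeps the substrate's C-modification and gets a free
#' amino terminus; internal fragments are free/free.
#'
#' @param substrate A one-row peptide tibble.
#' @param from,to 1-based positions within the substrate (local coordinates).
#' @return A one-row peptide tibble with parent coordinates propagated.
#' @export
subpeptide <- function(substrate, from, to) {
  stopifnot(nrow(substrate) == 1)
  n <- nchar(substrate$sequence)
  if (from < 1 || to > n || from > to) abort("subpeptide interval out of range")
  peptide(
    substr(substrate$sequence, from, to),
    n_mod = if (from == 1L) substrate$n_mod else "free",
    c_mod = if (to == n) substrate$c_mod else "free",
    parent = substrate$parent,
    start = substrate$start + from - 1L,
    end = substrate$start + to - 1L
  )
}

# "Arg5-His6"-style label for the bond between local positions i and i+1,
# numbered in parent coordinates
bond_label <- function(substrate, i) {
  aa <- strsplit(substrate$sequence, "")[[1]]
  pos <- substrate$start + i - 1L
  paste0(AA3[aa[i]], pos, "-", AA3[aa[i + 1L]], pos + 1L)
}
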