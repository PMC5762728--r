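# Physical constants. Atomic monoisotopic masses and isotopic abundances are
# fixed (IUPAC 2013 representative values) so results are identical across
# platforms; all m/z arithmetic in the package flows through these tables.

#' Monoisotopic atomic masses (Da)
#'
#' Named vector of the monoisotopic masses of the elements occurring in
#' unmodified peptides (C, H, N, O, S).
#'
#' @format Named numeric vector.
#' @export
ATOMIC_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass of the proton (Da)
#' @export
PROTON_MASS <- 1.00727646

# per-element isotope tables: mass (Da) and natural abundance (fraction)
ISOTOPE_TABLE <- list(
  H = list(mass = c(1.0078250319, 2.0141017781),
           abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.0033548351),
           abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.0030740052, 15.0001088989),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.9991317565, 17.9991596129),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207069, 32.9714589, 33.967867, 35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 1e-04))
)

# 18O - 16O mass difference, used by the labeling model
O18_SHIFT <- ISOTOPE_TABLE$O$mass[3] - ISOTOPE_TABLE$O$mass[1]

# Dehydrated (residue) elemental compositions of the 20 standard amino acids,
# columns C, H, N, O, S.
RESIDUE_FORMULA <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Terminal-modification deltas (element-count changes).
# acetyl: +C2H2O on the free N-terminus; amide: -OH +NH2 at the C-terminus.
TERMINAL_DELTA <- list(
  free   = c(C = 0, H = 0, N = 0, O = 0, S = 0),
  acetyl = c(C = 2, H = 2, N = 0, O = 1, S = 0),
  amide  = c(C = 0, H = 1, N = 1, O = -1, S = 0)
)

AA3 <- c(
  G = "Gly", A = "Ala", S = "Ser", P = "Pro", V = "Val", T = "Thr", C = "Cys",
  L = "Leu", I = "Ile", N = "Asn", D = "Asp", Q = "Gln", K = "Lys", E = "Glu",
  M = "Met", H = "His", F = "Phe", R = "Arg", Y = "Tyr", W = "Trp"
)
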