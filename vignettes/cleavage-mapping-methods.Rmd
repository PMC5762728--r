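---
title: "Methods: cleavage-site mapping, 18O quantitation, and trajectory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleavage-site mapping, 18O quantitation, and trajectory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acecleave)
library(dplyr)
```

This vignette documents the models and numerical choices behind
`acecleave`: how masses and isotope envelopes are computed, how the
digestion rules and the cleavage-map inference are defined, what the
synthetic-data generator does and does not emulate, how the
¹⁸O-internal-standard quantitation works, and the conventions of the
trajectory statistics.

## Mass arithmetic

All masses are monoisotopic. Atomic masses are fixed constants
(`ATOMIC_MASS`: H 1.0078250319, C 12, N 14.0030740052, O 15.9949146221,
S 31.97207069; proton 1.00727646), so results are identical across
platforms. A peptide's composition is the sum of its dehydrated residue
formulas plus one water, adjusted by the terminal modifications:
N-acetylation adds C₂H₂O (+42.010565 Da), C-amidation replaces a hydroxyl
with an amine (+NH−O, −0.984016 Da). Fragments inherit modifications from
their substrate: an N-terminal fragment keeps the substrate's N-terminal
state and acquires a free carboxyl; a C-terminal fragment keeps the
C-terminal state and acquires a free amine; internal fragments are
free/free. Only singly protonated ions are considered — MALDI spectra of
2 kDa peptides are dominated by [M+H]⁺ — and only the twenty standard
residues with the two terminal groups are supported.

Two identities are useful as self-checks and are enforced in the test
suite: amidation shifts any [M+H]⁺ by −0.98402 Da, and for every bond the
complementary fragments satisfy
[M+H]⁺(1..k) + [M+H]⁺(k+1..n) − [M+H]⁺(parent) = 19.01784 Da
(one water plus one proton).

## Isotope envelopes and the ¹⁸O labeling model

`isotope_pattern()` convolves per-element isotope distributions (fixed
IUPAC 2013 representative abundances, binary exponentiation over atom
counts). Peaks closer than 0.2 Da are merged into abundance-weighted
centroids: a reflector TOF resolves the ~1.003 Da isotopomer spacing of a
2 kDa peptide but not isotopic fine structure, so the 0.2 Da grid mirrors
what the instrument reports as centroids. The default truncation threshold
of 10⁻⁴ relative abundance leaves roughly eight visible isotopomers for a
2 kDa peptide, matching the visible extent of a MALDI envelope. Envelopes
are exact before truncation (abundances sum to 1), and on compositions of
ten or fewer atoms the implementation is tested against exhaustive
isotopologue enumeration.

Internal standards are prepared, experimentally, by completely digesting a
known amount of the substrate with trypsin in heavy water, which plants
water-derived oxygen in the product's C-terminal carboxyl.
`labeled_pattern()` models the standard as the composition minus
`n_sites` oxygens, convolved with `n_sites` independent label sites: each
site is ¹⁸O (+2.00425 Da) with probability `p_inc` and a natural-abundance
oxygen otherwise (the unexchanged fraction comes from ordinary water).
With `p_inc = 0` this reduces exactly to the natural envelope; with
`p_inc = 0.95` and two sites the site states carry binomial weights
(0.0025, 0.095, 0.9025) at shifts (0, +2.00425, +4.00849 Da). The number
of exchangeable sites is configurable per standard (0–2) rather than fixed
at two: for a C-amidated analyte the labeling chemistry of the tryptic
route is not fully determined, so the model must not hard-code the site
count. Defaults are `n_sites = 2`, `p_inc = 0.95` (the nominal enrichment
of commercial heavy water, 95–98 %).

## The digestion rule engine

`digest_with_rules()` is a generic specificity engine; the shipped
`ace_rules()` preset encodes the *observed* behavior of the two ACE
domains on the metal-binding-domain substrates, not a mechanistic model:

| enzyme | condition | mode | bonds |
|---|---|---|---|
| N-ACE | C-amidated substrate | endopeptidase, Arg↓His | Arg5-His6 (human), Arg13-His14 (rat) |
| N-ACE | free carboxyl | dipeptidyl carboxypeptidase | His14-Gln15 |
| C-ACE | free carboxyl | processive carboxypeptidase, depths 2–3 | His13-His14, His14-Gln15 |
| C-ACE | amidated rat sequence | processive carboxypeptidase, depths 1–3 | Arg13-His14, His14-Gln15, Gln15-Lys16 |

All activities are abolished by lisinopril. Carboxypeptidase rules carry an
explicit set of trim depths rather than a single maximum: on the free-acid
human domain only the di- and tripeptide removals were observed (no
depth-1 trim), while the amidated rat domain shows all three depths, and an
engine that always expanded `1..max_trim` could not express that
difference. Hydrolysis is limited: products are not re-digested within one
call (iterative digestion is available by feeding products back).
Endopeptidase cleavage emits both complementary fragments; carboxypeptidase
modes emit the N-anchored truncation (plus the released dipeptide in the
dipeptidyl mode). `trypsin_digest()` implements complete cleavage after
Lys/Arg except before Pro, as used for standard preparation.

## Matching and cleavage-map inference

`match_peaks()` assigns each observed centroid to every candidate fragment
whose calculated [M+H]⁺ lies within the tolerance, nearest first, and
never silently picks among ambiguous assignments. The default tolerance of
±0.3 Da covers the largest calculated-vs-observed discrepancy in the
externally calibrated spectra (~0.2 Da) with margin, while the nearest
alternative fragment assignments for these substrates sit more than
0.9 Da away. Matching is monoisotopic: calculated masses are envelope
heads, so a peak with a substantial neighbour ~1.003 Da below it is an
isotopomer of a larger envelope and is excluded from assignment. This is
deliberately *not* general deisotoping — it is the minimal condition for a
centroid to be a plausible monoisotopic peak.

`infer_cleavage_map()` converts matched fragments into bonds: a fragment
spanning local positions (i..j) implies the bond (i−1)–i when i > 1 and
j–(j+1) when j < n. A bond corroborated from both sides by a complementary
pair is accepted. A bond supported from one side only is accepted when the
missing complement's [M+H]⁺ falls below the matrix-suppression cutoff
(default m/z 500) — the fragment *could not* have been observed — and
flagged `tentative` otherwise. The cutoff sits between the unobservable
Gln15-Lys16 dipeptide (~275) and the observed acetylated 1–5 product
(679.3), comfortably clear of both.

`classify_mode()` reads the enzyme mode off the product geometry: a single
N-anchored truncation of exactly two residues is the canonical dipeptidyl
carboxypeptidase signature; truncations at two or more depths within the
last three residues indicate processive carboxypeptidase action; a single
corroborated cut deeper than two residues from the C-terminus — including
a lone specific cut releasing a C-terminal tripeptide, which a processive
trimmer would not produce without the shallower products — is called an
endopeptidase; everything else is ambiguous. The tripeptide clause matters
for the rat substrate, where the specific Arg13-His14 cut by N-ACE sits
three residues from the C-terminus and is an endopeptidase event by
specificity even though its product geometry grazes the carboxypeptidase
region.

`validate_with_inhibitor()` checks a control spectrum acquired with the
inhibitor: the map validates iff no product peak appears above an intensity
floor, by default three times the median control intensity (the published
work states no explicit floor; the median-based default assumes peak lists
dominated by low-level matrix peaks and is configurable).

## The synthetic-data generator

`simulate_timecourse()` treats each cleavable bond as an independent
first-order channel: the substrate decays with the total rate and each
bond's complementary product pair accrues in proportion to its rate share
(closed form, chain count conserved). Rate constants are free parameters —
the source experiments report incubation windows (10–130 min) and enzyme
concentrations but no rates — with a default of 0.05 min⁻¹, which converts
most of the substrate over a 40–60 min window, as observed.

`render_spectrum()` emulates a positive-ion reflector MALDI-TOF centroid
list: each species contributes its (optionally labeled) envelope at [M+H]⁺
scaled by concentration × response; every peak is shifted by a calibration
offset (drawn once per spectrum from N(0, 0.15 Da), emulating the ≤0.2 Da
external-calibration discrepancies, or fixed by the caller); intensities
are multiplied by lognormal noise with 5 % CV by default; peaks within
0.2 Da are summed; peaks below the suppression cutoff or outside the
acquisition window are removed. Spectra are centroid-only — no peak-shape,
resolution, or detector-saturation modeling — and with a fixed seed they
are bit-reproducible.

What passing tests on this generator do *not* show about real data: real
MALDI spectra contain matrix adducts, alkali adducts and unrelated
contaminants the generator never emits, intensity responses differ between
peptides (the generator's per-species response is flat by default), and
real calibration errors can drift with m/z rather than being a constant
offset. The closed-loop tests therefore establish the *internal
consistency* of the chain, not instrument-level robustness.

## Quantitation

Because the standard's enrichment is partial (95 %), its envelope leaks
intensity into the analyte's +2 Da region; a simple first-peak height
ratio is biased. `quantify_analyte()` therefore deconvolves: it predicts
both envelopes, pools them with the observed region onto a common 0.2 Da
grid, and solves `observed ≈ cA·analyte + cS·standard` by nonnegative
least squares (`pracma::lsqnonneg`; nonnegativity because concentrations
are physical). The analyte concentration is `(cA/cS) ·
standard_conc`. Before fitting, the region is recalibrated by the
intensity-weighted median shift of observed peaks to their nearest
predicted position, which absorbs the drawn calibration offset; without
this step an offset approaching the grid width could misalign the design.
Identical (degenerate) predicted patterns raise an error rather than an
estimate. The classical alternative — a least-squares line through
peak-height ratios at known loads with an inverse predictor
(`calibration_line()`) — is provided because the original method was
stated in both forms; the deconvolution is the package default. Noiseless
round trips through the generator are exact to 10⁻⁶ relative for
`p_inc` in {0.90, 0.95, 1.0} and 1–2 sites, and under the stated noise
model (5 % CV, drawn offsets, ratios 0.25–4) the median absolute relative
error over 100 seeded replicates is ~3 %, within the 10 % method error
reported for the experimental procedure.

## Trajectory statistics

The trajectory module validates, by construction, the statistics used to
rationalize the enzyme's specificity from molecular-dynamics simulations
of tetrapeptide–enzyme complexes.

* **Superposition / RMSD.** `superpose_kabsch()` computes the
  least-squares rigid superposition by SVD of the covariance matrix,
  restricted to proper rotations (the smallest singular vector's sign is
  flipped when the raw solution is a reflection); collinear or
  sub-3-atom selections are rejected. `rmsd_series()` reports per-frame
  RMSD against frame 1 (the initial structure) after superposition on the
  selection. Optimality is tested against a dense random-rotation grid.
* **Hydrogen bonds.** A contact is satisfied in a frame iff the
  donor–acceptor distance is ≤3.5 Å *and* the hydrogen–donor–acceptor
  angle is ≤30° — the convention of the common MD analysis utilities —
  with boundary values counting as satisfied (closed cutoffs, a documented
  convention rather than a numerical accident). Populations are fractions
  of frames; concatenating trajectories gives exactly the frame-weighted
  mean.
* **Dihedrals.** φ(i) = C(i−1)–N(i)–CA(i)–C(i), ψ(i) =
  N(i)–CA(i)–C(i)–N(i+1), signed per the IUPAC convention in (−180°, 180°],
  verified against an independent torsion implementation (`bio3d`);
  `circular_stats()` supplies the circular mean and variance appropriate
  for angle series.
* **Zinc coordination.** Tetrahedral coordination is `retained` in a frame
  iff all four Zn–ligand distances lie in [1.8, 2.6] Å and the mean
  absolute deviation of the six ligand–Zn–ligand angles from 109.47° is
  ≤15°; both windows are configurable.
* **Synthetic trajectories.** `synth_trajectory()` replicates a template
  frame, geometrically enforces each scheduled contact (acceptor on the
  donor–hydrogen axis at 2.9 Å when on, 6 Å when off), and adds Gaussian
  jitter — so every population statistic can be checked against its known
  construction. Coordinates are Ångström throughout; the XYZ reader
  converts nm on request.

The production simulations behind the published analysis (100 ns
trajectories of four tetrapeptide complexes) are not distributed, so no
numeric contact populations from them are asserted anywhere in the
package; the module is validated on synthetic trajectories only, and
readers for multi-model PDB and XYZ are provided for users with their own
data.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic or
published-table inputs: 100 quantitation replicates, trajectories of
100–1000 frames with 9–65 atoms, and rotation grids of 2000–3000 samples —
sizes chosen so the full chain, including every closed-loop condition,
completes in about a minute while keeping Monte-Carlo assertions (median
errors, retention rates) far from their thresholds. Every stochastic stage
takes an explicit seed; pipeline runs with the same scenario seed are
byte-identical.

## Known limitations

* Singly charged monoisotopic matching only; no average masses, ESI charge
  states, or side-chain modifications.
* The digestion engine is a specificity *rule* engine: it reproduces
  observed product sets and modes but knows nothing of kinetic competition
  between sites, pH, or buffer composition (buffers are metadata).
* Quantitation assumes the analyte's envelope is uncontaminated by
  co-eluting species other than its own standard; no deisotoping of
  unknown mixtures is attempted.
* The generator's noise model (multiplicative lognormal, flat response) is
  deliberately simple; see the generator section for what that implies
  about real-data claims.
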