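# acecleave

Cleavage-site mapping of amyloid-β peptides by limited proteolysis and
MALDI-TOF peptide mass fingerprinting.

## The problem

The two catalytic domains of somatic angiotensin-converting enzyme (N-ACE
and C-ACE) hydrolyze the amyloid-β metal-binding domain — residues 1–16,
`DAEFRHDSGYEVHHQK` in human, `DAEFGHDSGFEVRHQK` in rat — in ways that depend
critically on the state of the peptide termini. With a free carboxyl
terminus, both domains behave as carboxypeptidases, trimming C-terminal di-
and tripeptides. When the C-terminus is amidated (mimicking continuation of
the chain in full-length Aβ), N-ACE switches to an arginine-specific
**endopeptidase**, cleaving the Arg↓His bond (Arg5-His6 in human,
Arg13-His14 in rat), while C-ACE is blocked entirely.

`acecleave` implements the full computational chain behind this kind of
experiment, for anyone mapping protease specificity on short peptides by
MALDI-TOF mass fingerprinting:

* exact monoisotopic mass arithmetic with N-acetyl (+42.01056 Da) and
  C-amide (−0.98402 Da) terminal modifications,
* isotope-envelope prediction by elemental convolution, including a
  binomial ¹⁸O-labeling model for tryptically prepared internal standards,
* a rule-based limited-proteolysis engine (endopeptidase, dipeptidyl
  carboxypeptidase, processive carboxypeptidase modes; inhibitor handling),
* peak matching against all contiguous candidate fragments, inference of
  the cleaved-bond set from fragment boundaries (with matrix-suppression
  reasoning for unobservable complements), enzyme-mode classification, and
  inhibitor-control validation,
* absolute quantitation of a digestion product by nonnegative
  least-squares deconvolution of the overlapping analyte / ¹⁸O-standard
  envelopes, `c_analyte = (c_A/c_S) · c_standard`, plus the classical
  calibration-line (peak-height ratio vs load) alternative,
* a synthetic-data generator (first-order digestion kinetics, MALDI-like
  centroid spectra with calibration offset, lognormal intensity noise and
  low-mass matrix suppression) so the whole chain is testable without an
  instrument,
* molecular-dynamics trajectory statistics used to rationalize the
  specificity: Kabsch superposition and RMSD series, geometric
  hydrogen-bond contact populations, backbone φ/ψ dihedral series, and
  tetrahedral zinc-coordination checks.

Everything takes and returns tibbles, chains with the pipe, and exposes
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Map the cleavage sites of the rat metal-binding-domain analog digested by
C-ACE, starting from an observed centroid peak list:

```r
library(acecleave)
library(dplyr)

peaks <- read_spectrum_csv(system.file("extdata",
  "observed_peaks_rat_cace.csv", package = "acecleave"))
sub <- abeta_substrates("Ac-ratAbeta1-16-amide")
matches <- match_peaks(peaks, enumerate_candidate_fragments(sub), tol = 0.3)
matches |> select(peak_mz, label, calc_mz, mass_error)
#> # A tibble: 4 × 4
#>   peak_mz label                             calc_mz mass_error
#>     <dbl> <chr>                               <dbl>      <dbl>
#> 1   1508. [Acetyl]-DAEFGHDSGFEVR              1508.    -0.145
#> 2   1645. [Acetyl]-DAEFGHDSGFEVRH             1645.     0.196
#> 3   1773. [Acetyl]-DAEFGHDSGFEVRHQ            1773.     0.138
#> 4   1900. [Acetyl]-DAEFGHDSGFEVRHQK-[Amide]   1900.     0.0268

infer_cleavage_map(matches, sub)
#> <cleavage_map> [Acetyl]-DAEFGHDSGFEVRHQK-[Amide]
#>   mode: processive_carboxypeptidase
#>   bonds: Arg13-His14 (accepted), His14-Gln15 (accepted), Gln15-Lys16 (accepted)
#>   products: [Acetyl]-DAEFGHDSGFEVR, [Acetyl]-DAEFGHDSGFEVRH, [Acetyl]-DAEFGHDSGFEVRHQ
```

Each observed peak is assigned to a candidate fragment within the ±0.3 Da
matching tolerance; the three N-anchored truncations imply the three
C-terminal bonds, and the trimming depths (1–3 residues) classify C-ACE as
a processive carboxypeptidase on this substrate.

The same machinery runs as a closed simulation loop — digestion rules,
first-order kinetics, spectrum rendering, matching, inference, inhibitor
control, and ¹⁸O-standard quantitation:

```r
rep <- run_pipeline(scenario("Ac-Abeta1-16-amide", "N-ACE",
  rates = c(`5` = 0.05), times = c(10, 20, 40), c0 = 20,
  params = spectrum_params(noise_cv = 0.05), seed = 17))
rep
#> <pipeline_report> [Acetyl]-DAEFRHDSGYEVHHQK-[Amide] + N-ACE
#> <cleavage_map> [Acetyl]-DAEFRHDSGYEVHHQK-[Amide]
#>   mode: endopeptidase
#>   bonds: Arg5-His6 (accepted)
#>   products: [Acetyl]-DAEFR, HDSGYEVHHQK-[Amide]
#>   inhibitor control: validated
#> <quant_estimate> [Acetyl]-DAEFR: 17.680 uM (ratio 1.7680 vs 10 uM standard, residual 192)
```

The simulated 40-min digestion at 0.05 min⁻¹ leaves
20·(1−e⁻²) ≈ 17.3 µM of product; the envelope deconvolution against a
10 µM ¹⁸O standard recovers 17.68 µM from the 5 %-noise spectrum.

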