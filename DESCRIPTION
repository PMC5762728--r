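Package: acecleave
Title: Cleavage-Site Mapping of Amyloid-Beta Peptides by Limited
    Proteolysis and MALDI-TOF Mass Fingerprinting
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping protease cleavage sites in short peptide
    substrates by MALDI-TOF peptide mass fingerprinting, built around the
    limited proteolysis of the amyloid-beta metal-binding domain by the two
    catalytic domains of angiotensin-converting enzyme (ACE). Provides
    exact monoisotopic mass arithmetic with N-acetyl and C-amide terminal
    modifications, isotope-envelope prediction by elemental convolution
    including an 18O-labeling model for internal standards, a rule-based
    in-silico digestion engine covering endopeptidase and carboxypeptidase
    modes, peak matching and cleavage-map/mode inference with inhibitor
    control validation, absolute quantitation by nonnegative envelope
    deconvolution against 18O-labeled standards, a synthetic-data generator
    for MALDI-like centroid spectra and first-order digestion time courses,
    and molecular-dynamics trajectory statistics (Kabsch RMSD, hydrogen-bond
    contact populations, backbone dihedral series, zinc-coordination
    geometry).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
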