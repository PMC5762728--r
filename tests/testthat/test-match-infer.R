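# Peak matching, cleavage-map inference, mode classification, and
# inhibitor-control validation.

test_that("published observed m/z values match their fragments within tolerance", {
  sub <- abeta_substrates("Abeta1-16")
  cand <- enumerate_candidate_fragments(sub)
  m <- match_peaks(spectrum_from_peaks(1698.6, 100), cand, tol = 0.3)
  hit <- m[m$label == "DAEFRHDSGYEVHH", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mass_error, 1698.6 - 1698.72552, tolerance = 1e-4)

  rat <- abeta_substrates("Ac-ratAbeta1-16-amide")
  m2 <- match_peaks(spectrum_from_peaks(1507.5, 50),
                    enumerate_candidate_fragments(rat), tol = 0.3)
  expect_true("[Acetyl]-DAEFGHDSGFEVR" %in% m2$label)

  # tolerance monotonicity: tighter windows only lose matches
  m3 <- match_peaks(spectrum_from_peaks(1698.6, 100), cand, tol = 0.05)
  expect_equal(nrow(m3), 0)
  for (tol in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
    n_prev <- nrow(match_peaks(spectrum_from_peaks(1698.6, 100), cand,
                               tol = tol / 2))
    n_cur <- nrow(match_peaks(spectrum_from_peaks(1698.6, 100), cand, tol = tol))
    expect_lte(n_prev, n_cur)
  }

  expect_error(match_peaks(spectrum_from_peaks(1, 1), cand, tol = 0), "tol")
  expect_equal(nrow(match_peaks(spectrum_from_peaks(1698.6, 1), cand[0, ])), 0)
})

test_that("multi-candidate peaks report all candidates ranked by error", {
  sub <- abeta_substrates("Abeta1-16")
  cand <- enumerate_candidate_fragments(sub)
  # a wide tolerance makes several candidates eligible
  m <- match_peaks(spectrum_from_peaks(1698.6, 100), cand, tol = 60)
  expect_gt(nrow(m), 1)
  expect_equal(m$rank, seq_len(nrow(m)))
  expect_false(is.unsorted(abs(m$mass_error)))
  expect_equal(m$label[1], "DAEFRHDSGYEVHH")
})

test_that("cleavage maps from published peak lists reproduce the reported digestion table", {
  for (case in EXPECTED_MAPS) {
    map <- infer_from_published_peaks(case)
    expect_setequal(map$bonds$bond, case$bonds)
    expect_equal(map$mode_call, case$mode,
                 label = paste(case$substrate, case$enzyme))
    got <- unique(map$products[, c("start", "end")])
    want <- do.call(rbind, case$products)
    expect_equal(nrow(got), length(case$products))
    if (length(case$products))
      expect_setequal(paste(got$start, got$end),
                      paste(want[, 1], want[, 2]))
  }
})

test_that("suppressed complements are accepted, observable missing ones tentative", {
  # 1-14 alone: the QK complement sits at m/z 275, inside the suppression
  # region, so the bond is accepted
  sub <- abeta_substrates("Abeta1-16")
  m <- match_peaks(spectrum_from_peaks(c(1954.8, 1698.6), c(100, 40)),
                   enumerate_candidate_fragments(sub))
  map <- infer_cleavage_map(m, sub)
  expect_equal(map$bonds$status, "accepted")

  # an internal-looking single fragment whose complement would be observable:
  # 6-16 of the amidated substrate (complement 1-5 at m/z 637 > 500)
  amide <- abeta_substrates("Abeta1-16-amide")
  m2 <- match_peaks(spectrum_from_peaks(1335.6, 40),
                    enumerate_candidate_fragments(amide))
  map2 <- infer_cleavage_map(m2, amide)
  expect_equal(map2$bonds$status, "tentative")
  expect_equal(map2$bonds$bond, 5L)
  expect_equal(map2$mode_call, "endopeptidase")
  # with a harsher suppression cutoff the complement is excused
  map3 <- infer_cleavage_map(m2, amide, suppression_cutoff = 700)
  expect_equal(map3$bonds$status, "accepted")

  # no non-parent matches: empty map
  m4 <- match_peaks(spectrum_from_peaks(1954.8, 100),
                    enumerate_candidate_fragments(sub))
  map4 <- infer_cleavage_map(m4, sub)
  expect_equal(nrow(map4$bonds), 0)
  expect_equal(map4$mode_call, "none")
})

test_that("matches from a different substrate are rejected", {
  sub <- abeta_substrates("Abeta1-16")
  rat <- abeta_substrates("Ac-ratAbeta1-16-amide")
  m <- match_peaks(spectrum_from_peaks(1507.5, 50),
                   enumerate_candidate_fragments(rat))
  expect_error(infer_cleavage_map(m, sub), "outside this substrate")
})

test_that("mode classification follows the product geometry", {
  sub <- abeta_substrates("Abeta1-16")
  fake_map <- function(bonds, substrate = sub) {
    structure(list(substrate = substrate,
                   bonds = tibble::tibble(bond = as.integer(bonds)),
                   products = tibble::tibble(), mode_call = NA,
                   control_validated = NA),
              class = "cleavage_map")
  }
  expect_equal(classify_mode(fake_map(14)), "dipeptidyl_carboxypeptidase")
  expect_equal(classify_mode(fake_map(c(13, 14))), "processive_carboxypeptidase")
  expect_equal(classify_mode(fake_map(5)), "endopeptidase")
  expect_equal(classify_mode(fake_map(13)), "endopeptidase")
  expect_equal(classify_mode(fake_map(15)), "ambiguous")     # single depth-1 trim
  expect_equal(classify_mode(fake_map(c(5, 14))), "ambiguous")
  expect_equal(classify_mode(fake_map(integer())), "none")
})

test_that("inhibitor controls validate or flag the map", {
  sub <- abeta_substrates("Ac-Abeta1-16-amide")
  m <- match_peaks(spectrum_from_peaks(c(1995.8, 1335.6, 679.3),
                                       c(100, 40, 30)),
                   enumerate_candidate_fragments(sub))
  map <- infer_cleavage_map(m, sub)

  # control with only the parent peak: validated
  ctrl <- spectrum_from_peaks(1995.9, 100)
  expect_true(validate_with_inhibitor(map, ctrl)$control_validated)

  # control still showing the 1335.6 product above the noise floor
  # (a handful of low-level matrix peaks set the median): not validated
  ctrl2 <- spectrum_from_peaks(c(520.1, 611.4, 702.8, 845.2, 1101.7,
                                 1995.9, 1335.6),
                               c(2, 3, 2.5, 2, 3, 100, 60))
  expect_false(validate_with_inhibitor(map, ctrl2)$control_validated)

  # a trace below the intensity floor does not invalidate
  ctrl3 <- spectrum_from_peaks(c(1995.9, 1335.6), c(100, 1))
  expect_true(validate_with_inhibitor(map, ctrl3, floor = 50)$control_validated)

  # empty control validates vacuously
  empty <- spectrum_from_peaks(numeric(0), numeric(0))
  expect_true(validate_with_inhibitor(map, empty)$control_validated)
})

test_that("tidy and glance summarize cleavage maps", {
  case <- EXPECTED_MAPS[[8]]
  map <- infer_from_published_peaks(case)
  expect_equal(tidy(map)$bond, c(13L, 14L, 15L))
  g <- glance(map)
  expect_equal(g$mode_call, "processive_carboxypeptidase")
  expect_equal(g$n_bonds, 3L)
})
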