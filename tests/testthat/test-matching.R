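test_that("MS1 matching applies the ppm and RT windows", {
  target <- 724.3487
  feats <- tibble::tibble(
    mz = c(target, target * (1 + 25e-6), target * (1 + 15e-6), target),
    rt = c(27.0, 27.0, 27.3, 29.0),
    area = c(100, 100, 500, 100)
  )
  hits <- match_ms1(feats, target, 27.0)
  # exact match first (0 ppm), 15 ppm feature second, +25 ppm and RT-out excluded
  expect_equal(nrow(hits), 2)
  expect_equal(hits$ppm_error[1], 0)
  expect_equal(hits$ppm_error[2], 15, tolerance = 1e-6)

  # tie on ppm broken by larger area
  tie <- tibble::tibble(mz = rep(target, 2), rt = c(27, 27), area = c(1, 10))
  expect_equal(match_ms1(tie, target, 27)$area[1], 10)

  expect_equal(nrow(match_ms1(feats[0, ], target, 27)), 0)
  expect_error(match_ms1(feats, target, 27, ppm_tol = 0), "positive")
})

test_that("MS1 matching is monotone in its tolerances", {
  set.seed(42)
  target <- 800
  feats <- tibble::tibble(
    mz = target * (1 + rnorm(200, 0, 30) / 1e6),
    rt = 20 + rnorm(200, 0, 1.5),
    area = runif(200, 1, 100)
  )
  counts <- sapply(c(5, 10, 20, 40), function(tol)
    nrow(match_ms1(feats, target, 20, ppm_tol = tol)))
  expect_true(all(diff(counts) >= 0))
  counts_rt <- sapply(c(0.25, 0.5, 1, 2), function(rtt)
    nrow(match_ms1(feats, target, 20, rt_tol_min = rtt)))
  expect_true(all(diff(counts_rt) >= 0))
})

make_test_trace <- function(sn, expected_rt = 10, baseline_sd = 50,
                            seed = 42) {
  set.seed(seed)
  grid <- seq(0, 20, by = 0.02)
  base <- rnorm(length(grid), 500, baseline_sd)
  scale <- mad(base[grid <= 8], constant = 1.4826)
  peak <- sn * scale * exp(-(grid - expected_rt)^2 / (2 * 0.1^2))
  tibble::tibble(time = grid, intensity = pmax(base + peak, 0),
                 expected_rt = expected_rt)
}

test_that("MRM validation separates planted peaks from noise at S/N 2.5", {
  # flat noise-only trace
  flat <- make_test_trace(sn = 0)
  v0 <- validate_mrm(flat, c(9.9, 10.1), c(0, 8))
  expect_false(v0$validated)

  # planted 10-sigma peak at the expected RT
  v10 <- validate_mrm(make_test_trace(sn = 10), c(9.9, 10.1), c(0, 8))
  expect_true(v10$validated)
  expect_equal(v10$sn, 10, tolerance = 0.3)
  expect_equal(v10$apex_rt, 10, tolerance = 0.1)

  # planted 2-sigma peak stays below the 2.5 threshold
  v2 <- validate_mrm(make_test_trace(sn = 2), c(9.9, 10.1), c(0, 8))
  expect_false(v2$validated)

  # a strong peak at the wrong RT fails the co-elution gate
  off <- make_test_trace(sn = 10, expected_rt = 10)
  off$expected_rt <- 12
  voff <- validate_mrm(off, c(9.9, 10.1), c(0, 8))
  expect_false(voff$validated)
})

test_that("MRM validation guards windows and zero noise", {
  tr <- tibble::tibble(time = seq(0, 10, 0.1), intensity = 0,
                       expected_rt = 5)
  tr$intensity[tr$time > 4.8 & tr$time < 5.2] <- 100
  expect_warning(v <- validate_mrm(tr, c(4.5, 5.5), c(0, 4)), "Inf")
  expect_true(v$zero_noise)
  expect_true(is.infinite(v$sn))
  expect_error(validate_mrm(tr, c(4, 6), c(5, 8)), "disjoint")
  expect_error(validate_mrm(tr, c(-1, 2), c(5, 8)), "span")
})

test_that("MS/MS daughter matching counts peaks within tolerance", {
  frags <- fragment_ions("QFFGLM")
  sp <- tibble::tibble(mz = c(463.20, 900.1), intensity = c(10, 5))
  m <- match_msms(sp, frags)
  expect_gte(m$n_matched, 1)
  expect_true(m$detected)

  expect_equal(match_msms(sp[0, ], frags)$n_matched, 0)
  decoy <- tibble::tibble(mz = frags$mz + 5, intensity = 1)
  expect_false(match_msms(decoy, frags)$detected)
})

test_that("standard-curve quantification inverts the calibration line", {
  curve <- fit_standard_curve(
    tibble::tibble(conc_nM = c(1, 5, 10, 50), area = 2 * c(1, 5, 10, 50))
  )
  expect_equal(quantify(10, curve)$concentration_nM, 5, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)

  # planted noiseless curve with slope 1500 recovers unknowns exactly
  conc <- c(0.1, 1, 10, 100)
  curve2 <- fit_standard_curve(tibble::tibble(conc_nM = conc,
                                              area = 1500 * conc))
  unknown <- c(0.5, 7, 42)
  expect_equal(quantify(1500 * unknown, curve2)$concentration_nM, unknown,
               tolerance = 1e-9)

  # negative back-calculations are clipped and flagged
  curve3 <- fit_standard_curve(
    tibble::tibble(conc_nM = c(1, 2, 3), area = c(110, 120, 130))
  )
  q <- quantify(50, curve3)
  expect_equal(q$concentration_nM, 0)
  expect_true(q$clipped)

  bad <- fit_standard_curve(
    tibble::tibble(conc_nM = c(1, 2, 3), area = c(30, 20, 10))
  )
  expect_error(quantify(10, bad), "slope")
  expect_error(fit_standard_curve(tibble::tibble(conc_nM = c(1, 2),
                                                 area = c(1, 2))), "levels")
})

test_that("detection composes the evidence tiers independently", {
  cand <- tibble::tibble(core_sequence = "QFFGLM",
                         capped_notation = "pGlu-FFGLM-NH2")
  target <- ion_mz(peptide_mass("QFFGLM"), 1)
  feats <- tibble::tibble(mz = target, rt = 10, area = 5e4)
  tr <- make_test_trace(sn = 10)
  tr$compound <- "pGlu-FFGLM-NH2"
  sp <- tibble::tibble(compound = "pGlu-FFGLM-NH2", mz = 463.2,
                       intensity = 100)
  curve <- fit_standard_curve(
    tibble::tibble(conc_nM = c(1, 10, 100), area = 1e3 * c(1, 10, 100))
  )

  full <- detect_peptide(cand, feats, traces = tr, spectra = sp,
                         standard_rt = 10, curve = curve)
  expect_true(full$ms1_matched)
  expect_true(full$mrm_evaluated)
  expect_true(full$mrm_validated)
  expect_true(full$msms_detected)
  expect_equal(full$concentration_nM, 50, tolerance = 1e-6)

  # MS1-only evidence: trace carries no peak
  flat <- make_test_trace(sn = 0)
  flat$compound <- "pGlu-FFGLM-NH2"
  ms1_only <- detect_peptide(cand, feats, traces = flat, standard_rt = 10)
  expect_true(ms1_only$ms1_matched)
  expect_false(ms1_only$mrm_validated)

  # absent peptide: no tier fires
  none <- detect_peptide(cand, feats[0, ], traces = flat, standard_rt = 10)
  expect_false(none$ms1_matched)
  expect_false(none$mrm_validated)
  expect_true(is.na(none$concentration_nM))

  # no authentic standard: MRM tier not evaluated
  nostd <- detect_peptide(cand, feats, traces = tr, standard_rt = NA)
  expect_false(nostd$mrm_evaluated)
})
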