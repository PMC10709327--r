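test_that("peptide masses match the independent residue-table oracle", {
  # forced by the constants: glycine residue + water
  expect_equal(peptide_mass("G", pyroglu = FALSE, c_amide = FALSE),
               75.03203, tolerance = 1e-6)
  # CAP-TAC1 core, both caps: equals the bare residue sum
  expect_equal(peptide_mass("QFFGLM"), 723.3414, tolerance = 1e-4)
  expect_equal(peptide_mass("QFFGLM"), oracle_peptide_mass("QFFGLM"),
               tolerance = 5e-4)

  set.seed(42)
  for (i in 1:100) {
    s <- random_capped_core()
    expect_equal(peptide_mass(s, carbamidomethyl = FALSE),
                 oracle_peptide_mass(s), tolerance = 5e-4)
    expect_equal(
      peptide_mass(s, pyroglu = FALSE, c_amide = FALSE,
                   carbamidomethyl = FALSE),
      oracle_peptide_mass(s, pyroglu = FALSE, c_amide = FALSE),
      tolerance = 5e-4
    )
  }
})

test_that("the two caps cancel the water term exactly", {
  # -17.0265491 (pyroGlu) + -0.9840156 (amide) + 18.0105646 (water) ~ 0
  mods <- mass_constants()$mods
  expect_equal(mods[["pyroglu_from_gln"]] + mods[["c_amide"]],
               -mass_constants()$water, tolerance = 1e-6)
  set.seed(43)
  for (i in 1:1000) {
    s <- random_capped_core()
    bare_sum <- sum(mass_constants()$residues[strsplit(s, "")[[1]]])
    n_cys <- sum(strsplit(s, "")[[1]] == "C")
    expect_equal(
      peptide_mass(s),
      bare_sum + n_cys * mass_constants()$mods[["carbamidomethyl_cys"]],
      tolerance = 1e-6
    )
  }
})

test_that("unknown residues are reported with their position", {
  expect_error(peptide_mass("QAXA"), "position 3")
  expect_error(peptide_mass("BQA", pyroglu = FALSE), "position 1")
})

test_that("ion m/z follows (M + z*proton)/z", {
  expect_equal(ion_mz(723.3414, 1), 724.3487, tolerance = 1e-4)
  # within the 20 ppm window of the printed extracted-ion value
  expect_lt(abs(ion_mz(peptide_mass("QFFGLM"), 1) - 724.341) / 724.341 * 1e6,
            20)
  # algebraic identity between charge states
  M <- 1234.5678
  p <- mass_constants()$proton
  expect_equal(2 * ion_mz(M, 2) - 2 * p, ion_mz(M, 1) - p, tolerance = 1e-9)
  expect_error(ion_mz(M, 0), "charge")
  expect_error(ion_mz(-1, 1), "positive")
})

test_that("b/y fragments reproduce the CAP-TAC1 transition ions", {
  fr <- fragment_ions("QFFGLM")
  b4 <- fr$mz[fr$annotation == "b4+"]
  expect_equal(b4, 463.198, tolerance = 1e-3)
  expect_equal(round(b4, 1), 463.2)
  y2 <- fr$mz[fr$annotation == "y2+"]
  expect_equal(y2, 262.158, tolerance = 1e-3)
  expect_error(fragment_ions("QFFGLM", series = "c"), "series")
  expect_error(fragment_ions("Q"), "length")
})

test_that("b/y complementarity holds for random capped peptides", {
  set.seed(44)
  p <- mass_constants()$proton
  for (i in 1:100) {
    s <- random_capped_core()
    n <- nchar(s)
    fr <- fragment_ions(s)
    M <- peptide_mass(s)
    for (idx in seq_len(n - 1)) {
      b <- fr$mz[fr$series == "b" & fr$index == idx]
      y <- fr$mz[fr$series == "y" & fr$index == n - idx]
      expect_equal(b + y - 2 * p, M, tolerance = 1e-4)
    }
  }
})

test_that("transition design picks reference-spectrum peaks, else highest m/z", {
  cand <- tibble::tibble(core_sequence = "QFFGLM",
                         capped_notation = "pGlu-FFGLM-NH2")
  # reference spectrum whose tallest matched peak is the b4 ion
  ref <- tibble::tibble(compound = "pGlu-FFGLM-NH2",
                        mz = c(463.20, 613.33), intensity = c(1000, 200))
  tr <- build_transition_list(cand, msms_reference = ref)
  expect_equal(tr$product_annotation, "b4+")
  expect_equal(round(tr$precursor_mz, 1), 724.3)
  expect_equal(round(tr$product_mz, 1), 463.2)

  # without a reference: highest-m/z fragment above the floor
  tr2 <- build_transition_list(cand)
  frags <- fragment_ions("QFFGLM")
  expect_equal(tr2$product_mz, max(frags$mz[frags$mz >= 200]))

  # dipeptide core with every fragment below the floor is flagged
  dip <- tibble::tibble(core_sequence = "QG", capped_notation = "pGlu-G-NH2")
  tr3 <- build_transition_list(dip)
  expect_true(tr3$flagged)
  expect_true(is.na(tr3$product_mz))
})

test_that("transition lists round-trip through fragment recomputation", {
  set.seed(45)
  cands <- tibble::tibble(
    core_sequence = replicate(50, random_capped_core(max_len = 12))
  )
  cands$capped_notation <- paste0("pGlu-", substring(cands$core_sequence, 2),
                                  "-NH2")
  cands <- cands[!duplicated(cands$capped_notation), ]
  tr <- build_transition_list(cands)
  ok <- !tr$flagged
  expect_gt(sum(ok), 0)
  for (i in which(ok)) {
    frags <- fragment_ions(cands$core_sequence[i])
    hit <- frags[frags$annotation == tr$product_annotation[i], ]
    expect_equal(hit$mz, tr$product_mz[i], tolerance = 1e-9)
  }
})

test_that("scrambled controls preserve composition and the leading Q", {
  s <- scramble_control("QLELRLRVAAGR", seed = 1)
  expect_equal(substr(s, 1, 1), "Q")
  expect_false(s == "QLELRLRVAAGR")
  expect_equal(sort(strsplit(s, "")[[1]]),
               sort(strsplit("QLELRLRVAAGR", "")[[1]]))
  # deterministic per seed
  expect_equal(s, scramble_control("QLELRLRVAAGR", seed = 1))
  # the published scrambled control is one valid permutation of the core
  expect_equal(sort(strsplit("QGLEALRARLRV", "")[[1]]),
               sort(strsplit("QLELRLRVAAGR", "")[[1]]))
  # single-permutation and degenerate cases
  expect_equal(scramble_control("QAA"), "QAA")
  expect_error(scramble_control("QA"), "length")
  expect_error(scramble_control("ALA"), "begin with Q")
})
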