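test_that("composition comparison of identical sets is null", {
  set.seed(42)
  peps <- replicate(10, random_capped_core(max_len = 12))
  cmp <- compare_composition(peps, peps)
  expect_equal(cmp$mean_capped, cmp$mean_ref)
  present <- cmp$mean_capped > 0 & !cmp$zero_variance
  expect_true(all(abs(cmp$p_value[present] - 1) < 1e-9))
})

test_that("composition comparison detects planted differences", {
  a <- rep("QLLL", 10)
  b <- rep("QSSS", 10)
  cmp <- compare_composition(a, b)
  leu <- cmp[cmp$residue == "L", ]
  expect_equal(leu$mean_capped, 0.75)
  expect_equal(leu$mean_ref, 0)
  expect_true(leu$zero_variance)
  expect_lt(leu$p_value, 1e-6)
  # single-peptide sets report means but no p
  cmp1 <- compare_composition("QLL", c("QSS", "QTT"))
  expect_true(all(is.na(cmp1$p_value)))
  expect_error(compare_composition(character(0), a), "non-empty")
})

test_that("composition p-values agree with stats::t.test on non-degenerate data", {
  set.seed(43)
  a <- replicate(20, random_capped_core())
  b <- replicate(20, random_capped_core())
  cmp <- compare_composition(a, b)
  freq_of <- function(peps, res) {
    vapply(strsplit(peps, ""), function(r) mean(r == res), numeric(1))
  }
  for (res in c("A", "L", "Q")) {
    x <- freq_of(a, res)
    y <- freq_of(b, res)
    if (sd(x) > 0 || sd(y) > 0) {
      expect_equal(cmp$p_value[cmp$residue == res],
                   t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("flanking profiles read precursor context around the caps", {
  prot <- tibble::tibble(accession = "P1",
                         sequence = "TTTAQLLAGKRWWWW")
  cand <- predict_capped_peptides(prot)
  prof_n <- flanking_profile(cand, prot, k = 2, terminus = "N")
  # single candidate: one-hot columns; -1 is A, -2 is T
  expect_equal(prof_n$freq[prof_n$offset == -1 & prof_n$residue == "A"], 1)
  expect_equal(prof_n$freq[prof_n$offset == -2 & prof_n$residue == "T"], 1)

  prof_c <- flanking_profile(cand, prot, k = 2, terminus = "C")
  # +1 into the motif is the amide-donor glycine, by construction
  expect_equal(prof_c$freq[prof_c$offset == 1 & prof_c$residue == "G"], 1)
  # past-motif convention skips the G[K/R]R
  prof_c2 <- flanking_profile(cand, prot, k = 2, terminus = "C",
                              c_convention = "past_motif")
  expect_equal(prof_c2$freq[prof_c2$offset == 1 & prof_c2$residue == "W"], 1)

  expect_error(
    flanking_profile(dplyr::mutate(cand, accession = "missing"), prot),
    "Precursor"
  )
})

test_that("flanking frequencies recover planted context probabilities", {
  set.seed(44)
  n <- 150
  prots <- purrr::map_dfr(seq_len(n), function(i) {
    before <- if (runif(1) < 0.9) "A" else "V"
    tibble::tibble(
      accession = sprintf("P%03d", i),
      sequence = paste0("TTTTT", before, "QLLLAGKR", "WWWW")
    )
  })
  cands <- predict_capped_peptides(prots)
  expect_equal(nrow(cands), n)
  prof <- flanking_profile(cands, prots, k = 1, terminus = "N")
  a_freq <- prof$freq[prof$offset == -1 & prof$residue == "A"]
  expect_equal(a_freq, 0.9, tolerance = 0.08)
  # C-terminal +1 is glycine with frequency 1 for every candidate set
  prof_c <- flanking_profile(cands, prots, k = 1, terminus = "C")
  expect_equal(prof_c$freq[prof_c$offset == 1 & prof_c$residue == "G"], 1)
})

test_that("fold-change tables recover planted effects", {
  # identical groups give fold change 1
  q0 <- make_quant_experiment("pep1", planted_fcs = 1, cv = 0, seed = 1)
  fc0 <- fold_change_table(q0$quant, q0$sample_map, "control", "treated")
  expect_equal(fc0$fold_change, 1, tolerance = 1e-12)

  # planted 84-fold induction at 5% cv, n = 3/group
  q1 <- make_quant_experiment("cap_csf1", planted_fcs = 84, cv = 0.05,
                              n_per_group = 3, seed = 2)
  fc1 <- fold_change_table(q1$quant, q1$sample_map, "control", "treated")
  expect_equal(fc1$fold_change, 84, tolerance = 0.1)

  # planted 58% reduction
  q2 <- make_quant_experiment("cap_gdnf", planted_fcs = 0.42, cv = 0.05,
                              n_per_group = 3, seed = 3)
  fc2 <- fold_change_table(q2$quant, q2$sample_map, "control", "treated")
  expect_equal(fc2$fold_change, 0.42, tolerance = 0.1)
  expect_equal(fc2$log2_fc, log2(fc2$fold_change))

  # zero control mean flags an infinite ratio
  quant <- tibble::tibble(
    peptide = "p", sample = c("a1", "a2", "b1", "b2"),
    value = c(0, 0, 5, 6)
  )
  smap <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                         condition = c("a", "a", "b", "b"))
  fci <- fold_change_table(quant, smap, "a", "b")
  expect_true(fci$infinite)

  expect_error(fold_change_table(quant, smap, "a", "nope"), "absent")
  expect_error(
    fold_change_table(dplyr::mutate(quant, sample = paste0("x", sample)),
                      smap, "a", "b"),
    "missing"
  )
})

test_that("expression z-scores follow the normalise/log/z transform", {
  mat <- tibble::tibble(gene = "g1", t1 = 1, t2 = 10, t3 = 100)
  ez <- expression_zscore(mat)
  z <- ez$zscore["g1", ]
  # relative = x/111, log10 spacing exactly 1 -> sample-sd z-scores are -1,0,1
  expect_equal(unname(sort(z)), c(-1, 0, 1), tolerance = 1e-9)

  set.seed(45)
  big <- tibble::tibble(
    gene = sprintf("g%02d", 1:20),
    t1 = runif(20, 1, 100), t2 = runif(20, 1, 100),
    t3 = runif(20, 1, 100), t4 = runif(20, 1, 100)
  )
  ez2 <- expression_zscore(big)
  expect_equal(unname(rowMeans(ez2$zscore)), rep(0, 20), tolerance = 1e-6)
  expect_equal(unname(apply(ez2$zscore, 1, sd)), rep(1, 20),
               tolerance = 1e-6)

  # constant rows and non-positive rows are flagged and excluded
  bad <- tibble::tibble(gene = c("const", "neg", "ok1", "ok2"),
                        t1 = c(5, -1, 1, 3), t2 = c(5, 2, 4, 9),
                        t3 = c(5, 3, 2, 27))
  ez3 <- expression_zscore(bad)
  expect_setequal(ez3$flagged$gene, c("const", "neg"))
  expect_setequal(rownames(ez3$zscore), c("ok1", "ok2"))
})

test_that("replicate averaging and clustering recover planted structure", {
  rep_map <- tibble::tibble(sample = c("s1", "s2", "s3"),
                            tissue = c("brain", "brain", "liver"))
  m <- tibble::tibble(gene = "g", s1 = 2, s2 = 4, s3 = 9)
  ez <- expression_zscore(m, replicate_map = rep_map)
  expect_setequal(colnames(ez$zscore), c("brain", "liver"))

  # two planted expression blocks cluster apart
  set.seed(46)
  block <- function(genes, hi_tissues) {
    purrr::map_dfr(genes, function(g) {
      v <- runif(6, 1, 2)
      v[hi_tissues] <- v[hi_tissues] * 100
      tibble::tibble(gene = g, tissue = paste0("t", 1:6), value = v)
    })
  }
  long <- dplyr::bind_rows(block(sprintf("a%d", 1:5), 1:3),
                           block(sprintf("b%d", 1:5), 4:6))
  wide <- tidyr::pivot_wider(long, names_from = "tissue",
                             values_from = "value")
  ez2 <- expression_zscore(wide)
  cl <- stats::cutree(ez2$row_hclust, k = 2)
  expect_equal(length(unique(cl[grep("^a", names(cl))])), 1)
  expect_equal(length(unique(cl[grep("^b", names(cl))])), 1)
  expect_false(cl[["a1"]] == cl[["b1"]])
})
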