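# Synthetic-data generators with known ground truth for every pipeline
# stage: proteomes with planted candidates and decoys, MS1 features and MRM
# traces, multi-condition quantification tables, and pharmacology series.
# Every generator is deterministic for a given seed, and the planted truth
# is exactly recoverable by the corresponding pipeline stage in the
# noiseless limit.

random_sequence <- function(n, alphabet = CANONICAL_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_core <- function(len) {
  # core = leading Q plus non-Q residues, so the planted candidate set is
  # exactly one per motif (no nested glutamines)
  paste0("Q", paste(sample(setdiff(CANONICAL_AA, c("Q", "G", "R", "K")),
                           len - 1, replace = TRUE), collapse = ""))
}

#' Generate a synthetic secretome with planted capped-peptide candidates
#'
#' Background sequences are rejection-sampled to contain no accidental
#' candidate (no glutamine within the length window of any G[K/R]R motif).
#' Planted proteins carry one compliant Q...G[K/R]R context each at recorded
#' coordinates; the record is re-sampled until the predictor's closure over
#' it is exactly the planted candidate. Decoy proteins carry near-miss
#' contexts that must never be predicted: a glutamine at distance 21 from a
#' motif (one beyond the window), a GKK motif (second basic must be R), and
#' a candidate with an internal ambiguous X.
#'
#' @param n_proteins Total background + planted proteins (decoys are extra).
#' @param n_planted Number of planted candidates (`<= n_proteins`).
#' @param decoys Character vector choosing decoy classes, any of
#'   `"q_distance_21"`, `"gkk_motif"`, `"ambiguous_x"`; default all three.
#' @param seed Integer seed.
#' @param protein_length Background sequence length (default 300).
#' @param core_length_range Planted core lengths, inclusive (default 4..20).
#' @param max_tries Rejection-sampling retries per sequence before erroring.
#' @return List with `proteins` (tibble as from [read_fasta()]), `truth`
#'   (tibble of planted candidates: `accession`, `start`, `end`,
#'   `core_sequence`, `length`, `motif`, `motif_position`) and `seed`.
#' @export
make_proteome <- function(n_proteins = 10, n_planted = 3,
                          decoys = c("q_distance_21", "gkk_motif",
                                     "ambiguous_x"),
                          seed = 1, protein_length = 300,
                          core_length_range = c(4, 20), max_tries = 200) {
  stopifnot(n_planted <= n_proteins, n_planted >= 0)
  set.seed(seed)

  sample_background <- function() {
    for (i in seq_len(max_tries)) {
      s <- random_sequence(protein_length)
      cand <- enumerate_candidates(s, 20, 2, "Q")
      if (nrow(cand) == 0) return(s)
    }
    abort("Rejection sampling failed: could not draw a candidate-free background")
  }

  proteins <- list()
  truth <- list()
  for (i in seq_len(n_proteins)) {
    acc <- sprintf("SYN%04d", i)
    if (i <= n_planted) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        bg <- sample_background()
        core_len <- sample(seq(core_length_range[1], core_length_range[2]), 1)
        core <- random_core(core_len)
        motif <- sample(c("GKR", "GRR"), 1)
        ins_at <- sample(seq(10, protein_length - 40), 1)
        s <- paste0(substr(bg, 1, ins_at), core, motif,
                    substr(bg, ins_at + 1, protein_length))
        cand <- enumerate_candidates(s, 20, 2, "Q")
        if (nrow(cand) == 1 && cand$core_sequence == core) {
          proteins[[acc]] <- s
          truth[[acc]] <- mutate(cand, accession = acc)
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("Rejection sampling failed while planting a candidate")
    } else {
      proteins[[acc]] <- sample_background()
    }
  }

  decoy_context <- list(
    # Q exactly 21 residues from the motif G: one beyond the window
    q_distance_21 = paste0("Q", random_sequence(20,
      setdiff(CANONICAL_AA, c("Q", "G", "R", "K"))), "GKR"),
    # second basic is K, not R: not an amidation motif
    gkk_motif = "QLLALGKK",
    # internal ambiguous residue: candidate must be dropped
    ambiguous_x = "QLLXALGKR"
  )
  for (d in decoys) {
    acc <- paste0("DECOY_", toupper(d))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      bg <- sample_background()
      s <- paste0(substr(bg, 1, 50), decoy_context[[d]],
                  substr(bg, 51, protein_length))
      if (nrow(enumerate_candidates(s, 20, 2, "Q")) == 0) {
        proteins[[acc]] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("Rejection sampling failed while planting a decoy")
  }

  prot_tbl <- tibble(
    accession = names(proteins), name = NA_character_, gene = NA_character_,
    species = "synthetic", sequence = unname(unlist(proteins))
  ) %>%
    mutate(length = nchar(.data$sequence),
           has_ambiguous = stringr::str_detect(.data$sequence, "[BZXUO]"),
           signal_peptide_end = NA_integer_)
  truth_tbl <- if (length(truth) > 0) {
    bind_rows(truth) %>%
      select("accession", "start", "end", "core_sequence", "length",
             "motif", "motif_position")
  } else {
    tibble(accession = character(), start = integer(), end = integer(),
           core_sequence = character(), length = integer(),
           motif = character(), motif_position = integer())
  }
  list(proteins = prot_tbl, truth = truth_tbl, seed = seed)
}

#' Generate synthetic MS1 features and MRM traces for planted candidates
#'
#' Planted MS1 features sit at each candidate's theoretical \[M+H\]+ with
#' Gaussian ppm-scale jitter and an assigned retention time; decoy features
#' are planted at a fixed +25 ppm offset (outside the 20 ppm window).
#' Traces are Gaussian elution peaks at the expected retention time whose
#' height is `sn` times the baseline noise scale (1.4826 x MAD of the
#' Gaussian baseline), over a flat noisy baseline.
#'
#' @param candidates Candidate tibble (from [predict_capped_peptides()] or a
#'   proteome truth joined with cores).
#' @param ppm_sigma Gaussian m/z jitter, ppm (default 3; at the default a
#'   20 ppm window is a ~6.7 sigma bound, so planted features always match).
#' @param baseline_sd Baseline noise sd in intensity units (default 50).
#' @param sn Per-candidate signal-to-noise of the planted MRM peak; recycled
#'   (default 10).
#' @param decoy_ppm Offset of decoy MS1 features, ppm (default +25).
#' @param rt_start,rt_step Retention times assigned to candidates,
#'   `rt_start + (i-1) * rt_step` minutes.
#' @param seed Integer seed.
#' @return List with `features` (tibble `mz`, `rt`, `area`, `sample`,
#'   `kind`), `traces` (tibble `compound`, `time`, `intensity`,
#'   `expected_rt`), and `truth` (per-candidate `compound`, `target_mz`,
#'   `rt`, `area`, `sn`).
#' @export
make_ms1_and_traces <- function(candidates, ppm_sigma = 3, baseline_sd = 50,
                                sn = 10, decoy_ppm = 25, rt_start = 5,
                                rt_step = 2, seed = 1) {
  stopifnot(nrow(candidates) > 0)
  set.seed(seed)
  n <- nrow(candidates)
  sn <- rep_len(sn, n)
  target_mz <- ion_mz(peptide_mass(candidates$core_sequence), 1)
  rts <- rt_start + (seq_len(n) - 1) * rt_step
  areas <- stats::runif(n, 1e4, 1e6)

  feat_true <- tibble(
    mz = target_mz * (1 + rnorm(n, 0, ppm_sigma) / 1e6),
    rt = rts + rnorm(n, 0, 0.05), area = areas, sample = "synthetic",
    kind = "planted"
  )
  feat_decoy <- tibble(
    mz = target_mz * (1 + decoy_ppm / 1e6),
    rt = rts, area = areas * 0.5, sample = "synthetic", kind = "decoy"
  )
  features <- bind_rows(feat_true, feat_decoy)

  grid <- seq(0, rt_start + n * rt_step + 5, by = 0.02)
  traces <- purrr::map_dfr(seq_len(n), function(i) {
    base <- rnorm(length(grid), 10 * baseline_sd, baseline_sd)
    noise_scale <- mad(base, constant = 1.4826)
    peak <- sn[i] * noise_scale * exp(-(grid - rts[i])^2 / (2 * 0.1^2))
    tibble(
      compound = candidates$capped_notation[i], time = grid,
      intensity = pmax(base + peak, 0), expected_rt = rts[i]
    )
  })

  truth <- tibble(
    compound = candidates$capped_notation, target_mz = target_mz,
    rt = rts, area = areas, sn = sn
  )
  list(features = features, traces = traces, truth = truth, seed = seed)
}

#' Generate a multi-condition quantification experiment with planted fold
#' changes
#'
#' Values are drawn log-normally around condition means with a given
#' coefficient of variation (mean-preserving parameterisation, so `cv = 0`
#' reproduces the planted means exactly). Fold changes are planted per
#' peptide relative to the first (control) condition.
#'
#' @param peptides Character vector of peptide identifiers.
#' @param planted_fcs Either a numeric vector (one fold change per peptide,
#'   two-condition design) or a tibble `peptide`, `condition`, `fc` for
#'   multi-condition designs; the control condition is implicitly 1.
#' @param conditions Condition labels; the first is the control (default
#'   `c("control", "treated")`).
#' @param n_per_group Replicates per condition (default 3).
#' @param cv Coefficient of variation of the log-normal noise (default
#'   0.05).
#' @param base_level Control-condition mean (default 1000; recycled).
#' @param seed Integer seed.
#' @return List with `quant` (long tibble `peptide`, `sample`, `value`),
#'   `sample_map` (`sample`, `condition`) and `truth` (tibble `peptide`,
#'   `condition`, `fc`, `mean`).
#' @export
make_quant_experiment <- function(peptides, planted_fcs,
                                  conditions = c("control", "treated"),
                                  n_per_group = 3, cv = 0.05,
                                  base_level = 1000, seed = 1) {
  stopifnot(cv >= 0, length(conditions) >= 2)
  set.seed(seed)
  base_level <- rep_len(base_level, length(peptides))
  if (!is.data.frame(planted_fcs)) {
    stopifnot(length(conditions) == 2)
    planted_fcs <- tibble(
      peptide = peptides, condition = conditions[2],
      fc = rep_len(planted_fcs, length(peptides))
    )
  }
  truth <- tidyr::crossing(
    peptide = peptides, condition = conditions
  ) %>%
    left_join(planted_fcs, by = c("peptide", "condition")) %>%
    mutate(
      fc = dplyr::if_else(.data$condition == conditions[1], 1,
                          dplyr::coalesce(.data$fc, 1)),
      mean = base_level[match(.data$peptide, peptides)] * .data$fc
    )
  sample_map <- tidyr::crossing(
    condition = conditions, rep = seq_len(n_per_group)
  ) %>%
    mutate(sample = paste0(.data$condition, "_", .data$rep)) %>%
    select("sample", "condition")
  sdlog <- sqrt(log(1 + cv^2))
  quant <- tidyr::crossing(truth, rep = seq_len(n_per_group)) %>%
    mutate(
      sample = paste0(.data$condition, "_", .data$rep),
      value = .data$mean *
        exp(rnorm(dplyr::n(), -sdlog^2 / 2, sdlog))
    ) %>%
    select("peptide", "sample", "value")
  list(quant = quant, sample_map = sample_map,
       truth = select(truth, "peptide", "condition", "fc", "mean"),
       seed = seed)
}

#' Generate synthetic pharmacology series (dose-response or decay)
#'
#' @param kind `"dose_response"` (four-parameter logistic) or `"decay"`
#'   (single exponential).
#' @param params For dose-response: `ec50` (molar), `hill`, `bottom`, `top`;
#'   optional `doses` (molar vector; default 8 log-spaced levels spanning
#'   +/- 3 logs around the EC50). For decay: `t_half` (minutes),
#'   optional `amplitude` (default 100) and `times` (default
#'   `c(0, 20, 40, 60)`, the plasma-stability sampling design).
#' @param noise Noise level. Dose-response: additive Gaussian sd as a
#'   fraction of the response span. Decay: multiplicative log-normal sd
#'   (e.g. 0.1 for 10%).
#' @param n_replicates Replicates per level (default 2).
#' @param seed Integer seed.
#' @return List with `data` (tibble `dose_molar`/`time_min`, `response`/
#'   `level`, `replicate`), `truth` (the parameter list) and `kind`.
#' @export
make_pharm_data <- function(kind = c("dose_response", "decay"),
                            params = list(), noise = 0, n_replicates = 2,
                            seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "dose_response") {
    ec50 <- params$ec50 %||% 1e-9
    hill <- params$hill %||% 1
    bottom <- params$bottom %||% 0
    top <- params$top %||% 100
    doses <- params$doses %||% (ec50 * 10^seq(-3, 3, length.out = 8))
    d <- tidyr::crossing(dose_molar = doses,
                         replicate = seq_len(n_replicates)) %>%
      mutate(
        response = bottom + (top - bottom) /
          (1 + (ec50 / .data$dose_molar)^hill) +
          rnorm(dplyr::n(), 0, noise * (top - bottom))
      )
    list(data = d,
         truth = list(ec50 = ec50, hill = hill, bottom = bottom, top = top),
         kind = kind, seed = seed)
  } else {
    t_half <- params$t_half %||% 8.5
    amplitude <- params$amplitude %||% 100
    times <- params$times %||% c(0, 20, 40, 60)
    k <- log(2) / t_half
    d <- tidyr::crossing(time_min = times,
                         replicate = seq_len(n_replicates)) %>%
      mutate(level = amplitude * exp(-k * .data$time_min) *
               exp(rnorm(dplyr::n(), 0, noise)))
    list(data = d,
         truth = list(t_half = t_half, amplitude = amplitude, k = k),
         kind = kind, seed = seed)
  }
}
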