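# Independent oracles used to cross-check the implementation. These are
# deliberately written against the structure of the implementation: a
# second residue-mass table typed from the standard monoisotopic values, a
# brute-force triple-loop candidate enumerator, and a tiny Needleman-Wunsch
# score DP.

ORACLE_AA <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276
ORACLE_NH3 <- 17.026549

oracle_peptide_mass <- function(seq, pyroglu = TRUE, c_amide = TRUE) {
  res <- strsplit(seq, "")[[1]]
  m <- sum(ORACLE_AA[res]) + ORACLE_WATER
  if (pyroglu) m <- m - ORACLE_NH3
  if (c_amide) m <- m - (ORACLE_WATER - ORACLE_NH3) # -OH+NH2 = -0.984016
  m
}

# Brute-force candidate enumeration: loop over every (Q, motif) pair.
oracle_predict <- function(seq, max_len = 20, min_len = 2, nterm = "Q") {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  out <- list()
  for (m in seq_len(n)) {
    if (m + 2 > n) next
    if (res[m] != "G" || !(res[m + 1] %in% c("K", "R")) || res[m + 2] != "R") next
    for (q in seq_len(n)) {
      if (res[q] != nterm) next
      len <- m - q
      if (len < min_len || len > max_len) next
      core <- paste(res[q:(m - 1)], collapse = "")
      if (grepl("[BZXUO]", core)) next
      out[[length(out) + 1]] <- data.frame(
        start = q, end = m - 1L, core_sequence = core, length = len,
        motif = paste(res[m:(m + 2)], collapse = ""),
        motif_position = m, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      start = integer(), end = integer(), core_sequence = character(),
      length = integer(), motif = character(), motif_position = integer(),
      stringsAsFactors = FALSE
    ))
  }
  df <- do.call(rbind, out)
  df[order(df$motif_position, df$start), , drop = FALSE]
}

# Needleman-Wunsch optimal global score: match +1, mismatch 0, gap -1.
oracle_nw_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -(0:m)
  S[, 1] <- -(0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + as.integer(A[i] == B[j]),
        S[i, j + 1] - 1, S[i + 1, j] - 1
      )
    }
  }
  S[n + 1, m + 1]
}

random_aa_sequence <- function(n, alphabet = cappedpep::mass_constants()$residues) {
  paste(sample(names(alphabet), n, replace = TRUE), collapse = "")
}

random_capped_core <- function(max_len = 20) {
  len <- sample(2:max_len, 1)
  paste0("Q", random_aa_sequence(len - 1))
}
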