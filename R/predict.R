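# Capped-peptide candidate enumeration: scan secretome sequences for
# glycine-dibasic amidation motifs (G[K/R]R) and pair each with every
# upstream glutamine inside the length window.

#' Find C-terminal amidation motifs in a sequence
#'
#' Returns the 1-based positions of the glycine of every `G[K/R]R` match
#' (the glycine is the amide donor; the dibasic pair marks proprotein-
#' convertase cleavage). Overlapping matches are all reported. Ambiguous
#' letters (B, Z, X, U, O) never match.
#'
#' @param sequence A single uppercase amino-acid string.
#' @return Integer vector of motif positions (possibly empty).
#' @examples
#' find_amidation_motifs("AAGKRAA") # 3
#' find_amidation_motifs("GKRGRR") # 1 4
#' @export
find_amidation_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) return(integer(0))
  m <- gregexpr("(?=G[KR]R)", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Predict capped peptides from secretome proteins
#'
#' For every amidation motif in every protein, enumerates one candidate per
#' upstream `nterm_residue` (glutamine by default) whose distance to the
#' motif glycine lies within the length window. The candidate is the
#' inclusive sequence from the glutamine to the residue immediately
#' preceding the motif glycine; its capped form carries N-terminal
#' pyroglutamate and a C-terminal amide. All qualifying glutamines are
#' enumerated, so one motif can yield several nested candidates and one
#' protein several peptides.
#'
#' @param proteins A protein tibble as returned by [read_fasta()] (columns
#'   `accession`, `sequence`; optional `gene`, `signal_peptide_end`).
#' @param max_length Maximum candidate length in residues, counting the
#'   pyroGlu (default 20, the practical ceiling for synthesis of authentic
#'   standards).
#' @param min_length Minimum candidate length (default 2; a bare pGlu-NH2
#'   is chemically degenerate).
#' @param nterm_residue Residue seeding the N-terminus (default `"Q"`;
#'   other residues explore non-pyroGlu N-terminal chemistries).
#' @param exclude_signal_overlap If `TRUE`, drop candidates starting at or
#'   before `signal_peptide_end`. Off by default: capped peptides starting
#'   just after the signal peptide are real (e.g. one maps four residues
#'   beyond it).
#' @return A tibble with one row per candidate: `accession`, `gene`,
#'   `start`, `end` (1-based inclusive span of the core), `core_sequence`,
#'   `capped_notation` (`pGlu-...-NH2`), `length`, `motif` (`GKR`/`GRR`),
#'   `motif_position`, `duplicated_core` (TRUE when the same core sequence
#'   occurs at another position of the same protein). Rows are ordered by
#'   protein, then `motif_position`, then `start`.
#' @examples
#' prot <- tibble::tibble(accession = "TAC1", sequence = "RRPKPQQFFGLMGKR")
#' predict_capped_peptides(prot)
#' @export
predict_capped_peptides <- function(proteins, max_length = 20, min_length = 2,
                                    nterm_residue = "Q",
                                    exclude_signal_overlap = FALSE) {
  if (min_length < 1) abort("`min_length` must be >= 1")
  if (max_length < min_length) abort("`max_length` must be >= `min_length`")
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  if (!nchar(nterm_residue) == 1) abort("`nterm_residue` must be one letter")

  gene_col <- if ("gene" %in% names(proteins)) proteins$gene else
    rep(NA_character_, nrow(proteins))
  sp_col <- if ("signal_peptide_end" %in% names(proteins))
    proteins$signal_peptide_end else rep(NA_integer_, nrow(proteins))

  out <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    seq <- toupper(proteins$sequence[i])
    cands <- enumerate_candidates(seq, max_length, min_length, nterm_residue)
    if (nrow(cands) == 0) return(cands)
    if (exclude_signal_overlap && !is.na(sp_col[i])) {
      cands <- filter(cands, .data$start > sp_col[i])
    }
    if (nrow(cands) == 0) return(cands)
    cands %>%
      mutate(
        accession = proteins$accession[i], gene = gene_col[i],
        duplicated_core = duplicated(.data$core_sequence) |
          duplicated(.data$core_sequence, fromLast = TRUE)
      ) %>%
      select("accession", "gene", "start", "end", "core_sequence",
             "capped_notation", "length", "motif", "motif_position",
             "duplicated_core")
  })
  if (nrow(out) == 0) {
    out <- tibble(
      accession = character(), gene = character(), start = integer(),
      end = integer(), core_sequence = character(),
      capped_notation = character(), length = integer(), motif = character(),
      motif_position = integer(), duplicated_core = logical()
    )
  }
  out
}

enumerate_candidates <- function(seq, max_length, min_length, nterm_residue) {
  motifs <- find_amidation_motifs(seq)
  empty <- tibble(
    start = integer(), end = integer(), core_sequence = character(),
    capped_notation = character(), length = integer(), motif = character(),
    motif_position = integer()
  )
  if (length(motifs) == 0) return(empty)
  q_pos <- which(strsplit(seq, "", fixed = TRUE)[[1]] == nterm_residue)
  if (length(q_pos) == 0) return(empty)
  rows <- purrr::map_dfr(motifs, function(m) {
    qs <- q_pos[m - q_pos >= min_length & m - q_pos <= max_length]
    if (length(qs) == 0) return(empty)
    tibble(
      start = qs, end = m - 1L,
      core_sequence = substring(seq, qs, m - 1L),
      length = m - qs,
      motif = substr(seq, m, m + 2L),
      motif_position = as.integer(m)
    ) %>%
      filter(!stringr::str_detect(.data$core_sequence, "[BZXUO]")) %>%
      mutate(capped_notation = paste0(
        "pGlu-", substring(.data$core_sequence, 2), "-NH2"
      ))
  })
  arrange(rows, .data$motif_position, .data$start) %>%
    select("start", "end", "core_sequence", "capped_notation", "length",
           "motif", "motif_position")
}

#' Write predicted candidates to TSV
#'
#' @param candidates Candidate tibble from [predict_capped_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(candidates, path) {
  readr::write_tsv(candidates, path)
  invisible(path)
}
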