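# Secretome FASTA input/output. Parsing is delegated to Biostrings; headers
# are interpreted in both the Uniprot `sp|ACC|NAME` dialect and as plain
# identifiers.

#' Read a secretome FASTA file into a protein tibble
#'
#' One row per FASTA entry, order preserved. Uniprot-style headers
#' (`sp|P41539|TKN1_MOUSE ... OS=Mus musculus ... GN=Tac1`) are parsed for
#' accession, entry name, species and gene; any other header is taken as a
#' plain accession (first whitespace-delimited token).
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `accession`, `name`, `gene`, `species`,
#'   `sequence`, `length`, `has_ambiguous` (TRUE when the sequence contains
#'   any of B, Z, X, U, O) and `signal_peptide_end` (NA; may be filled from
#'   annotation by the caller).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|A", "MQAGKRA", ">P2", "MAAA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  empty_tbl <- tibble(
    accession = character(), name = character(), gene = character(),
    species = character(), sequence = character(), length = integer(),
    has_ambiguous = logical(), signal_peptide_end = integer()
  )
  if (length(nonblank) == 0) return(empty_tbl)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf(
      "Malformed FASTA: line %d does not start a '>' header", nonblank[1]
    ))
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(empty_tbl)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf(
      "Malformed FASTA: empty sequence for entry '%s'",
      headers[which(!nzchar(seqs))[1]]
    ))
  }
  parsed <- purrr::map_dfr(headers, parse_fasta_header)
  if (anyDuplicated(parsed$accession)) {
    dup <- parsed$accession[duplicated(parsed$accession)][1]
    abort(sprintf("Duplicate accession in FASTA: %s", dup))
  }
  parsed %>%
    mutate(
      sequence = unname(seqs),
      length = nchar(.data$sequence),
      has_ambiguous = stringr::str_detect(.data$sequence, "[BZXUO]"),
      signal_peptide_end = NA_integer_
    )
}

parse_fasta_header <- function(header) {
  first <- strsplit(header, "\\s+")[[1]][1]
  accession <- first
  name <- NA_character_
  if (grepl("^(sp|tr)\\|", first)) {
    parts <- strsplit(first, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2) accession <- parts[2]
    if (length(parts) >= 3) name <- parts[3]
  }
  gene <- stringr::str_match(header, "GN=(\\S+)")[, 2]
  species <- stringr::str_match(header, "OS=([^=]+?)(?:\\s+[A-Z]{2}=|$)")[, 2]
  tibble(
    accession = accession, name = name,
    gene = unname(gene), species = trimws(unname(species))
  )
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with `accession` and `sequence` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$accession
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
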