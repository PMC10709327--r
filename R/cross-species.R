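# Cross-species comparison of capped-peptide sets: exact sequence
# conservation, pairwise global-alignment similarity, and an average-linkage
# guide tree (a deliberately simple stand-in for a full progressive MSA
# phylotree).

#' Find exactly conserved capped peptides between two species sets
#'
#' @param set_a,set_b Tibbles with `core_sequence` and optionally `species`,
#'   `name` columns (or plain character vectors of core sequences).
#' @return Tibble of species-labelled pairs with identical core sequences:
#'   `core_sequence`, `name_a`, `name_b`, `species_a`, `species_b`,
#'   `identity` (always 1).
#' @export
find_conserved <- function(set_a, set_b) {
  norm <- function(x, default_species) {
    if (!is.data.frame(x)) x <- tibble(core_sequence = as.character(x))
    if (!"name" %in% names(x)) x$name <- x$core_sequence
    if (!"species" %in% names(x)) x$species <- default_species
    x
  }
  a <- norm(set_a, "a")
  b <- norm(set_b, "b")
  dplyr::inner_join(
    select(a, core_sequence = "core_sequence", name_a = "name",
           species_a = "species"),
    select(b, core_sequence = "core_sequence", name_b = "name",
           species_b = "species"),
    by = "core_sequence", relationship = "many-to-many"
  ) %>%
    mutate(identity = 1) %>%
    select("core_sequence", "name_a", "name_b", "species_a", "species_b",
           "identity")
}

#' Pairwise global-alignment identity and distance
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, gap -1;
#' identity is the fraction of identical aligned positions over the
#' alignment length (gaps included), and distance is `1 - identity`.
#'
#' @param a,b Peptide sequences (single strings).
#' @return One-row tibble: `score`, `alignment_length`, `identity`,
#'   `distance`.
#' @examples
#' align_peptides("QVL", "QVLDT") # identity 0.6, distance 0.4
#' @export
align_peptides <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  mat <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
    type = "global"
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  ps <- as.character(Biostrings::alignedSubject(aln))
  ra <- strsplit(pa, "")[[1]]
  rb <- strsplit(ps, "")[[1]]
  len <- length(ra)
  ident <- sum(ra == rb & ra != "-") / len
  tibble(
    score = Biostrings::score(aln), alignment_length = len,
    identity = ident, distance = 1 - ident
  )
}

#' Cluster capped peptides into a similarity guide tree
#'
#' Computes all pairwise global-alignment distances (see
#' [align_peptides()]) and builds an average-linkage (UPGMA-style)
#' agglomerative tree. Input order is canonicalised lexicographically so the
#' result is deterministic; duplicate sequences are allowed (zero distance).
#'
#' @param peptides Tibble with `core_sequence` and optionally `name`,
#'   `species` columns, or a character vector; >= 2 peptides.
#' @return Object of class `peptide_tree`: list with `tree` (an
#'   [ape::phylo]), `hclust`, `dist` (the distance matrix) and `labels`.
#' @export
cluster_peptides <- function(peptides) {
  if (!is.data.frame(peptides)) {
    peptides <- tibble(core_sequence = as.character(peptides))
  }
  if (!"name" %in% names(peptides)) peptides$name <- peptides$core_sequence
  if ("species" %in% names(peptides)) {
    peptides$label <- paste0(peptides$species, "|", peptides$name)
  } else {
    peptides$label <- peptides$name
  }
  if (nrow(peptides) < 2) abort("Need >= 2 peptides to build a tree")
  if (anyDuplicated(peptides$label)) {
    peptides$label <- make.unique(peptides$label, sep = "#")
  }
  peptides <- arrange(peptides, .data$label)
  n <- nrow(peptides)
  dmat <- matrix(0, n, n, dimnames = list(peptides$label, peptides$label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- align_peptides(peptides$core_sequence[i],
                          peptides$core_sequence[j])$distance
      dmat[i, j] <- d
      dmat[j, i] <- d
    }
  }
  hc <- hclust(stats::as.dist(dmat), method = "average")
  structure(
    list(tree = ape::as.phylo(hc), hclust = hc, dist = dmat,
         labels = peptides$label),
    class = "peptide_tree"
  )
}

#' @export
print.peptide_tree <- function(x, ...) {
  cat(sprintf("Capped-peptide guide tree over %d peptides\n",
              length(x$labels)))
  invisible(x)
}

#' Write a peptide tree to Newick
#'
#' @param x A `peptide_tree` from [cluster_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "peptide_tree"))
  ape::write.tree(x$tree, file = path)
  invisible(path)
}
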