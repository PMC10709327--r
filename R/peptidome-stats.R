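# Downstream peptidome statistics: amino-acid composition versus a
# reference hormone set, flanking-residue profiles around the caps,
# perturbation fold-change tables, and tissue-expression z-score matrices.

peptide_vector <- function(x, col = c("core_sequence", "sequence", "peptide")) {
  if (is.data.frame(x)) {
    hit <- intersect(col, names(x))
    if (length(hit) == 0) abort("No peptide sequence column found")
    x <- x[[hit[1]]]
  }
  toupper(as.character(x))
}

composition_matrix <- function(peptides) {
  counts <- t(vapply(split_residues(peptides), function(res) {
    tab <- table(factor(res, levels = CANONICAL_AA))
    as.numeric(tab) / length(res)
  }, numeric(length(CANONICAL_AA))))
  colnames(counts) <- CANONICAL_AA
  counts
}

#' Compare amino-acid composition between two peptide sets
#'
#' Each peptide contributes its own residue-frequency vector (summing to 1);
#' for every residue a two-sided two-sample Student's t-test compares the
#' per-peptide frequencies of the two sets. When both groups have zero
#' variance for a residue, the test degenerates: p is 1 for equal means and
#' ~0 otherwise, and the row is flagged.
#'
#' @param capped,reference Peptide sets: character vectors of sequences or
#'   tibbles with a `core_sequence`/`sequence` column. Both non-empty.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw p-values), `"BH"` available.
#' @return Tibble with one row per residue: `residue`, `mean_capped`,
#'   `mean_ref`, `p_value`, `zero_variance`. p is NA when either set has a
#'   single peptide.
#' @export
compare_composition <- function(capped, reference, p_adjust = "none") {
  capped <- peptide_vector(capped)
  reference <- peptide_vector(reference)
  if (length(capped) == 0 || length(reference) == 0) {
    abort("Both peptide sets must be non-empty")
  }
  a <- composition_matrix(capped)
  b <- composition_matrix(reference)
  out <- purrr::map_dfr(CANONICAL_AA, function(res) {
    x <- a[, res]
    y <- b[, res]
    zero_var <- sd(x) == 0 && sd(y) == 0
    p <- if (length(x) < 2 || length(y) < 2) {
      NA_real_
    } else if (zero_var) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
      tryCatch(
        t.test(x, y, var.equal = TRUE)$p.value,
        error = function(e) NA_real_
      )
    }
    tibble(residue = res, mean_capped = mean(x), mean_ref = mean(y),
           p_value = p, zero_variance = zero_var)
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Residue frequencies flanking the N- or C-terminal cap
#'
#' For every candidate, reads the precursor residues at offsets -k..-1 and
#' +1..+k relative to the capped residue: the pyroglutamylated Q for the N
#' terminus, the final amidated residue for the C terminus. Positions
#' falling outside the precursor are skipped. Each offset column is
#' normalised over the residues observed there.
#'
#' For the C terminus the downstream convention is ambiguous because the
#' G[K/R]R motif sits immediately after the amidated residue:
#' `"into_motif"` counts +1 as the motif glycine (so the +1 column is all G
#' by construction); `"past_motif"` starts the downstream offsets after the
#' motif's final R.
#'
#' @param candidates Candidate tibble (`accession`, `start`, `end`).
#' @param precursors Protein tibble (`accession`, `sequence`) containing
#'   every candidate's precursor.
#' @param k Number of flanking positions each side (default 4).
#' @param terminus `"N"` or `"C"`.
#' @param c_convention Downstream offset convention at the C terminus.
#' @return Tidy tibble: `offset` (-k..-1, +1..+k), `residue`, `freq`
#'   (column-normalised), `n_obs` (observations at that offset).
#' @export
flanking_profile <- function(candidates, precursors, k = 4,
                             terminus = c("N", "C"),
                             c_convention = c("into_motif", "past_motif")) {
  terminus <- match.arg(terminus)
  c_convention <- match.arg(c_convention)
  stopifnot(k >= 1)
  missing_acc <- setdiff(candidates$accession, precursors$accession)
  if (length(missing_acc) > 0) {
    abort(sprintf("Precursor not found for accession %s", missing_acc[1]))
  }
  seq_by_acc <- setNames(toupper(precursors$sequence), precursors$accession)
  offsets <- c(-(k:1), 1:k)
  obs <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    seq <- seq_by_acc[[candidates$accession[i]]]
    anchor <- if (terminus == "N") candidates$start[i] else candidates$end[i]
    pos <- anchor + offsets
    if (terminus == "C" && c_convention == "past_motif") {
      pos[offsets > 0] <- pos[offsets > 0] + 3L
    }
    keep <- pos >= 1 & pos <= nchar(seq)
    tibble(
      offset = offsets[keep],
      residue = substring(seq, pos[keep], pos[keep])
    )
  })
  obs <- filter(obs, .data$residue %in% CANONICAL_AA)
  obs %>%
    dplyr::count(.data$offset, .data$residue, name = "count") %>%
    group_by(.data$offset) %>%
    mutate(n_obs = sum(.data$count), freq = .data$count / .data$n_obs) %>%
    ungroup() %>%
    select("offset", "residue", "freq", "n_obs")
}

#' Per-peptide fold changes between two conditions
#'
#' Fold change is the ratio of condition means (b over a) of areas or
#' concentrations; a two-sided Student's t-test compares the two groups per
#' peptide.
#'
#' @param quant Long quantification tibble: `peptide`, `sample`, `value`
#'   (non-negative areas or nM).
#' @param sample_map Tibble mapping `sample` to `condition`; every sample in
#'   `quant` must be mapped.
#' @param condition_a,condition_b Condition labels (fold change = b / a).
#' @param p_adjust Correction method for [stats::p.adjust()]; default raw.
#' @return Tibble per peptide: `peptide`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2_fc`, `p_value`, `infinite` (TRUE when `mean_a` is
#'   zero and the ratio is infinite).
#' @export
fold_change_table <- function(quant, sample_map, condition_a, condition_b,
                              p_adjust = "none") {
  stopifnot(all(c("peptide", "sample", "value") %in% names(quant)),
            all(c("sample", "condition") %in% names(sample_map)))
  unmapped <- setdiff(unique(quant$sample), sample_map$sample)
  if (length(unmapped) > 0) {
    abort(sprintf("Sample '%s' missing from sample_map", unmapped[1]))
  }
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% sample_map$condition) {
      abort(sprintf("Condition '%s' absent from sample_map", cond))
    }
  }
  df <- left_join(quant, sample_map, by = "sample") %>%
    filter(.data$condition %in% c(condition_a, condition_b))
  out <- df %>%
    group_by(.data$peptide) %>%
    summarise(
      mean_a = mean(.data$value[.data$condition == condition_a]),
      mean_b = mean(.data$value[.data$condition == condition_b]),
      p_value = {
        x <- .data$value[.data$condition == condition_a]
        y <- .data$value[.data$condition == condition_b]
        if (length(x) < 2 || length(y) < 2 || (sd(x) == 0 && sd(y) == 0)) {
          if (length(x) >= 2 && length(y) >= 2 &&
              isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
        } else {
          t.test(x, y, var.equal = TRUE)$p.value
        }
      },
      .groups = "drop"
    ) %>%
    mutate(
      fold_change = .data$mean_b / .data$mean_a,
      log2_fc = log2(.data$fold_change),
      infinite = is.infinite(.data$fold_change)
    ) %>%
    select("peptide", "mean_a", "mean_b", "fold_change", "log2_fc",
           "p_value", "infinite")
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Tissue-expression z-score matrix with hierarchical clustering
#'
#' Reproduces the expression-heatmap transform: replicates are averaged per
#' tissue, each gene row is normalised to sum 1 across tissues, log10 is
#' taken, and the row is z-scored (sample-sd convention). Rows with a
#' non-positive averaged value, and constant rows whose z-score is
#' undefined, are flagged and excluded. Rows and columns are ordered by
#' agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance).
#'
#' @param expr Gene-by-tissue expression: a data frame with a `gene` column
#'   and one numeric column per sample, or a numeric matrix with gene
#'   rownames. Values must be raw (positive) expression.
#' @param replicate_map Optional tibble with `sample`, `tissue` columns;
#'   replicate samples of the same tissue are averaged. Default: one sample
#'   per tissue.
#' @return An object of class `expression_zscore`: list with `zscore`
#'   (matrix, clustered order), `flagged` (tibble of excluded genes with
#'   reasons), `row_hclust`, `col_hclust`. Has `tidy()` and `autoplot()`
#'   methods.
#' @export
expression_zscore <- function(expr, replicate_map = NULL) {
  if (is.data.frame(expr)) {
    stopifnot("gene" %in% names(expr))
    genes <- expr$gene
    mat <- as.matrix(expr[setdiff(names(expr), "gene")])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(expr)
    if (is.null(rownames(mat))) abort("Matrix input needs gene rownames")
  }
  if (!is.null(replicate_map)) {
    stopifnot(all(c("sample", "tissue") %in% names(replicate_map)))
    missing_s <- setdiff(colnames(mat), replicate_map$sample)
    if (length(missing_s) > 0) {
      abort(sprintf("Sample '%s' missing from replicate_map", missing_s[1]))
    }
    tissues <- replicate_map$tissue[match(colnames(mat), replicate_map$sample)]
    mat <- t(rowsum(t(mat), tissues) / as.vector(table(tissues)[
      sort(unique(tissues))
    ]))
    mat <- mat[, sort(unique(tissues)), drop = FALSE]
  }

  flagged <- tibble(gene = character(), reason = character())
  nonpos <- rowSums(mat <= 0) > 0
  if (any(nonpos)) {
    flagged <- bind_rows(flagged, tibble(
      gene = rownames(mat)[nonpos], reason = "non-positive expression"
    ))
    mat <- mat[!nonpos, , drop = FALSE]
  }
  rel <- mat / rowSums(mat)
  lg <- log10(rel)
  constant <- apply(lg, 1, sd) == 0
  if (any(constant)) {
    flagged <- bind_rows(flagged, tibble(
      gene = rownames(lg)[constant], reason = "constant across tissues"
    ))
    lg <- lg[!constant, , drop = FALSE]
  }
  z <- t(scale(t(lg))) # row-wise z-score, sample-sd convention
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL

  row_hc <- if (nrow(z) >= 2) hclust(dist(z), method = "complete") else NULL
  col_hc <- if (ncol(z) >= 2) hclust(dist(t(z)), method = "complete") else NULL
  ord_r <- if (is.null(row_hc)) seq_len(nrow(z)) else row_hc$order
  ord_c <- if (is.null(col_hc)) seq_len(ncol(z)) else col_hc$order
  structure(
    list(
      zscore = z[ord_r, ord_c, drop = FALSE],
      flagged = flagged, row_hclust = row_hc, col_hclust = col_hc
    ),
    class = "expression_zscore"
  )
}

#' @export
print.expression_zscore <- function(x, ...) {
  cat(sprintf(
    "Expression z-score matrix: %d genes x %d tissues (%d flagged/excluded)\n",
    nrow(x$zscore), ncol(x$zscore), nrow(x$flagged)
  ))
  invisible(x)
}
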