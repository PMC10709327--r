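# Mass-spectrometric chemistry of capped peptides: monoisotopic masses of
# modified peptides, charge-state m/z, b/y fragment series, MRM transition
# design and scrambled-sequence controls.

# Monoisotopic residue (amino-acid minus water) masses, Da. Values follow the
# standard Unimod/expasy monoisotopic table.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.0105646
MASS_PROTON <- 1.00727646
MASS_NH3 <- 17.0265491

# Fixed modification deltas, Da. pyroGlu-from-Gln is loss of NH3 on the
# N-terminal Q; C-terminal amidation replaces -OH with -NH2 (net -0.9840156
# versus the free acid); carbamidomethyl-Cys reflects iodoacetamide
# alkylation of the sample. The pyroGlu + amide deltas cancel the water term
# exactly, so a doubly capped peptide's neutral mass equals its bare residue
# sum.
MOD_DELTAS <- c(
  pyroglu_from_gln = -17.0265491,
  c_amide = -0.9840156,
  carbamidomethyl_cys = 57.0214637
)

#' Monoisotopic residue masses and modification deltas
#'
#' Returns the constants used throughout the mass calculations: standard
#' monoisotopic residue masses for the 20 canonical amino acids, the water,
#' proton and ammonia masses, and the fixed modification deltas
#' (pyroglutamate-from-Gln, C-terminal amide, carbamidomethyl-Cys).
#'
#' @return A named list with elements `residues` (named numeric vector, Da),
#'   `water`, `proton`, `nh3` and `mods` (named numeric vector of deltas, Da).
#' @examples
#' mass_constants()$residues[["G"]]
#' @export
mass_constants <- function() {
  list(
    residues = AA_MONO,
    water = MASS_WATER,
    proton = MASS_PROTON,
    nh3 = MASS_NH3,
    mods = MOD_DELTAS
  )
}

split_residues <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)
}

check_canonical <- function(residues, sequence) {
  bad <- which(!residues %in% names(AA_MONO))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown residue '%s' at position %d of sequence '%s'",
      residues[bad[1]], bad[1], sequence
    ))
  }
  invisible(residues)
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Computes the neutral monoisotopic mass as the sum of residue masses plus
#' water, plus the deltas of the applied modifications. With both caps
#' applied (`pyroglu = TRUE`, `c_amide = TRUE`) the two deltas cancel the
#' water term, so the mass equals the bare residue sum.
#'
#' @param sequence Character vector of peptide sequences (canonical residues
#'   only; a pyroglutamylated peptide is written with its leading `Q`).
#' @param pyroglu Apply the N-terminal pyroglutamate-from-Gln delta
#'   (-17.0265491 Da). Default `TRUE`: this package's peptides are capped.
#' @param c_amide Apply the C-terminal amide delta (-0.9840156 Da).
#' @param carbamidomethyl Apply carbamidomethyl (+57.0214637 Da) to every
#'   cysteine, reflecting iodoacetamide-alkylated samples. Default `TRUE`.
#' @param custom Optional named numeric vector of additional deltas (Da),
#'   each applied once per peptide.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("G", pyroglu = FALSE, c_amide = FALSE) # glycine + water
#' peptide_mass("QFFGLM") # CAP-TAC1, caps cancel water: 723.3414
#' @export
peptide_mass <- function(sequence, pyroglu = TRUE, c_amide = TRUE,
                         carbamidomethyl = TRUE, custom = NULL) {
  stopifnot(is.character(sequence), length(sequence) >= 1)
  res_list <- split_residues(sequence)
  vapply(seq_along(res_list), function(i) {
    res <- res_list[[i]]
    if (length(res) == 0) abort("Empty peptide sequence")
    check_canonical(res, sequence[i])
    m <- sum(AA_MONO[res]) + MASS_WATER
    if (pyroglu) {
      if (res[1] != "Q") {
        abort(sprintf(
          "pyroGlu-from-Gln requires a leading Q (sequence '%s')", sequence[i]
        ))
      }
      m <- m + MOD_DELTAS[["pyroglu_from_gln"]]
    }
    if (c_amide) m <- m + MOD_DELTAS[["c_amide"]]
    if (carbamidomethyl) {
      m <- m + MOD_DELTAS[["carbamidomethyl_cys"]] * sum(res == "C")
    }
    if (!is.null(custom)) m <- m + sum(custom)
    m
  }, numeric(1))
}

#' m/z of an ion from its neutral mass and charge
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (must be positive).
#' @param charge Positive integer charge state.
#' @return `(neutral_mass + charge * proton) / charge`, vectorised.
#' @examples
#' ion_mz(723.3414, 1) # CAP-TAC1 [M+H]+ ~ 724.349
#' @export
ion_mz <- function(neutral_mass, charge = 1) {
  if (any(charge <= 0) || any(charge != round(charge))) {
    abort("`charge` must be a positive integer")
  }
  if (any(neutral_mass <= 0)) abort("`neutral_mass` must be positive")
  (neutral_mass + charge * MASS_PROTON) / charge
}

#' b/y fragment ions of a capped (or control) peptide
#'
#' Computes singly (and optionally multiply) charged b and y ions. N-terminal
#' deltas (pyroGlu) land on the b series; the C-terminal amide replaces the
#' y-series water with ammonia. Carbamidomethyl is applied per cysteine on
#' whichever side carries it.
#'
#' @inheritParams peptide_mass
#' @param series Character vector, subset of `c("b", "y")`.
#' @param max_charge Fragment charge states `1..max_charge` are emitted.
#' @return A tibble with columns `series`, `index`, `charge`, `mz`,
#'   `annotation` (e.g. `"b4+"`, `"y2++"`).
#' @examples
#' fragment_ions("QFFGLM") # CAP-TAC1: the b4+ ion is the Fig.-style 463.2
#' @export
fragment_ions <- function(sequence, pyroglu = TRUE, c_amide = TRUE,
                          carbamidomethyl = TRUE, series = c("b", "y"),
                          max_charge = 1) {
  stopifnot(length(sequence) == 1)
  if (!all(series %in% c("b", "y"))) {
    abort("`series` must be a subset of c('b', 'y')")
  }
  res <- split_residues(sequence)[[1]]
  n <- length(res)
  if (n < 2) abort("Fragmentation requires a peptide of length >= 2")
  check_canonical(res, sequence)
  if (pyroglu && res[1] != "Q") abort("pyroGlu-from-Gln requires a leading Q")

  masses <- unname(AA_MONO[res])
  if (carbamidomethyl) {
    masses[res == "C"] <- masses[res == "C"] + MOD_DELTAS[["carbamidomethyl_cys"]]
  }
  nterm_delta <- if (pyroglu) MOD_DELTAS[["pyroglu_from_gln"]] else 0
  cterm_water <- if (c_amide) MASS_NH3 else MASS_WATER

  rows <- list()
  idx <- seq_len(n - 1)
  if ("b" %in% series) {
    b_neutral <- cumsum(masses)[idx] + nterm_delta
    rows$b <- tibble(series = "b", index = idx, neutral = b_neutral)
  }
  if ("y" %in% series) {
    y_neutral <- rev(cumsum(rev(masses)))[n - idx + 1] + cterm_water
    rows$y <- tibble(series = "y", index = idx, neutral = y_neutral)
  }
  out <- bind_rows(rows)
  out <- tidyr::crossing(out, charge = seq_len(max_charge))
  out %>%
    mutate(
      mz = (.data$neutral + .data$charge * MASS_PROTON) / .data$charge,
      annotation = paste0(
        .data$series, .data$index, strrep("+", .data$charge)
      )
    ) %>%
    select("series", "index", "charge", "mz", "annotation") %>%
    arrange(.data$series, .data$index, .data$charge)
}

#' Build an MRM transition list for predicted capped peptides
#'
#' One default precursor-to-product transition per candidate. When a
#' reference MS/MS spectrum is supplied for a compound, the product ion is
#' the theoretical b/y ion matching the most intense reference peak;
#' otherwise the highest-m/z b or y ion above `floor_mz` is used (mimicking
#' transition design from synthetic-standard spectra). Candidates with no
#' fragment above the floor are flagged and get no product ion.
#'
#' @param candidates A candidate tibble from [predict_capped_peptides()]
#'   (needs `core_sequence` and `capped_notation` columns).
#' @param msms_reference Optional tibble of reference spectra with columns
#'   `compound` (matching `capped_notation`), `mz`, `intensity`.
#' @param floor_mz Minimum product m/z considered (default 200 Da).
#' @param precursor_charge Charge state of the precursor ion (default 1).
#' @param match_tol_da Tolerance for matching reference peaks to theoretical
#'   fragments (default 0.5 Da).
#' @return A tibble: `compound`, `precursor_mz`, `precursor_charge`,
#'   `product_mz`, `product_annotation`, `collision_energy` (NA unless
#'   configured upstream), `flagged`.
#' @export
build_transition_list <- function(candidates, msms_reference = NULL,
                                  floor_mz = 200, precursor_charge = 1,
                                  match_tol_da = 0.5) {
  stopifnot(is.data.frame(candidates))
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    core <- candidates$core_sequence[i]
    compound <- candidates$capped_notation[i]
    prec <- ion_mz(peptide_mass(core), precursor_charge)
    frags <- fragment_ions(core)
    chosen <- NULL
    if (!is.null(msms_reference)) {
      ref <- dplyr::filter(msms_reference, .data$compound == !!compound)
      if (nrow(ref) > 0) {
        ref <- arrange(ref, desc(.data$intensity))
        for (j in seq_len(nrow(ref))) {
          hit <- frags %>%
            filter(abs(.data$mz - ref$mz[j]) <= match_tol_da,
                   .data$mz >= floor_mz)
          if (nrow(hit) > 0) {
            chosen <- slice(arrange(hit, abs(.data$mz - ref$mz[j])), 1)
            break
          }
        }
      }
    }
    if (is.null(chosen)) {
      above <- filter(frags, .data$mz >= floor_mz)
      if (nrow(above) > 0) chosen <- slice(arrange(above, desc(.data$mz)), 1)
    }
    if (is.null(chosen) || nrow(chosen) == 0) {
      tibble(
        compound = compound, precursor_mz = prec,
        precursor_charge = precursor_charge, product_mz = NA_real_,
        product_annotation = NA_character_, collision_energy = NA_real_,
        flagged = TRUE
      )
    } else {
      tibble(
        compound = compound, precursor_mz = prec,
        precursor_charge = precursor_charge, product_mz = chosen$mz,
        product_annotation = chosen$annotation, collision_energy = NA_real_,
        flagged = FALSE
      )
    }
  })
}

#' Scrambled-sequence control peptide
#'
#' Permutes the residues after the leading glutamine, preserving amino-acid
#' composition, for use as a sequence-specificity control. Deterministic for
#' a given seed; guaranteed to differ from the input whenever any distinct
#' permutation exists.
#'
#' @param core_sequence A capped-peptide core beginning with `Q`, length >= 3.
#' @param seed Integer seed.
#' @return A scrambled core sequence (leading `Q` fixed).
#' @examples
#' scramble_control("QLELRLRVAAGR", seed = 1)
#' @export
scramble_control <- function(core_sequence, seed = 1) {
  res <- split_residues(core_sequence)[[1]]
  if (length(res) < 3) abort("Nothing to scramble: need length >= 3")
  if (res[1] != "Q") abort("Core sequence must begin with Q")
  tail_res <- res[-1]
  if (length(unique(tail_res)) == 1) {
    return(core_sequence) # only one permutation exists
  }
  out <- core_sequence
  bump <- 0L
  while (out == core_sequence) {
    set.seed(seed + bump)
    out <- paste0("Q", paste(sample(tail_res), collapse = ""))
    bump <- bump + 1L
  }
  out
}
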