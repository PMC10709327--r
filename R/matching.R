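# Two-step targeted detection: MS1 parent-ion matching at ppm/RT tolerance,
# MRM signal-to-noise validation against an authentic-standard retention
# time, MS/MS daughter-ion confirmation, and external standard-curve
# quantification.

#' Match MS1 features against a target m/z and retention time
#'
#' A feature qualifies when its m/z lies within `ppm_tol` parts-per-million
#' of the target and its retention time within `rt_tol_min` minutes. Matches
#' are ordered best-first: smaller ppm error, then larger area.
#'
#' @param features Tibble of MS1 features: `mz` (Da), `rt` (minutes),
#'   `area`; any further columns (e.g. `sample`) are carried through.
#' @param target_mz,target_rt Target m/z (Da) and retention time (min),
#'   normally those of the authentic synthetic standard.
#' @param ppm_tol Mass tolerance in ppm (default 20).
#' @param rt_tol_min Co-elution tolerance in minutes (default 1).
#' @return Matching rows of `features` with extra columns `ppm_error`
#'   (signed) and `rt_error`, best match first. Empty tibble when nothing
#'   matches.
#' @export
match_ms1 <- function(features, target_mz, target_rt, ppm_tol = 20,
                      rt_tol_min = 1.0) {
  if (ppm_tol <= 0 || rt_tol_min <= 0) abort("Tolerances must be positive")
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) {
    return(mutate(features, ppm_error = numeric(0), rt_error = numeric(0)))
  }
  features %>%
    mutate(
      ppm_error = (.data$mz - target_mz) / target_mz * 1e6,
      rt_error = .data$rt - target_rt
    ) %>%
    filter(abs(.data$ppm_error) <= ppm_tol,
           abs(.data$rt_error) <= rt_tol_min) %>%
    arrange(abs(.data$ppm_error), desc(.data$area))
}

boxcar_smooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)] # keep raw values at the edges
  sm
}

#' Validate an MRM transition trace by signal-to-noise
#'
#' The peak is the maximum intensity inside `peak_window`; the baseline and
#' noise scale come from a disjoint `noise_window`: baseline = median, noise
#' scale = 1.4826 x median absolute deviation (the Gaussian-consistent
#' robust sigma). S/N = (peak - baseline) / noise scale. The trace is
#' validated when S/N exceeds `sn_threshold` (detection rule: > 2.5) and the
#' peak apex falls within `rt_tol_min` of the expected retention time.
#'
#' @param trace Tibble with `time` (minutes, strictly increasing) and
#'   `intensity` columns; `expected_rt` may be a column or passed explicitly.
#' @param peak_window,noise_window Numeric length-2 vectors (minutes),
#'   disjoint, both inside the trace span.
#' @param sn_threshold Signal-to-noise threshold (default 2.5).
#' @param expected_rt Expected retention time of the authentic standard
#'   (minutes); defaults to the trace's `expected_rt` column.
#' @param rt_tol_min Apex co-elution tolerance (default 0.2 min).
#' @param smooth_points Width (in points, made odd) of the boxcar smoother
#'   applied before apex picking and height measurement; light smoothing is
#'   standard practice for chromatographic S/N. Set 1 to disable.
#' @return One-row tibble: `sn`, `apex_rt`, `validated`, `zero_noise`
#'   (TRUE when the noise scale was zero and S/N is reported as `Inf`).
#' @export
validate_mrm <- function(trace, peak_window, noise_window, sn_threshold = 2.5,
                         expected_rt = NULL, rt_tol_min = 0.2,
                         smooth_points = 5) {
  stopifnot(is.data.frame(trace),
            all(c("time", "intensity") %in% names(trace)))
  if (is.unsorted(trace$time, strictly = TRUE)) {
    abort("`trace$time` must be strictly increasing")
  }
  if (length(peak_window) != 2 || length(noise_window) != 2) {
    abort("Windows must be length-2 numeric (min, max)")
  }
  if (max(min(peak_window), min(noise_window)) <
      min(max(peak_window), max(noise_window))) {
    abort("`peak_window` and `noise_window` must be disjoint")
  }
  span <- range(trace$time)
  if (min(peak_window) < span[1] || max(peak_window) > span[2] ||
      min(noise_window) < span[1] || max(noise_window) > span[2]) {
    abort("Windows must lie within the trace time span")
  }
  expected_rt <- expected_rt %||% unique(trace$expected_rt)
  if (length(expected_rt) != 1 || is.na(expected_rt)) {
    abort("A single `expected_rt` is required")
  }

  in_peak <- trace$time >= peak_window[1] & trace$time <= peak_window[2]
  in_noise <- trace$time >= noise_window[1] & trace$time <= noise_window[2]
  if (!any(in_peak) || !any(in_noise)) {
    abort("Windows must contain at least one trace point")
  }
  smoothed <- boxcar_smooth(trace$intensity, smooth_points)
  baseline <- median(trace$intensity[in_noise])
  noise_scale <- mad(trace$intensity[in_noise], constant = 1.4826)
  peak_height <- max(smoothed[in_peak])
  apex_rt <- trace$time[in_peak][which.max(smoothed[in_peak])]

  zero_noise <- noise_scale == 0
  if (zero_noise) {
    warn("Noise scale is zero; S/N reported as Inf")
    sn <- if (peak_height > baseline) Inf else 0
  } else {
    sn <- (peak_height - baseline) / noise_scale
  }
  validated <- sn > sn_threshold && abs(apex_rt - expected_rt) <= rt_tol_min
  tibble(sn = sn, apex_rt = apex_rt, validated = validated,
         zero_noise = zero_noise)
}

#' Count matched daughter ions in an MS/MS spectrum
#'
#' Detection in a full MS/MS scan requires at least one theoretical b/y ion
#' with a spectrum peak within tolerance.
#'
#' @param spectrum Tibble with `mz` (and optionally `intensity`) columns;
#'   may be empty.
#' @param fragments Theoretical fragments from [fragment_ions()] (needs an
#'   `mz` column).
#' @param tol_da Matching tolerance in Da (default 0.5).
#' @return One-row tibble: `n_matched`, `detected` (`n_matched >= 1`).
#' @export
match_msms <- function(spectrum, fragments, tol_da = 0.5) {
  if (tol_da <= 0) abort("`tol_da` must be positive")
  if (is.null(spectrum) || nrow(spectrum) == 0) {
    return(tibble(n_matched = 0L, detected = FALSE))
  }
  n <- sum(vapply(fragments$mz, function(f) {
    any(abs(spectrum$mz - f) <= tol_da)
  }, logical(1)))
  tibble(n_matched = as.integer(n), detected = n >= 1)
}

#' Integrate a chromatographic peak by the trapezoid rule
#'
#' Baseline-subtracted trapezoidal integration of the trace intensity over a
#' retention-time window; the baseline is the median of a disjoint noise
#' window.
#'
#' @param trace Tibble with `time` and `intensity` columns.
#' @param window Length-2 numeric, integration window (minutes).
#' @param noise_window Optional length-2 numeric for baseline estimation;
#'   default uses everything outside the integration window.
#' @return The integrated area (intensity x minutes), floored at 0.
#' @export
integrate_peak <- function(trace, window, noise_window = NULL) {
  stopifnot(all(c("time", "intensity") %in% names(trace)),
            length(window) == 2)
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(sel) < 2) abort("Integration window contains < 2 trace points")
  base_sel <- if (is.null(noise_window)) !sel else {
    trace$time >= noise_window[1] & trace$time <= noise_window[2]
  }
  if (!any(base_sel)) abort("No baseline points available")
  baseline <- median(trace$intensity[base_sel])
  t <- trace$time[sel]
  y <- trace$intensity[sel] - baseline
  max(sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2), 0)
}

#' Fit an external standard curve
#'
#' Ordinary least squares of response area on known concentration.
#'
#' @param curve Tibble with `conc_nM` and `area` columns, >= 3 levels.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(curve) {
  stopifnot(all(c("conc_nM", "area") %in% names(curve)))
  if (length(unique(curve$conc_nM)) < 3) {
    abort("A standard curve needs >= 3 concentration levels")
  }
  fit <- lm(area ~ conc_nM, data = curve)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((curve$area - mean(curve$area))^2)
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_, fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "External standard curve: area = %.4g * conc_nM + %.4g (R^2 = %.4f)\n",
    x$slope, x$intercept, x$r_squared
  ))
  invisible(x)
}

#' Back-calculate concentration from a standard curve
#'
#' @param area Numeric vector of integrated peak areas.
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @return Tibble with `concentration_nM` (negative back-calculations
#'   clipped to 0) and `clipped` flag.
#' @export
quantify <- function(area, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) abort("Unusable standard curve: slope <= 0")
  conc <- (area - curve$intercept) / curve$slope
  clipped <- conc < 0
  conc[clipped] <- 0
  tibble(concentration_nM = conc, clipped = clipped)
}

#' Default detection/matching configuration
#'
#' Tolerances mirror the targeted workflow: 20 ppm MS1 mass window, 1 min
#' co-elution, S/N > 2.5 for MRM, 0.5 Da MS/MS daughter tolerance, 0.2 min
#' MRM apex tolerance.
#'
#' @param ppm_tol,rt_tol_min,sn_threshold,msms_tol_da,mrm_rt_tol_min
#'   Override any default.
#' @return Named list of tolerances.
#' @export
detection_config <- function(ppm_tol = 20, rt_tol_min = 1.0,
                             sn_threshold = 2.5, msms_tol_da = 0.5,
                             mrm_rt_tol_min = 0.2) {
  stopifnot(ppm_tol > 0, rt_tol_min > 0, sn_threshold > 0, msms_tol_da > 0,
            mrm_rt_tol_min > 0)
  list(ppm_tol = ppm_tol, rt_tol_min = rt_tol_min,
       sn_threshold = sn_threshold, msms_tol_da = msms_tol_da,
       mrm_rt_tol_min = mrm_rt_tol_min)
}

#' Two-step targeted detection of one capped-peptide candidate
#'
#' Composes the evidence tiers: (1) MS1 parent-ion match against the feature
#' table at ppm/RT tolerance; (2) MRM transition validation by S/N, only
#' evaluated when an authentic-standard retention time is available; (3)
#' MS/MS daughter-ion confirmation when a spectrum is supplied. Each tier is
#' recorded independently. Concentration is back-calculated from the best
#' MS1 feature's area when a standard curve is given, and only for
#' MS1-matched candidates.
#'
#' @param candidate One-row candidate tibble (from
#'   [predict_capped_peptides()]).
#' @param features MS1 feature tibble (`mz`, `rt`, `area`).
#' @param traces Optional tibble of MRM traces (`compound`, `time`,
#'   `intensity`, `expected_rt`) or NULL.
#' @param spectra Optional tibble of MS/MS spectra (`compound`, `mz`,
#'   `intensity`) or NULL.
#' @param standard_rt Authentic-standard retention time (min); NA when no
#'   standard was run, in which case the MRM tier is "not evaluated".
#' @param curve Optional `standard_curve` for quantification.
#' @param config Tolerances from [detection_config()].
#' @param charge Precursor charge used for the MS1 target (default 1).
#' @return One-row tibble: `compound`, `target_mz`, `ms1_matched`,
#'   `ms1_ppm_error`, `ms1_area`, `mrm_evaluated`, `mrm_validated`,
#'   `mrm_sn`, `msms_daughters_matched`, `msms_detected`,
#'   `concentration_nM`.
#' @export
detect_peptide <- function(candidate, features, traces = NULL, spectra = NULL,
                           standard_rt = NA_real_, curve = NULL,
                           config = detection_config(), charge = 1) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1)
  compound <- candidate$capped_notation
  target_mz <- ion_mz(peptide_mass(candidate$core_sequence), charge)

  ms1_matched <- FALSE
  ms1_ppm <- NA_real_
  ms1_area <- NA_real_
  if (!is.na(standard_rt) && nrow(features) > 0) {
    hits <- match_ms1(features, target_mz, standard_rt,
                      ppm_tol = config$ppm_tol,
                      rt_tol_min = config$rt_tol_min)
    if (nrow(hits) > 0) {
      ms1_matched <- TRUE
      ms1_ppm <- hits$ppm_error[1]
      ms1_area <- hits$area[1]
    }
  }

  mrm_evaluated <- FALSE
  mrm_validated <- FALSE
  mrm_sn <- NA_real_
  if (!is.na(standard_rt) && !is.null(traces)) {
    tr <- dplyr::filter(traces, .data$compound == !!compound)
    if (nrow(tr) > 0) {
      mrm_evaluated <- TRUE
      span <- range(tr$time)
      peak_win <- c(max(span[1], standard_rt - 0.5),
                    min(span[2], standard_rt + 0.5))
      noise_win <- if (peak_win[1] - span[1] >= span[2] - peak_win[2]) {
        c(span[1], peak_win[1] - 1e-9)
      } else {
        c(peak_win[2] + 1e-9, span[2])
      }
      v <- validate_mrm(tr, peak_win, noise_win,
                        sn_threshold = config$sn_threshold,
                        expected_rt = standard_rt,
                        rt_tol_min = config$mrm_rt_tol_min)
      mrm_validated <- v$validated
      mrm_sn <- v$sn
    }
  }

  msms_n <- 0L
  msms_detected <- FALSE
  if (!is.null(spectra)) {
    sp <- dplyr::filter(spectra, .data$compound == !!compound)
    if (nrow(sp) > 0) {
      frags <- fragment_ions(candidate$core_sequence)
      mm <- match_msms(sp, frags, tol_da = config$msms_tol_da)
      msms_n <- mm$n_matched
      msms_detected <- mm$detected
    }
  }

  conc <- NA_real_
  if (ms1_matched && !is.null(curve)) {
    conc <- quantify(ms1_area, curve)$concentration_nM
  }

  tibble(
    compound = compound, target_mz = target_mz,
    ms1_matched = ms1_matched, ms1_ppm_error = ms1_ppm, ms1_area = ms1_area,
    mrm_evaluated = mrm_evaluated, mrm_validated = mrm_validated,
    mrm_sn = mrm_sn, msms_daughters_matched = msms_n,
    msms_detected = msms_detected, concentration_nM = conc
  )
}

#' Detect a whole candidate table
#'
#' Applies [detect_peptide()] to every row of a candidate tibble. The
#' per-candidate standard RT is looked up in `standard_rts` by
#' `capped_notation`.
#'
#' @inheritParams detect_peptide
#' @param candidates Candidate tibble.
#' @param standard_rts Tibble with `compound` and `rt` columns (authentic
#'   standard retention times); candidates without an entry get the MRM tier
#'   "not evaluated" and no MS1 RT gate.
#' @return One row per candidate, columns as [detect_peptide()].
#' @export
detect_peptides <- function(candidates, features, traces = NULL,
                            spectra = NULL, standard_rts = NULL, curve = NULL,
                            config = detection_config(), charge = 1) {
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    rt <- NA_real_
    if (!is.null(standard_rts)) {
      hit <- standard_rts$rt[standard_rts$compound == cand$capped_notation]
      if (length(hit) == 1) rt <- hit
    }
    detect_peptide(cand, features, traces, spectra, standard_rt = rt,
                   curve = curve, config = config, charge = charge)
  })
}
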