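# Pipeline orchestration: a single config drives predict -> chemistry ->
# match -> quantify, writing stage outputs and a reproducible run manifest.

#' Build a pipeline configuration
#'
#' Defaults mirror the targeted workflow's printed tolerances: 20 ppm MS1
#' window, 1 min co-elution, S/N > 2.5, 0.5 Da MS/MS tolerance; prediction
#' window 2..20 residues seeded at glutamine.
#'
#' @param fasta Path to the secretome FASTA (required).
#' @param features Optional path to an MS1 feature CSV
#'   (`mz,rt_min,area,sample`).
#' @param traces Optional path to an MRM trace CSV
#'   (`compound,time_min,intensity,expected_rt`).
#' @param standard_rts Optional path to an authentic-standard RT CSV
#'   (`compound,rt_min`).
#' @param curve Optional path to a standard-curve CSV (`conc_nM,area`).
#' @param ppm_tol,rt_tol_min,sn_threshold,msms_tol_da,mrm_rt_tol_min
#'   Detection tolerances (see [detection_config()]).
#' @param max_length,min_length,nterm_residue Prediction parameters (see
#'   [predict_capped_peptides()]).
#' @param carbamidomethyl Apply fixed carbamidomethyl-Cys in mass
#'   calculations.
#' @param floor_mz MRM product-ion floor (Da).
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list; serialises losslessly to YAML via
#'   [write_config()] / [read_config()].
#' @export
pipeline_config <- function(fasta, features = NULL, traces = NULL,
                            standard_rts = NULL, curve = NULL,
                            ppm_tol = 20, rt_tol_min = 1.0,
                            sn_threshold = 2.5, msms_tol_da = 0.5,
                            mrm_rt_tol_min = 0.2, max_length = 20,
                            min_length = 2, nterm_residue = "Q",
                            carbamidomethyl = TRUE, floor_mz = 200,
                            seed = 1) {
  stopifnot(ppm_tol > 0, rt_tol_min > 0, sn_threshold > 0, msms_tol_da > 0,
            mrm_rt_tol_min > 0)
  structure(
    list(
      fasta = fasta, features = features, traces = traces,
      standard_rts = standard_rts, curve = curve, ppm_tol = ppm_tol,
      rt_tol_min = rt_tol_min, sn_threshold = sn_threshold,
      msms_tol_da = msms_tol_da, mrm_rt_tol_min = mrm_rt_tol_min,
      max_length = max_length, min_length = min_length,
      nterm_residue = nterm_residue, carbamidomethyl = carbamidomethyl,
      floor_mz = floor_mz, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

read_feature_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    rename(rt = "rt_min")
}

read_trace_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    rename(time = "time_min")
}

#' Run the discovery pipeline end to end
#'
#' Executes prediction, transition design and (when feature/trace inputs
#' are configured) two-step detection plus quantification, writing each
#' stage's table and a YAML manifest (config, package version, seed) to the
#' run directory. Stage outputs are identical to running the stages
#' individually with the same configuration; re-running the same config
#' reproduces the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list of the stage tibbles: `predictions`,
#'   `transitions`, and when inputs allow, `detections`.
#' @export
run_discovery <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  proteins <- read_fasta(config$fasta)
  predictions <- predict_capped_peptides(
    proteins, max_length = config$max_length, min_length = config$min_length,
    nterm_residue = config$nterm_residue
  )
  readr::write_tsv(predictions, file.path(out_dir, "predictions.tsv"))

  transitions <- build_transition_list(predictions,
                                       floor_mz = config$floor_mz)
  readr::write_csv(transitions, file.path(out_dir, "transitions.csv"))

  out <- list(predictions = predictions, transitions = transitions)

  if (!is.null(config$features)) {
    features <- read_feature_csv(config$features)
    traces <- if (!is.null(config$traces)) read_trace_csv(config$traces)
    standard_rts <- if (!is.null(config$standard_rts)) {
      readr::read_csv(config$standard_rts, show_col_types = FALSE) %>%
        rename(rt = "rt_min")
    }
    curve <- if (!is.null(config$curve)) {
      fit_standard_curve(readr::read_csv(config$curve,
                                         show_col_types = FALSE))
    }
    det_cfg <- detection_config(
      ppm_tol = config$ppm_tol, rt_tol_min = config$rt_tol_min,
      sn_threshold = config$sn_threshold, msms_tol_da = config$msms_tol_da,
      mrm_rt_tol_min = config$mrm_rt_tol_min
    )
    detections <- detect_peptides(
      predictions, features, traces = traces, standard_rts = standard_rts,
      curve = curve, config = det_cfg
    )
    readr::write_tsv(detections, file.path(out_dir, "detections.tsv"))
    out$detections <- detections
  }

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("cappedpep")),
    seed = config$seed,
    counts = lapply(out, nrow)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out)
}
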