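# One-command pipeline: import -> filter -> calibrate (SiRT landmarks when
# supplied, otherwise CiRT discovery) -> consensus -> transition selection
# -> decoys -> serialization, with a per-stage QC report.

#' Build a pipeline configuration
#'
#' @param psm_path Generic-dialect PSM TSV (or NULL when `table` is passed
#'   to [run_build()] directly).
#' @param spectra_path MGF (or mzML/mzXML) file with the fragment spectra.
#' @param landmarks_path Optional SiRT/CiRT landmark TSV with reference iRT
#'   values; when absent, CiRT landmarks are discovered.
#' @param out_path Output OpenSWATH transition TSV.
#' @param dialect PSM dialect for [read_psm_table()].
#' @param min_score,allowed_charges,require_tryptic PSM filter settings.
#' @param cirt A [cirt_config()].
#' @param transitions A [transition_config()].
#' @param consensus_tol,min_replicate_fraction Consensus parameters.
#' @param min_fragments_annotated,min_replicates Quality-filter thresholds.
#' @param decoy_method,seed Decoy settings.
#' @param sample_type Optional sample-type tag.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(psm_path = NULL, spectra_path = NULL,
                            landmarks_path = NULL, out_path = NULL,
                            dialect = "generic", min_score = NULL,
                            allowed_charges = NULL, require_tryptic = FALSE,
                            cirt = cirt_config(),
                            transitions = transition_config(),
                            consensus_tol = 0.03,
                            min_replicate_fraction = 0.6,
                            min_fragments_annotated = 4L,
                            min_replicates = 1L,
                            decoy_method = "pseudo-reverse", seed = 1L,
                            sample_type = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in intersect(names(y), names(cfg))) {
    if (k == "cirt") {
      cfg$cirt <- do.call(cirt_config, y$cirt)
    } else if (k == "transitions") {
      cfg$transitions <- do.call(transition_config, y$transitions)
    } else {
      cfg[[k]] <- y[[k]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  out <- lapply(config, function(x) {
    if (inherits(x, "cirt_config") || inherits(x, "transition_config")) {
      unclass(x)
    } else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full library-building pipeline
#'
#' @param config A [pipeline_config()].
#' @param table Optional in-memory [psm_table()] (overrides `psm_path`).
#' @param spectra Optional in-memory spectra list (overrides `spectra_path`).
#' @return List of class `build_result`: `library` (an `assay_library`),
#'   `stats` ([library_stats()]), `landmarks`, `fits` (per-run calibration),
#'   and `qc` (per-stage counts).
#' @export
run_build <- function(config, table = NULL, spectra = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s\nQC so far: %s",
                   name, conditionMessage(e),
                   paste(names(qc), unlist(qc), sep = "=", collapse = ", ")),
           call. = FALSE)
    })
  }
  # -- import ---------------------------------------------------------------
  table <- stage("import", {
    if (is.null(table)) {
      if (is.null(config$psm_path) || !file.exists(config$psm_path)) {
        stop("PSM table not found: ", config$psm_path)
      }
      read_psm_table(config$psm_path, dialect = config$dialect,
                     sample_type = config$sample_type)
    } else table
  })
  qc$psms_imported <- nrow(table$records)
  table <- stage("import", {
    if (is.null(spectra)) {
      if (is.null(config$spectra_path) || !file.exists(config$spectra_path)) {
        stop("spectra file not found: ", config$spectra_path)
      }
      attach_spectra(table, config$spectra_path)
    } else attach_spectra(table, spectra)
  })
  qc$psms_with_spectrum <- sum(!vapply(table$spectra, is.null, logical(1)))
  # -- filter ---------------------------------------------------------------
  spectra_attached <- table$spectra
  filtered <- stage("filter", filter_psms(
    table, min_score = config$min_score,
    allowed_charges = config$allowed_charges,
    require_tryptic = config$require_tryptic))
  kept <- table$records$scan_id %in% filtered$records$scan_id
  filtered$spectra <- spectra_attached[kept]
  qc$psms_after_filter <- nrow(filtered$records)
  # -- calibrate ------------------------------------------------------------
  landmarks <- stage("calibrate", {
    if (!is.null(config$landmarks_path)) {
      read_landmarks(config$landmarks_path)
    } else {
      lm <- select_cirt(filtered, config = config$cirt)
      assign_reference_irt(lm)
    }
  })
  qc$n_landmarks <- nrow(landmarks)
  qc$n_empty_bins <- attr(landmarks, "n_empty_bins") %||% NA_integer_
  fits <- stage("calibrate", {
    f <- lapply(filtered$runs$run_id, function(r)
      calibrate_run(filtered, landmarks, run_id = r))
    names(f) <- filtered$runs$run_id
    f
  })
  qc$calibration_r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  irt <- vapply(seq_len(nrow(filtered$records)), function(i) {
    apply_calibration(filtered$records$rt_seconds[i],
                      fits[[filtered$records$run_id[i]]])
  }, numeric(1))
  # -- consensus ------------------------------------------------------------
  consensus <- stage("consensus", {
    groups <- group_by_precursor(filtered)
    lapply(groups, function(g) {
      idx <- match(g$records$scan_id, filtered$records$scan_id)
      build_consensus(g, tol = config$consensus_tol,
                      min_replicate_fraction = config$min_replicate_fraction,
                      irt = irt[idx])
    })
  })
  qc$n_precursors <- length(consensus)
  consensus <- stage("quality_filter", quality_filter(
    consensus, min_fragments_annotated = config$min_fragments_annotated,
    min_replicates = config$min_replicates,
    tol = config$transitions$tol))
  qc$n_precursors_after_qc <- length(consensus)
  # -- assays + decoys ------------------------------------------------------
  lib <- stage("assays", {
    targets <- lapply(consensus, select_transitions,
                      config = config$transitions)
    targets <- Filter(Negate(is.null), targets)
    if (!length(targets)) stop("no precursor yielded transitions")
    qc$n_assay_entries <- length(targets)
    assemble_library(targets, decoy_method = config$decoy_method,
                     seed = config$seed,
                     metadata = list(
                       sample_types = unique(filtered$records$sample_type),
                       consensus_tol = config$consensus_tol,
                       min_replicate_fraction = config$min_replicate_fraction,
                       top_n = config$transitions$top_n))
  })
  stats <- library_stats(lib)
  # -- serialize ------------------------------------------------------------
  if (!is.null(config$out_path)) {
    stage("serialize", write_openswath_tsv(lib, config$out_path))
    qc$library_written <- config$out_path
  }
  structure(list(library = lib, stats = stats, landmarks = landmarks,
                 fits = fits, qc = qc),
            class = "build_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.build_result <- function(x, ...) {
  cat("<build_result>\n")
  cat(sprintf("  transition groups: %d\n  peptides: %d\n  protein groups: %d\n  proteotypic proteins: %d\n",
              x$stats$n_transition_groups, x$stats$n_peptides,
              x$stats$n_protein_groups, x$stats$n_proteotypic_proteins))
  cat(sprintf("  landmarks: %d; calibration r2: %s\n", nrow(x$landmarks),
              paste(sprintf("%.4f", x$qc$calibration_r2), collapse = ", ")))
  invisible(x)
}
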