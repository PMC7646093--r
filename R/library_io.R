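# Library serialization (OpenSWATH transition TSV, TraML), merging and
# partitioning, and scheduled PRM inclusion-list export.

#' Write a library as OpenSWATH transition TSV
#'
#' One row per transition; the column set is the OpenSWATH transition-list
#' dialect (`PrecursorMz`, `ProductMz`, `Tr_recalibrated`,
#' `transition_name`, `LibraryIntensity`, `decoy`, `PeptideSequence`,
#' `FullUniModPeptideName`, `PrecursorCharge`, `ProteinName`,
#' `FragmentType`, `FragmentCharge`, `FragmentSeriesNumber`), plus
#' provenance extras. Unknown extra columns are preserved on read.
#'
#' @param library An `assay_library`.
#' @param path Output file.
#' @export
write_openswath_tsv <- function(library, path) {
  stopifnot(inherits(library, "assay_library"))
  cols <- c(LIBRARY_COLUMNS,
            intersect(names(library$transitions),
                      setdiff(names(library$transitions), LIBRARY_COLUMNS)))
  utils::write.table(library$transitions[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OpenSWATH transition TSV
#'
#' @param path TSV file.
#' @param metadata Optional metadata list for the returned library.
#' @return An `assay_library`.
#' @export
read_openswath_tsv <- function(path, metadata = list()) {
  d <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed transition TSV: ", conditionMessage(e),
                             call. = FALSE))
  miss <- setdiff(LIBRARY_COLUMNS, names(d))
  if (length(miss)) {
    stop("transition TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(d$PrecursorMz) | is.na(d$ProductMz))
  if (length(bad)) {
    stop("malformed transition TSV row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  assay_library(d, metadata)
}

#' Write a library or landmark set as TraML
#'
#' Emits TraML 1.0.0-style XML (PSI transition markup language): one
#' `<Compound>`/`<Peptide>` per precursor with a normalized-retention-time
#' cvParam, and one `<Transition>` per product ion. Landmark sets produce
#' peptide entries with retention-time annotations only.
#'
#' @param x An `assay_library` or `landmark_set`.
#' @param path Output file.
#' @export
write_traml <- function(x, path) {
  root <- xml2::xml_new_root(
    "TraML", version = "1.0.0",
    xmlns = "http://psi.hupo.org/ms/traml")
  cvlist <- xml2::xml_add_child(root, "cvList")
  xml2::xml_add_child(cvlist, "cv", id = "MS",
                      fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology",
                      URI = "http://psidev.info/ms/mzML/psi-ms.obo")
  xml2::xml_add_child(cvlist, "cv", id = "UO",
                      fullName = "Unit Ontology",
                      URI = "http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo")
  add_rt <- function(parent, irt) {
    rtl <- xml2::xml_add_child(parent, "RetentionTimeList")
    rt <- xml2::xml_add_child(rtl, "RetentionTime")
    xml2::xml_add_child(rt, "cvParam", cvRef = "MS", accession = "MS:1000896",
                        name = "normalized retention time",
                        value = sprintf("%.6f", irt))
  }
  if (inherits(x, "landmark_set")) {
    comp <- xml2::xml_add_child(root, "CompoundList")
    for (i in seq_len(nrow(x))) {
      mod_seq <- x$sequence[i]
      pep <- xml2::xml_add_child(
        comp, "Peptide",
        id = sprintf("%s_%d", mod_seq, x$charge[i]),
        sequence = strip_mods(mod_seq))
      xml2::xml_add_child(pep, "cvParam", cvRef = "MS",
                          accession = "MS:1000041", name = "charge state",
                          value = as.character(x$charge[i]))
      add_rt(pep, if (is.na(x$reference_irt[i])) 0 else x$reference_irt[i])
    }
    xml2::xml_add_child(root, "TransitionList")
  } else {
    stopifnot(inherits(x, "assay_library"))
    t <- x$transitions
    entries <- split(t, paste(t$FullUniModPeptideName, t$PrecursorCharge,
                              t$decoy))
    comp <- xml2::xml_add_child(root, "CompoundList")
    for (e in entries) {
      pep_id <- sprintf("%s%s_%d", if (e$decoy[1L] == 1L) "DECOY_" else "",
                        e$FullUniModPeptideName[1L], e$PrecursorCharge[1L])
      pep <- xml2::xml_add_child(comp, "Peptide", id = pep_id,
                                 sequence = e$PeptideSequence[1L])
      xml2::xml_add_child(pep, "cvParam", cvRef = "MS",
                          accession = "MS:1000041", name = "charge state",
                          value = as.character(e$PrecursorCharge[1L]))
      add_rt(pep, if (is.na(e$Tr_recalibrated[1L])) 0 else e$Tr_recalibrated[1L])
    }
    tl <- xml2::xml_add_child(root, "TransitionList")
    for (e in entries) {
      pep_id <- sprintf("%s%s_%d", if (e$decoy[1L] == 1L) "DECOY_" else "",
                        e$FullUniModPeptideName[1L], e$PrecursorCharge[1L])
      for (i in seq_len(nrow(e))) {
        tr <- xml2::xml_add_child(tl, "Transition",
                                  id = e$transition_name[i],
                                  peptideRef = pep_id)
        prec <- xml2::xml_add_child(tr, "Precursor")
        xml2::xml_add_child(prec, "cvParam", cvRef = "MS",
                            accession = "MS:1000827",
                            name = "isolation window target m/z",
                            value = sprintf("%.6f", e$PrecursorMz[i]))
        prod <- xml2::xml_add_child(tr, "Product")
        xml2::xml_add_child(prod, "cvParam", cvRef = "MS",
                            accession = "MS:1000827",
                            name = "isolation window target m/z",
                            value = sprintf("%.6f", e$ProductMz[i]))
        xml2::xml_add_child(tr, "cvParam", cvRef = "MS",
                            accession = "MS:1001226",
                            name = "product ion intensity",
                            value = sprintf("%.6f", e$LibraryIntensity[i]))
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Validate a TraML document against the bundled reduced schema
#'
#' Checks well-formedness and conformance to a reduced TraML 1.0.0 schema
#' shipped with the package (a synthetic, offline-authored subset of the
#' PSI schema covering the elements this toolkit writes).
#'
#' @param path TraML file.
#' @return TRUE invisibly; errors with the validator's messages otherwise.
#' @export
validate_traml <- function(path) {
  doc <- xml2::read_xml(path)
  xsd_path <- system.file("extdata", "traml-reduced-synthetic.xsd",
                          package = "dialib", mustWork = TRUE)
  ok <- xml2::xml_validate(doc, xml2::read_xml(xsd_path))
  if (!ok) {
    stop("TraML validation failed: ",
         paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

#' PRM schedule configuration
#'
#' @param rt_halfwidth_minutes Half-width of the scheduled acquisition
#'   window (default 5 min, i.e. +/- 5 min around the predicted RT).
#' @param max_concurrent_precursors Warn when more precursor windows than
#'   this overlap at any time point (default 100).
#' @param include_transitions Also return per-transition rows.
#' @return Object of class `prm_config`.
#' @export
prm_config <- function(rt_halfwidth_minutes = 5,
                       max_concurrent_precursors = 100L,
                       include_transitions = FALSE) {
  stopifnot(rt_halfwidth_minutes > 0, max_concurrent_precursors >= 1L)
  structure(list(rt_halfwidth_minutes = rt_halfwidth_minutes,
                 max_concurrent_precursors = as.integer(max_concurrent_precursors),
                 include_transitions = isTRUE(include_transitions)),
            class = "prm_config")
}

#' Export a scheduled PRM inclusion list
#'
#' For each requested peptide present in the library, the predicted RT
#' center is the library iRT mapped back through the inverse calibration;
#' the acquisition window is center +/- the configured half-width.
#' Retention times are reported in minutes (instrument convention).
#'
#' @param library An `assay_library`.
#' @param targets Character vector of peptide sequences (modified or
#'   stripped) to schedule.
#' @param fit A `calibration_fit` mapping RT (s) -> iRT for the intended
#'   acquisition gradient; its inverse predicts RT.
#' @param config A [prm_config()].
#' @param path Optional output TSV path.
#' @return Data frame with columns `Mass [m/z]`, `z`, `Start [min]`,
#'   `End [min]`, `Polarity`, `Comment`; peptides not found are listed in
#'   `attr(, "missing")`; a concurrency warning is raised when more windows
#'   overlap than configured.
#' @export
export_prm_schedule <- function(library, targets, fit,
                                config = prm_config(), path = NULL) {
  stopifnot(inherits(library, "assay_library"),
            inherits(fit, "calibration_fit"))
  t <- library$transitions[library$transitions$decoy == 0L, , drop = FALSE]
  hit <- t$FullUniModPeptideName %in% targets | t$PeptideSequence %in% targets
  missing <- setdiff(targets,
                     union(t$FullUniModPeptideName, t$PeptideSequence))
  t <- t[hit, , drop = FALSE]
  prec <- unique(t[c("FullUniModPeptideName", "PrecursorCharge",
                     "PrecursorMz", "Tr_recalibrated", "ProteinName")])
  center_min <- invert_calibration(prec$Tr_recalibrated, fit) / 60
  out <- data.frame(
    `Mass [m/z]` = prec$PrecursorMz,
    z = prec$PrecursorCharge,
    `Start [min]` = center_min - config$rt_halfwidth_minutes,
    `End [min]` = center_min + config$rt_halfwidth_minutes,
    Polarity = "Positive",
    Comment = sprintf("%s (%s)", prec$FullUniModPeptideName, prec$ProteinName),
    check.names = FALSE
  )
  if (nrow(out)) {
    events <- rbind(data.frame(t = out$`Start [min]`, d = 1L),
                    data.frame(t = out$`End [min]`, d = -1L))
    events <- events[order(events$t, -events$d), ]
    peak <- max(cumsum(events$d))
    if (peak > config$max_concurrent_precursors) {
      warning(sprintf("up to %d precursor windows overlap (limit %d)",
                      peak, config$max_concurrent_precursors), call. = FALSE)
    }
  }
  if (length(missing)) {
    warning(length(missing), " requested peptide(s) absent from the library",
            call. = FALSE)
  }
  attr(out, "missing") <- missing
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Merge assay libraries
#'
#' Merge is keyed on the target precursor (modified sequence, charge).
#' Conflicts are resolved by `conflict_rule`: keep the entry with the
#' higher best identification score (default), the one with more
#' replicates, or the first seen. A decoy survives iff its target does.
#'
#' @param libraries List of `assay_library` objects, in merge order.
#' @param conflict_rule One of `"higher_best_score"`, `"more_replicates"`,
#'   `"keep_first"`.
#' @return Merged `assay_library`.
#' @export
merge_libraries <- function(libraries,
                            conflict_rule = c("higher_best_score",
                                              "more_replicates", "keep_first")) {
  conflict_rule <- match.arg(conflict_rule)
  stopifnot(length(libraries) >= 1L,
            all(vapply(libraries, inherits, logical(1), "assay_library")))
  chosen <- list()   # key -> list(target = df, decoy = df or NULL, order = i)
  better <- function(new, old) {
    switch(conflict_rule,
           keep_first = FALSE,
           higher_best_score =
             isTRUE(new$target$best_score[1L] > old$target$best_score[1L]),
           more_replicates =
             isTRUE(new$target$n_replicates[1L] > old$target$n_replicates[1L]))
  }
  for (lib in libraries) {
    t <- lib$transitions
    tg <- t[t$decoy == 0L, , drop = FALSE]
    dc <- t[t$decoy == 1L, , drop = FALSE]
    # decoys are paired to targets via the shared transition_name suffix
    dkey <- sub("^DECOY_", "", dc$transition_name)
    for (e in split(tg, paste(tg$FullUniModPeptideName, tg$PrecursorCharge))) {
      key <- paste(e$FullUniModPeptideName[1L], e$PrecursorCharge[1L])
      pair_decoy <- dc[dkey %in% e$transition_name, , drop = FALSE]
      cand <- list(target = e,
                   decoy = if (nrow(pair_decoy)) pair_decoy else NULL)
      if (is.null(chosen[[key]]) || better(cand, chosen[[key]])) {
        chosen[[key]] <- cand
      }
    }
  }
  transitions <- do.call(rbind, unlist(lapply(chosen, function(x)
    list(x$target, x$decoy)), recursive = FALSE))
  rownames(transitions) <- NULL
  meta <- libraries[[1L]]$metadata
  meta$merged_from <- length(libraries)
  meta$conflict_rule <- conflict_rule
  assay_library(transitions, meta)
}

#' Subset a library
#'
#' @param library An `assay_library`.
#' @param sample_types,proteins,peptides Optional filters; an entry is kept
#'   when it matches all supplied filters (protein match is by accession
#'   substring within the `;`-joined annotation). Decoys survive iff their
#'   target does.
#' @return Subset `assay_library`.
#' @export
subset_library <- function(library, sample_types = NULL, proteins = NULL,
                           peptides = NULL) {
  stopifnot(inherits(library, "assay_library"))
  t <- library$transitions
  tg <- t[t$decoy == 0L, , drop = FALSE]
  keep <- rep(TRUE, nrow(tg))
  if (!is.null(sample_types)) keep <- keep & tg$sample_type %in% sample_types
  if (!is.null(proteins)) {
    keep <- keep & vapply(strsplit(tg$ProteinName, ";", fixed = TRUE),
                          function(p) any(p %in% proteins), logical(1))
  }
  if (!is.null(peptides)) {
    keep <- keep & (tg$FullUniModPeptideName %in% peptides |
                      tg$PeptideSequence %in% peptides)
  }
  kept_names <- tg$transition_name[keep]
  dc <- t[t$decoy == 1L, , drop = FALSE]
  dc_keep <- sub("^DECOY_", "", dc$transition_name) %in% kept_names
  out <- rbind(tg[keep, , drop = FALSE], dc[dc_keep, , drop = FALSE])
  rownames(out) <- NULL
  assay_library(out, library$metadata)
}
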