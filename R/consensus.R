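# Consensus spectrum building: one representative MS2 spectrum per peptide
# precursor, aggregated across replicate identifications.

#' Group PSMs (with attached spectra) by precursor
#'
#' @param table A [psm_table()] after [attach_spectra()]; records without a
#'   spectrum are ignored.
#' @return List of `replicate_group` objects, each with the precursor
#'   `sequence`/`charge`, member `records` (data frame), `spectra` (list),
#'   `proteins` (union of member annotations) and `sample_type`.
#' @export
group_by_precursor <- function(table) {
  stopifnot(inherits(table, "psm_table"))
  if (is.null(table$spectra)) {
    stop("spectra not attached; call attach_spectra() first", call. = FALSE)
  }
  has <- !vapply(table$spectra, is.null, logical(1))
  rec <- table$records[has, , drop = FALSE]
  spec <- table$spectra[has]
  if (!nrow(rec)) return(list())
  key <- paste(rec$sequence, rec$charge, sep = "/")
  idx <- split(seq_len(nrow(rec)), key)
  lapply(idx, function(i) {
    structure(list(
      sequence = rec$sequence[i[1L]],
      charge = rec$charge[i[1L]],
      records = rec[i, , drop = FALSE],
      spectra = spec[i],
      proteins = sort(unique(unlist(strsplit(rec$proteins[i], ";", fixed = TRUE)))),
      sample_type = rec$sample_type[i[1L]]
    ), class = "replicate_group")
  })
}

# Drop peaks within +/- halfwidth of the precursor m/z (library hygiene).
strip_precursor_region <- function(s, prec_mz, halfwidth = 1.5) {
  if (is.na(prec_mz)) return(s)
  keep <- abs(s$mz - prec_mz) > halfwidth
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Build a consensus spectrum for a replicate group
#'
#' Peaks are clustered greedily across replicates: the highest-intensity
#' unclustered peak seeds a cluster that absorbs the nearest unclustered
#' peak within `tol` from each other replicate. Clusters observed in at
#' least `min_replicate_fraction` of replicates are kept (the fraction rule
#' applies only from 3 replicates up; with 2, peaks of either member are
#' kept). Consensus m/z is the intensity-weighted mean, consensus intensity
#' the median of member intensities. Peaks within 1.5 Th of the precursor
#' m/z are removed first.
#'
#' @param group A `replicate_group` from [group_by_precursor()].
#' @param tol Peak clustering tolerance in Th (default 0.03).
#' @param min_replicate_fraction Minimum fraction of replicates a peak must
#'   appear in (default 0.6).
#' @param irt Optional calibrated iRT values, one per member; the consensus
#'   stores their median.
#' @return Object of class `consensus_spectrum`: precursor identity, peak
#'   vectors `mz`/`intensity`, `n_replicates`, `best_score`, `irt`,
#'   `proteins`, `sample_type`.
#' @export
build_consensus <- function(group, tol = 0.03, min_replicate_fraction = 0.6,
                            irt = NULL) {
  stopifnot(inherits(group, "replicate_group"), length(group$spectra) >= 1L)
  n_rep <- length(group$spectra)
  prec_mz <- precursor_mz(group$sequence, group$charge)
  members <- lapply(group$spectra, strip_precursor_region, prec_mz = prec_mz)
  irt_out <- if (is.null(irt)) NA_real_ else stats::median(irt)
  if (n_rep == 1L) {
    s <- members[[1L]]
    cons_mz <- s$mz
    cons_int <- s$intensity
  } else {
    pool <- data.frame(
      mz = unlist(lapply(members, `[[`, "mz")),
      intensity = unlist(lapply(members, `[[`, "intensity")),
      replicate = rep(seq_len(n_rep),
                      vapply(members, function(s) length(s$mz), integer(1)))
    )
    pool$free <- TRUE
    need <- if (n_rep >= 3L) ceiling(min_replicate_fraction * n_rep) else 1L
    cons_mz <- numeric()
    cons_int <- numeric()
    while (any(pool$free)) {
      seed <- which(pool$free)[which.max(pool$intensity[pool$free])]
      cluster <- seed
      for (r in setdiff(seq_len(n_rep), pool$replicate[seed])) {
        j <- which(pool$free & pool$replicate == r &
                     abs(pool$mz - pool$mz[seed]) <= tol)
        if (length(j)) {
          cluster <- c(cluster, j[which.min(abs(pool$mz[j] - pool$mz[seed]))])
        }
      }
      pool$free[cluster] <- FALSE
      if (length(cluster) >= need) {
        w <- pool$intensity[cluster]
        cons_mz <- c(cons_mz, sum(pool$mz[cluster] * w) / sum(w))
        cons_int <- c(cons_int, stats::median(w))
      }
    }
    o <- order(cons_mz)
    cons_mz <- cons_mz[o]
    cons_int <- cons_int[o]
  }
  structure(list(
    sequence = group$sequence, charge = group$charge,
    mz = cons_mz, intensity = cons_int,
    n_replicates = n_rep,
    best_score = max(group$records$score),
    irt = irt_out,
    proteins = group$proteins,
    sample_type = group$sample_type
  ), class = "consensus_spectrum")
}

#' @export
print.consensus_spectrum <- function(x, ...) {
  cat(sprintf("<consensus_spectrum> %s/%d: %d peak(s), %d replicate(s), iRT %.2f\n",
              x$sequence, x$charge, length(x$mz), x$n_replicates, x$irt))
  invisible(x)
}

#' Filter low-quality consensus spectra
#'
#' @param consensus_list List of `consensus_spectrum` objects.
#' @param min_fragments_annotated Minimum number of consensus peaks matching
#'   theoretical b/y ions (default 4).
#' @param min_replicates Minimum replicate support (default 1).
#' @param tol Annotation match tolerance in Th.
#' @return Filtered list; removal counts in `attr(, "removed")`.
#' @export
quality_filter <- function(consensus_list, min_fragments_annotated = 4L,
                           min_replicates = 1L, tol = 0.03) {
  n_annot <- vapply(consensus_list, function(cs) {
    ions <- annotate_fragments(cs$sequence)
    m <- match_peaks(cs, ions, tol = tol)
    sum(!is.na(m$peak_index))
  }, integer(1))
  n_rep <- vapply(consensus_list, `[[`, integer(1), "n_replicates")
  keep <- n_annot >= min_fragments_annotated & n_rep >= min_replicates
  out <- consensus_list[keep]
  attr(out, "removed") <- c(
    low_annotation = sum(n_annot < min_fragments_annotated),
    low_replicates = sum(n_rep < min_replicates & n_annot >= min_fragments_annotated)
  )
  out
}

#' Export consensus spectra as MSP-style text
#'
#' @param consensus_list List of `consensus_spectrum` objects.
#' @param path Output file.
#' @export
write_msp <- function(consensus_list, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cs in consensus_list) {
    writeLines(sprintf("Name: %s/%d", cs$sequence, cs$charge), con)
    writeLines(sprintf("PrecursorMZ: %.6f",
                       precursor_mz(cs$sequence, cs$charge)), con)
    writeLines(sprintf("Comment: iRT=%.4f Nreps=%d Protein=%s",
                       cs$irt, cs$n_replicates,
                       paste(cs$proteins, collapse = ";")), con)
    writeLines(sprintf("Num peaks: %d", length(cs$mz)), con)
    if (length(cs$mz)) writeLines(sprintf("%.6f\t%.6f", cs$mz, cs$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}
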