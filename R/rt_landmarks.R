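# Endogenous retention-time landmark (CiRT) discovery and robust affine
# RT -> iRT calibration.
#
# CiRT peptides replace synthetic spike-in (SiRT) standards: abundant,
# unmodified, proteotypic endogenous peptides at charge 2-3 whose retention
# times tile the LC gradient. The gradient window is split into equal-width
# bins and the most intense qualifying precursor is picked per bin.

#' CiRT selection configuration
#'
#' @param n_bins Number of equal-width gradient bins (default 20); one
#'   landmark is picked per non-empty bin.
#' @param intensity_quantile Precursors must exceed this sample quantile of
#'   all quantified precursor intensities (default 0.75, the 3rd quartile;
#'   type-7 linear-interpolation quantile).
#' @param allowed_charges Precursor charges admitted (default 2 and 3).
#' @param require_unmodified Drop modified sequences (default TRUE).
#' @param require_proteotypic Keep only peptides mapping to exactly one
#'   protein accession (default TRUE).
#' @return Object of class `cirt_config`.
#' @export
cirt_config <- function(n_bins = 20L, intensity_quantile = 0.75,
                        allowed_charges = c(2L, 3L),
                        require_unmodified = TRUE,
                        require_proteotypic = TRUE) {
  stopifnot(n_bins >= 2L, intensity_quantile > 0, intensity_quantile < 1)
  structure(list(n_bins = as.integer(n_bins),
                 intensity_quantile = intensity_quantile,
                 allowed_charges = as.integer(allowed_charges),
                 require_unmodified = isTRUE(require_unmodified),
                 require_proteotypic = isTRUE(require_proteotypic)),
            class = "cirt_config")
}

#' Select CiRT landmark peptides from a PSM table
#'
#' Candidate precursors must be (1) proteotypic, (2) unmodified,
#' (3) more intense than the configured quantile of all quantified
#' precursors, and (4) of allowed charge; (5) uniform gradient coverage is
#' enforced by equal-width binning of the observed RT span with one pick --
#' the most intense candidate (ties: higher score, then lexicographically
#' first sequence) -- per bin.
#'
#' @param table A [psm_table()] whose records carry `precursor_intensity`.
#' @param proteotypicity Optional named logical vector (stripped sequence ->
#'   is proteotypic). When absent, a peptide is proteotypic iff its
#'   `proteins` field lists exactly one accession.
#' @param config A [cirt_config()].
#' @return A `landmark_set`: data frame with columns `sequence`, `charge`,
#'   `median_rt`, `intensity`, `reference_irt` (NA until assigned),
#'   `source`; `attr(, "n_empty_bins")` counts empty bins.
#' @export
select_cirt <- function(table, proteotypicity = NULL, config = cirt_config()) {
  stopifnot(inherits(table, "psm_table"), inherits(config, "cirt_config"))
  rec <- table$records
  quantified <- rec[!is.na(rec$precursor_intensity), , drop = FALSE]
  if (!nrow(quantified)) {
    stop("precursor intensities are required for CiRT selection", call. = FALSE)
  }
  # collapse to precursor level: max intensity, max score, median RT
  key <- paste(quantified$sequence, quantified$charge, sep = "/")
  prec <- do.call(rbind, lapply(split(quantified, key), function(d) {
    data.frame(sequence = d$sequence[1L], charge = d$charge[1L],
               stripped = d$stripped_sequence[1L],
               proteins = d$proteins[1L],
               median_rt = stats::median(d$rt_seconds),
               intensity = max(d$precursor_intensity),
               score = max(d$score))
  }))
  threshold <- stats::quantile(prec$intensity, config$intensity_quantile,
                               type = 7, names = FALSE)
  is_proteotypic <- if (!is.null(proteotypicity)) {
    unname(proteotypicity[prec$stripped])
  } else {
    !grepl(";", prec$proteins, fixed = TRUE)
  }
  is_proteotypic[is.na(is_proteotypic)] <- FALSE
  keep <- prec$intensity > threshold &
    prec$charge %in% config$allowed_charges
  if (config$require_unmodified) keep <- keep & prec$sequence == prec$stripped
  if (config$require_proteotypic) keep <- keep & is_proteotypic
  cand <- prec[keep, , drop = FALSE]
  if (!nrow(cand)) {
    stop("no precursor satisfies the CiRT candidate criteria", call. = FALSE)
  }
  span <- range(cand$median_rt)
  if (diff(span) <= 0) {
    bin <- rep(1L, nrow(cand))
  } else {
    edges <- seq(span[1L], span[2L], length.out = config$n_bins + 1L)
    bin <- findInterval(cand$median_rt, edges, rightmost.closed = TRUE)
  }
  picks <- do.call(rbind, lapply(split(cand, bin), function(d) {
    d <- d[order(-d$intensity, -d$score, d$sequence), , drop = FALSE]
    d[1L, , drop = FALSE]
  }))
  n_empty <- config$n_bins - length(unique(bin))
  if (n_empty > 0.25 * config$n_bins) {
    warning(sprintf("%d of %d gradient bins have no CiRT candidate",
                    n_empty, config$n_bins), call. = FALSE)
  }
  out <- data.frame(sequence = picks$sequence, charge = picks$charge,
                    median_rt = picks$median_rt, intensity = picks$intensity,
                    reference_irt = NA_real_, source = "CiRT")
  out <- out[order(out$median_rt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("landmark_set", "data.frame")
  attr(out, "n_empty_bins") <- n_empty
  attr(out, "intensity_threshold") <- threshold
  out
}

#' Assign reference iRT values to a landmark set
#'
#' With a SiRT-anchored calibration fit, each landmark's reference iRT is
#' the fit evaluated at its median RT in the reference run. Without an
#' anchor, landmark RTs are min-max scaled onto \[0, 100\], the customary
#' iRT span.
#'
#' @param landmarks A `landmark_set` from [select_cirt()] or
#'   [read_landmarks()].
#' @param anchor A `calibration_fit` (see [fit_irt_map()]) or `NULL`.
#' @param reference_rt Optional named numeric vector (\code{"sequence/charge"}
#'   -> RT seconds in the reference run); defaults to the set's `median_rt`.
#' @return The landmark set with `reference_irt` filled in; landmarks absent
#'   from the reference run are dropped with a warning.
#' @export
assign_reference_irt <- function(landmarks, anchor = NULL,
                                 reference_rt = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  rts <- if (is.null(reference_rt)) {
    landmarks$median_rt
  } else {
    unname(reference_rt[paste(landmarks$sequence, landmarks$charge, sep = "/")])
  }
  seen <- !is.na(rts)
  if (any(!seen)) {
    warning(sum(!seen), " landmark(s) not observed in the reference run; dropped",
            call. = FALSE)
  }
  landmarks <- landmarks[seen, , drop = FALSE]
  rts <- rts[seen]
  if (nrow(landmarks) < 3L) {
    stop("fewer than 3 landmarks observed in the reference run", call. = FALSE)
  }
  if (!is.null(anchor)) {
    stopifnot(inherits(anchor, "calibration_fit"))
    landmarks$reference_irt <- apply_calibration(rts, anchor)
  } else {
    span <- range(rts)
    if (diff(span) <= 0) stop("degenerate landmark RT range", call. = FALSE)
    landmarks$reference_irt <- (rts - span[1L]) / diff(span) * 100
  }
  rownames(landmarks) <- NULL
  class(landmarks) <- c("landmark_set", "data.frame")
  landmarks
}

#' Fit a robust affine RT -> iRT calibration
#'
#' Ordinary least squares followed by iterative outlier rejection: points
#' with absolute residual above 3 times the median absolute deviation of the
#' residuals are dropped and the line refit, to a fixpoint (at most 5
#' rounds).
#'
#' @param rt_seconds Observed retention times (s).
#' @param reference_irt Matching reference iRT values.
#' @param keys Optional identifiers reported for rejected points.
#' @return Object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `n_points_used`, `outlier_keys`.
#' @export
fit_irt_map <- function(rt_seconds, reference_irt, keys = NULL) {
  stopifnot(length(rt_seconds) == length(reference_irt))
  if (length(rt_seconds) < 3L) {
    stop("at least 3 landmark pairs are required", call. = FALSE)
  }
  if (stats::sd(rt_seconds) == 0) {
    stop("degenerate fit: zero retention-time variance", call. = FALSE)
  }
  if (is.null(keys)) keys <- as.character(seq_along(rt_seconds))
  keep <- rep(TRUE, length(rt_seconds))
  for (round in seq_len(5L)) {
    fit <- stats::lm(reference_irt[keep] ~ rt_seconds[keep])
    res <- stats::residuals(fit)
    s <- stats::mad(res)
    if (s < 1e-9) break
    bad <- abs(res) > 3 * s
    if (!any(bad)) break
    idx <- which(keep)
    keep[idx[bad]] <- FALSE
    if (sum(keep) < 3L) {
      stop("fewer than 3 landmarks survive outlier rejection", call. = FALSE)
    }
  }
  fit <- stats::lm(reference_irt[keep] ~ rt_seconds[keep])
  co <- unname(stats::coef(fit))
  # suppressed: summary.lm warns on numerically perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = co[2L], intercept = co[1L],
                 r_squared = r2,
                 n_points_used = sum(keep),
                 outlier_keys = keys[!keep]),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> iRT = %.6g * RT + %.6g (r2 = %.4f, n = %d, %d outlier(s))\n",
              x$slope, x$intercept, x$r_squared, x$n_points_used,
              length(x$outlier_keys)))
  invisible(x)
}

#' Apply a calibration to retention times
#'
#' @param rt_seconds Retention times (s).
#' @param fit A `calibration_fit`.
#' @return iRT values.
#' @export
apply_calibration <- function(rt_seconds, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$slope * rt_seconds + fit$intercept
}

#' Invert a calibration: iRT -> retention time
#'
#' @param irt iRT values.
#' @param fit A `calibration_fit`.
#' @return Retention times in seconds.
#' @export
invert_calibration <- function(irt, fit) {
  stopifnot(inherits(fit, "calibration_fit"), fit$slope != 0)
  (irt - fit$intercept) / fit$slope
}

#' Calibrate a run against a landmark set
#'
#' Matches the run's PSMs to the landmarks by (sequence, charge), takes the
#' median observed RT per landmark, and fits [fit_irt_map()].
#'
#' @param table A [psm_table()] (a single run, or pass `run_id`).
#' @param landmarks A `landmark_set` with `reference_irt` assigned.
#' @param run_id Optional run to restrict to.
#' @return A `calibration_fit`.
#' @export
calibrate_run <- function(table, landmarks, run_id = NULL) {
  stopifnot(inherits(table, "psm_table"), inherits(landmarks, "landmark_set"))
  if (anyNA(landmarks$reference_irt)) {
    stop("landmarks have no reference iRT; call assign_reference_irt() first",
         call. = FALSE)
  }
  rec <- table$records
  if (!is.null(run_id)) rec <- rec[rec$run_id == run_id, , drop = FALSE]
  key <- paste(rec$sequence, rec$charge, sep = "/")
  lkey <- paste(landmarks$sequence, landmarks$charge, sep = "/")
  obs <- vapply(lkey, function(k) {
    hit <- rec$rt_seconds[key == k]
    if (length(hit)) stats::median(hit) else NA_real_
  }, numeric(1))
  seen <- !is.na(obs)
  if (sum(seen) < 3L) {
    stop("fewer than 3 landmarks observed in the run", call. = FALSE)
  }
  fit_irt_map(obs[seen], landmarks$reference_irt[seen], keys = lkey[seen])
}

#' Read / write landmark sets as TSV
#'
#' Columns: `sequence`, `charge`, `reference_irt`, `source` (and
#' `median_rt`, `intensity` when present).
#'
#' @param path TSV file.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "charge", "reference_irt", "source")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("landmark file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(d$median_rt)) d$median_rt <- NA_real_
  if (is.null(d$intensity)) d$intensity <- NA_real_
  d <- d[c("sequence", "charge", "median_rt", "intensity", "reference_irt",
           "source")]
  class(d) <- c("landmark_set", "data.frame")
  d
}

#' @rdname read_landmarks
#' @param landmarks A `landmark_set`.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  utils::write.table(as.data.frame(landmarks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
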