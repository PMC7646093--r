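# Reading, validating and filtering peptide-spectrum-match tables, and
# linking them to fragment spectra. The canonical internal retention-time
# unit is seconds; dialects that report minutes are converted on ingest.

GENERIC_PSM_COLUMNS <- c("scan_id", "run_id", "rt_seconds", "sequence",
                         "charge", "proteins", "score",
                         "precursor_intensity", "sample_type")

#' Construct a PSM table
#'
#' @param records Data frame with one row per peptide-spectrum match and
#'   columns `scan_id`, `run_id`, `rt_seconds`, `sequence` (modified
#'   sequence in UniMod bracket notation), `stripped_sequence`, `charge`,
#'   `proteins` (accessions joined by `;`), `score`, `precursor_intensity`,
#'   `sample_type`.
#' @param runs Data frame with columns `run_id`, `gradient_seconds`.
#' @return Object of class `psm_table`.
#' @export
psm_table <- function(records, runs = NULL) {
  need <- c("scan_id", "run_id", "rt_seconds", "sequence", "charge",
            "proteins", "score")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("psm_table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$precursor_intensity)) records$precursor_intensity <- NA_real_
  if (is.null(records$sample_type)) records$sample_type <- "unknown"
  if (is.null(records$stripped_sequence)) {
    records$stripped_sequence <- strip_mods(records$sequence)
  }
  if (nrow(records) && any(!nzchar(records$proteins))) {
    stop("every PSM must carry at least one protein accession", call. = FALSE)
  }
  if (is.null(runs)) {
    runs <- data.frame(run_id = unique(records$run_id),
                       gradient_seconds = NA_real_)
  }
  if (nrow(records) && !all(records$run_id %in% runs$run_id)) {
    stop("record run_id absent from run metadata", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, runs = runs), class = "psm_table")
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("<psm_table> %d PSMs, %d run(s), %d precursor(s)\n",
              nrow(x$records), nrow(x$runs),
              nrow(unique(x$records[c("sequence", "charge")]))))
  invisible(x)
}

#' Strip modification tags from sequences
#'
#' @param x Character vector of modified sequences.
#' @return Bare residue sequences.
#' @export
strip_mods <- function(x) gsub("\\[[^]]*\\]", "", x)

# Column maps per dialect: input name -> internal name.
.psm_dialects <- list(
  generic = list(
    map = c(scan_id = "scan_id", run_id = "run_id", rt_seconds = "rt_seconds",
            sequence = "sequence", charge = "charge", proteins = "proteins",
            score = "score", precursor_intensity = "precursor_intensity",
            sample_type = "sample_type"),
    required = c("scan_id", "run_id", "rt_seconds", "sequence", "charge",
                 "proteins", "score"),
    rt_unit = "seconds"),
  `pfind-style` = list(
    map = c(File_Name = "scan_id", Run = "run_id", RT = "rt_seconds",
            Sequence = "sequence", Charge = "charge", Proteins = "proteins",
            Final_Score = "score", Intensity = "precursor_intensity",
            Sample_Type = "sample_type"),
    required = c("File_Name", "Run", "RT", "Sequence", "Charge", "Proteins",
                 "Final_Score"),
    rt_unit = "seconds"),
  `maxquant-peptides` = list(
    map = c(`MS.MS.scan.number` = "scan_id", `Raw.file` = "run_id",
            `Retention.time` = "rt_seconds", Sequence = "sequence",
            Charge = "charge", Proteins = "proteins", Score = "score",
            Intensity = "precursor_intensity", Sample_Type = "sample_type"),
    required = c("Sequence", "Charge", "Proteins", "Score", "Retention.time"),
    rt_unit = "minutes")
)

#' Read a PSM table from a TSV file
#'
#' @param path Tab-separated file.
#' @param dialect One of `"generic"`, `"pfind-style"`,
#'   `"maxquant-peptides"`. The MaxQuant dialect reports retention times in
#'   minutes; they are converted to seconds.
#' @param sample_type Optional tag overriding/filling the sample type column.
#' @param gradient_seconds Optional named vector of gradient lengths per run.
#' @return A [psm_table()]. Rows whose sequence fails to parse are skipped;
#'   the number skipped is available as `attr(x, "n_skipped")`.
#' @export
read_psm_table <- function(path, dialect = "generic", sample_type = NULL,
                           gradient_seconds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dia <- .psm_dialects[[match.arg(dialect, names(.psm_dialects))]]
  raw <- utils::read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(make.names(dia$required), names(raw))
  if (length(miss)) {
    stop("PSM table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  present <- intersect(make.names(names(dia$map)), names(raw))
  out <- raw[present]
  names(out) <- unname(dia$map[match(present, make.names(names(dia$map)))])
  if (is.null(out$scan_id)) out$scan_id <- as.character(seq_len(nrow(out)))
  if (is.null(out$run_id)) out$run_id <- "run1"
  out$scan_id <- as.character(out$scan_id)
  out$run_id <- as.character(out$run_id)
  if (dia$rt_unit == "minutes") out$rt_seconds <- out$rt_seconds * 60
  if (!is.null(sample_type)) out$sample_type <- sample_type
  # normalize modification notation; skip unparseable rows with a count
  ok <- vapply(out$sequence, function(s) {
    !inherits(tryCatch(parse_modified_sequence(s), error = identity), "error")
  }, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(n_skipped, " row(s) with unparseable sequences skipped",
            call. = FALSE)
    out <- out[ok, , drop = FALSE]
  }
  out$sequence <- vapply(out$sequence, function(s)
    format_modified_sequence(parse_modified_sequence(s)), character(1))
  runs <- data.frame(run_id = unique(out$run_id),
                     gradient_seconds = NA_real_)
  if (!is.null(gradient_seconds)) {
    runs$gradient_seconds <- unname(gradient_seconds[runs$run_id])
  }
  res <- psm_table(out, runs)
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Write a PSM table in the generic TSV dialect
#'
#' @param table A [psm_table()].
#' @param path Output file.
#' @export
write_psm_table <- function(table, path) {
  stopifnot(inherits(table, "psm_table"))
  utils::write.table(table$records[GENERIC_PSM_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter PSM records
#'
#' Each criterion is applied independently; removal counts per criterion are
#' attached as `attr(x, "removed")`.
#'
#' @param table A [psm_table()].
#' @param min_score Minimum identification score (NULL = off; upstream FDR
#'   control is assumed).
#' @param allowed_charges Integer vector of precursor charges to keep
#'   (NULL = all).
#' @param require_tryptic If TRUE and the records carry `previous_aa` /
#'   `next_aa` context columns, drop peptides violating the K/R-not-before-P
#'   rule; a no-op without context columns.
#' @return Filtered [psm_table()].
#' @export
filter_psms <- function(table, min_score = NULL, allowed_charges = NULL,
                        require_tryptic = FALSE) {
  stopifnot(inherits(table, "psm_table"))
  rec <- table$records
  removed <- c(score = 0L, charge = 0L, tryptic = 0L)
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(min_score)) {
    fail <- rec$score < min_score
    removed["score"] <- sum(fail & keep)
    keep <- keep & !fail
  }
  if (!is.null(allowed_charges)) {
    fail <- !rec$charge %in% allowed_charges
    removed["charge"] <- sum(fail & keep)
    keep <- keep & !fail
  }
  if (require_tryptic && all(c("previous_aa", "next_aa") %in% names(rec))) {
    last_res <- substr(rec$stripped_sequence, nchar(rec$stripped_sequence),
                       nchar(rec$stripped_sequence))
    nterm_ok <- rec$previous_aa %in% c("K", "R", "-") &
      substr(rec$stripped_sequence, 1, 1) != "P"
    cterm_ok <- (last_res %in% c("K", "R") & rec$next_aa != "P") |
      rec$next_aa == "-"
    fail <- !(nterm_ok & cterm_ok)
    removed["tryptic"] <- sum(fail & keep)
    keep <- keep & !fail
  }
  out <- psm_table(rec[keep, , drop = FALSE], table$runs)
  attr(out, "removed") <- removed
  out
}

#' Attach fragment spectra to PSM records
#'
#' @param table A [psm_table()].
#' @param spectra Either a list of [spectrum()] objects, a path to an MGF
#'   file, or a path to an mzML/mzXML file (read via the mzR package when
#'   installed). Spectra are keyed by `scan_id` (and `run_id` when the
#'   spectra carry one in their scan id as `"run:scan"`).
#' @return The table with a `spectra` element: a list parallel to
#'   `records`, `NULL` where the scan was not found; unmatched scan ids in
#'   `attr(, "unmatched")`.
#' @export
attach_spectra <- function(table, spectra) {
  stopifnot(inherits(table, "psm_table"))
  if (is.character(spectra) && length(spectra) == 1L) {
    ext <- tolower(tools::file_ext(spectra))
    spectra <- if (ext == "mgf") read_mgf(spectra) else read_mzml_spectra(spectra)
  }
  ids <- vapply(spectra, function(s) s$scan_id, character(1))
  idx <- match(table$records$scan_id, ids)
  if (all(is.na(idx))) {
    stop("no PSM scan id matches the spectra source (wrong file pairing?)",
         call. = FALSE)
  }
  table$spectra <- lapply(idx, function(i) if (is.na(i)) NULL else spectra[[i]])
  attr(table, "unmatched") <- table$records$scan_id[is.na(idx)]
  table
}

#' Read an MGF peak-list file
#'
#' @param path MGF file.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(begins) == length(ends))
  lapply(seq_along(begins), function(k) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    kv <- strsplit(hdr, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
    peaks <- do.call(rbind, strsplit(trimws(block[!is_hdr]), "[ \t]+"))
    mz <- if (is.null(peaks)) numeric() else as.numeric(peaks[, 1L])
    int <- if (is.null(peaks)) numeric() else as.numeric(peaks[, 2L])
    pep <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(vals[keys == "PEPMASS"], " ")[[1L]][1L])
    } else NA_real_
    z <- if ("CHARGE" %in% keys) {
      as.integer(sub("[+-]$", "", vals[keys == "CHARGE"]))
    } else NA_integer_
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[keys == "RTINSECONDS"])
    } else NA_real_
    sid <- if ("TITLE" %in% keys) vals[keys == "TITLE"] else as.character(k)
    spectrum(mz, int, scan_id = sid, rt_seconds = rt, precursor_mz = pep,
             precursor_charge = z)
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$scan_id), con)
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    }
    if (!is.na(s$precursor_charge)) {
      writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    }
    if (!is.na(s$rt_seconds)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$rt_seconds), con)
    }
    if (length(s$mz)) {
      writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# mzML/mzXML via mzR when available.
read_mzml_spectra <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML/mzXML requires the mzR package; ",
         "supply spectra as an MGF file or a list of spectrum objects",
         call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(hdr)), function(i) {
    spectrum(pk[[i]][, 1L], pk[[i]][, 2L],
             scan_id = as.character(hdr$acquisitionNum[i]),
             rt_seconds = hdr$retentionTime[i],
             precursor_mz = hdr$precursorMZ[i],
             precursor_charge = hdr$precursorCharge[i])
  })
}
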