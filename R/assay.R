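# Transition assay generation: top-N product-ion selection from consensus
# spectra and pseudo-reverse decoy appending.
#
# The assay library is held flat: one row per transition, in the OpenSWATH
# transition-TSV column dialect, with a metadata list for provenance.

#' Transition selection configuration
#'
#' @param top_n Maximum product ions per precursor (default 6).
#' @param fragment_mz_min,fragment_mz_max Product m/z bounds (default
#'   300-1800 Th).
#' @param precursor_exclusion_halfwidth Products within this distance of
#'   the precursor m/z are excluded (default 9 Th, about half a DIA
#'   isolation window).
#' @param allowed_series Fragment series (default b and y).
#' @param allowed_fragment_charges Fragment charges (default 1 and 2).
#' @param tol Peak annotation tolerance in Th (default 0.03).
#' @return Object of class `transition_config`.
#' @export
transition_config <- function(top_n = 6L, fragment_mz_min = 300,
                              fragment_mz_max = 1800,
                              precursor_exclusion_halfwidth = 9,
                              allowed_series = c("b", "y"),
                              allowed_fragment_charges = c(1L, 2L),
                              tol = 0.03) {
  stopifnot(top_n >= 1L, fragment_mz_min < fragment_mz_max)
  structure(list(top_n = as.integer(top_n),
                 fragment_mz_min = fragment_mz_min,
                 fragment_mz_max = fragment_mz_max,
                 precursor_exclusion_halfwidth = precursor_exclusion_halfwidth,
                 allowed_series = allowed_series,
                 allowed_fragment_charges = as.integer(allowed_fragment_charges),
                 tol = tol),
            class = "transition_config")
}

LIBRARY_COLUMNS <- c("PrecursorMz", "ProductMz", "Tr_recalibrated",
                     "transition_name", "LibraryIntensity", "decoy",
                     "PeptideSequence", "FullUniModPeptideName",
                     "PrecursorCharge", "ProteinName", "FragmentType",
                     "FragmentCharge", "FragmentSeriesNumber")
LIBRARY_EXTRA_COLUMNS <- c("sample_type", "n_replicates", "best_score")

#' Select the top-N transitions for a consensus spectrum
#'
#' Consensus peaks are annotated with theoretical b/y ions; candidates
#' outside the product m/z bounds or within the precursor exclusion window
#' are discarded; the remainder are ranked by library intensity (ties:
#' lower product m/z) and the top `top_n` kept.
#'
#' @param consensus A `consensus_spectrum`.
#' @param config A [transition_config()].
#' @return Data frame of transition rows (the OpenSWATH columns plus
#'   provenance extras), or `NULL` when no candidate survives the filters.
#' @export
select_transitions <- function(consensus, config = transition_config()) {
  stopifnot(inherits(consensus, "consensus_spectrum"),
            inherits(config, "transition_config"))
  prec_mz <- precursor_mz(consensus$sequence, consensus$charge)
  ions <- annotate_fragments(consensus$sequence,
                             max_fragment_charge = max(config$allowed_fragment_charges))
  ions <- ions[ions$series %in% config$allowed_series &
                 ions$charge %in% config$allowed_fragment_charges, , drop = FALSE]
  m <- match_peaks(consensus, ions, tol = config$tol)
  m <- m[!is.na(m$peak_index), , drop = FALSE]
  m <- m[m$mz >= config$fragment_mz_min & m$mz <= config$fragment_mz_max &
           abs(m$mz - prec_mz) > config$precursor_exclusion_halfwidth, ,
         drop = FALSE]
  if (!nrow(m)) return(NULL)  # rejected: nothing annotatable in range
  m <- m[order(-m$peak_intensity, m$mz), , drop = FALSE]
  m <- m[seq_len(min(config$top_n, nrow(m))), , drop = FALSE]
  stripped <- strip_mods(consensus$sequence)
  data.frame(
    PrecursorMz = prec_mz,
    ProductMz = m$mz,
    Tr_recalibrated = consensus$irt,
    transition_name = sprintf("%s_%s_%d", m$annotation, consensus$sequence,
                              consensus$charge),
    LibraryIntensity = m$peak_intensity,
    decoy = 0L,
    PeptideSequence = stripped,
    FullUniModPeptideName = consensus$sequence,
    PrecursorCharge = consensus$charge,
    ProteinName = paste(consensus$proteins, collapse = ";"),
    FragmentType = m$series,
    FragmentCharge = m$charge,
    FragmentSeriesNumber = m$ordinal,
    sample_type = consensus$sample_type,
    n_replicates = consensus$n_replicates,
    best_score = consensus$best_score
  )
}

#' Pseudo-reverse a peptide (decoy sequence scheme)
#'
#' Residues 1..n-1 are reversed, the C-terminal residue is fixed;
#' modifications travel with their residues (N-terminal modifications stay
#' N-terminal).
#'
#' @param pep A [peptide()] or modified-sequence string.
#' @return A [peptide()].
#' @export
pseudo_reverse <- function(pep) {
  if (is.character(pep)) pep <- parse_modified_sequence(pep)
  n <- nchar(pep$sequence)
  res <- strsplit(pep$sequence, "")[[1]]
  perm <- c(rev(seq_len(n - 1L)), n)  # new position i holds old residue perm[i]
  new_seq <- paste(res[perm], collapse = "")
  mods <- pep$mods
  if (nrow(mods)) {
    internal <- mods$position > 0L
    mods$position[internal] <- match(mods$position[internal], perm)
  }
  peptide(new_seq, mods)
}

# Shuffle of residues 1..n-1 (palindrome fallback); uses the session RNG,
# seeded by assemble_library().
shuffle_prefix <- function(pep) {
  n <- nchar(pep$sequence)
  res <- strsplit(pep$sequence, "")[[1]]
  perm <- c(sample(seq_len(n - 1L)), n)
  mods <- pep$mods
  if (nrow(mods)) {
    internal <- mods$position > 0L
    mods$position[internal] <- match(mods$position[internal], perm)
  }
  peptide(paste(res[perm], collapse = ""), mods)
}

#' Generate a decoy assay for a target entry
#'
#' The decoy keeps the target's precursor m/z, library intensities and iRT;
#' product m/z values are recomputed for the same (series, ordinal, charge)
#' annotations on the pseudo-reversed sequence. If pseudo-reversal
#' reproduces the target sequence, a seeded shuffle of residues 1..n-1 is
#' attempted (up to 10 tries).
#'
#' @param entry Transition rows of one target precursor
#'   (from [select_transitions()]).
#' @param method `"pseudo-reverse"` (default) or `"shuffle"`.
#' @return Decoy transition rows, or `NULL` if no distinct decoy sequence
#'   could be produced (counted as a failure by [assemble_library()]).
#' @export
generate_decoy <- function(entry, method = c("pseudo-reverse", "shuffle")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(entry), all(entry$decoy == 0L))
  target <- parse_modified_sequence(entry$FullUniModPeptideName[1L])
  decoy_pep <- if (method == "pseudo-reverse") {
    pseudo_reverse(target)
  } else {
    shuffle_prefix(target)
  }
  tries <- 0L
  while (format_modified_sequence(decoy_pep) == format_modified_sequence(target) &&
         tries < 10L) {
    decoy_pep <- shuffle_prefix(target)
    tries <- tries + 1L
  }
  if (format_modified_sequence(decoy_pep) == format_modified_sequence(target)) {
    return(NULL)  # decoy failure: degenerate composition, counted upstream
  }
  ions <- annotate_fragments(decoy_pep,
                             max_fragment_charge = max(entry$FragmentCharge))
  key <- paste(ions$series, ions$ordinal, ions$charge)
  want <- paste(entry$FragmentType, entry$FragmentSeriesNumber,
                entry$FragmentCharge)
  decoy_seq <- format_modified_sequence(decoy_pep)
  out <- entry
  out$ProductMz <- ions$mz[match(want, key)]
  out$decoy <- 1L
  out$PeptideSequence <- strip_mods(decoy_seq)
  out$FullUniModPeptideName <- decoy_seq
  out$transition_name <- paste0("DECOY_", entry$transition_name)
  out$ProteinName <- paste0("DECOY_",
                            strsplit(entry$ProteinName[1L], ";")[[1]],
                            collapse = ";")
  out
}

#' Assemble a library from target entries, appending decoys
#'
#' @param targets List of transition data frames (one per precursor, from
#'   [select_transitions()]), or a single data frame of target transitions.
#' @param decoy_method Passed to [generate_decoy()].
#' @param seed Integer seed for the shuffle fallback.
#' @param metadata Named list merged into the library metadata.
#' @return Object of class `assay_library`: list with `transitions` (data
#'   frame) and `metadata`.
#' @export
assemble_library <- function(targets, decoy_method = "pseudo-reverse",
                             seed = 1L, metadata = list()) {
  if (is.data.frame(targets)) {
    targets <- split(targets,
                     paste(targets$FullUniModPeptideName, targets$PrecursorCharge))
  }
  targets <- Filter(Negate(is.null), targets)
  if (!length(targets)) stop("no target entries", call. = FALSE)
  set.seed(seed)
  decoys <- lapply(targets, generate_decoy, method = decoy_method)
  n_failed <- sum(vapply(decoys, is.null, logical(1)))
  transitions <- do.call(rbind, c(targets, Filter(Negate(is.null), decoys)))
  rownames(transitions) <- NULL
  meta <- utils::modifyList(list(
    decoy_method = decoy_method, seed = seed,
    n_targets = length(targets),
    n_decoys = length(targets) - n_failed,
    n_decoy_failures = n_failed,
    fragment_series = "b/y", fragment_charges = "1-2",
    tool = paste0("dialib ", as.character(utils::packageVersion("dialib")))
  ), metadata)
  assay_library(transitions, meta)
}

#' Construct an assay library object
#'
#' @param transitions Data frame with the OpenSWATH transition columns.
#' @param metadata Named provenance list.
#' @return Object of class `assay_library`.
#' @export
assay_library <- function(transitions, metadata = list()) {
  miss <- setdiff(LIBRARY_COLUMNS, names(transitions))
  if (length(miss)) {
    stop("library missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in LIBRARY_EXTRA_COLUMNS) {
    if (is.null(transitions[[col]])) {
      transitions[[col]] <- switch(col, sample_type = "unknown",
                                   n_replicates = NA_integer_,
                                   best_score = NA_real_)
    }
  }
  if (anyDuplicated(transitions$transition_name)) {
    stop("transition names must be unique within a library", call. = FALSE)
  }
  rownames(transitions) <- NULL
  structure(list(transitions = transitions, metadata = metadata),
            class = "assay_library")
}

#' @export
print.assay_library <- function(x, ...) {
  s <- library_stats(x)
  cat(sprintf("<assay_library> %d transitions; %d transition groups, %d peptides (targets); %d decoy transitions\n",
              nrow(x$transitions), s$n_transition_groups, s$n_peptides,
              sum(x$transitions$decoy == 1L)))
  invisible(x)
}

# Per-precursor split of target transitions, in stable order.
target_entries <- function(library) {
  t <- library$transitions[library$transitions$decoy == 0L, , drop = FALSE]
  split(t, paste(t$FullUniModPeptideName, t$PrecursorCharge))
}
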