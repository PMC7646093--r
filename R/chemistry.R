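# Peptide mass and fragment-ion chemistry.
#
# Monoisotopic masses only: the libraries this toolkit targets are built from
# high-resolution Orbitrap data. Fragmentation is restricted to singly and
# doubly charged b/y ions, the convention of OpenSWATH-style assay libraries.

#' Monoisotopic mass constants
#'
#' Published monoisotopic residue masses for the 20 canonical amino acids,
#' plus the masses of water and a proton, all in Dalton.
#'
#' @format A list with elements `residues` (named numeric vector),
#'   `water` and `proton`.
#' @export
MASS_CONSTANTS <- local({
  residues <- c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
  list(residues = residues, water = 18.010565, proton = 1.007276)
})

# Bundled UniMod subset: id -> monoisotopic mass delta (Da).
UNIMOD_DELTAS <- c(
  "1"  = 42.010565,   # Acetyl
  "4"  = 57.021464,   # Carbamidomethyl
  "7"  = 0.984016,    # Deamidated
  "21" = 79.966331,   # Phospho
  "35" = 15.994915    # Oxidation
)

#' Construct a modified peptide
#'
#' @param sequence Uppercase string over the 20 canonical residues.
#' @param mods Data frame with columns `position` (1-based residue index, or
#'   0 for the N-terminus), `unimod_id` (integer) and `mass_delta` (Da).
#'   May be `NULL` for an unmodified peptide.
#' @return An object of class `peptide`.
#' @export
peptide <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(MASS_CONSTANTS$residues))
  if (length(bad)) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), unimod_id = integer(),
                       mass_delta = numeric())
  }
  stopifnot(all(c("position", "unimod_id", "mass_delta") %in% names(mods)))
  if (nrow(mods)) {
    if (any(mods$position < 0L | mods$position > nchar(sequence))) {
      stop("modification position outside [0, peptide length]", call. = FALSE)
    }
    if (anyDuplicated(mods$position)) {
      stop("at most one modification per position", call. = FALSE)
    }
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(sequence = sequence, mods = mods), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", format_modified_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Parse a modified peptide sequence
#'
#' Accepts bracketed UniMod tags (`"C[UniMod:4]AR"`) and bracketed mass
#' deltas (`"C[+57.0215]AR"`, resolved to the nearest bundled UniMod entry
#' within 0.01 Da). A leading tag before the first residue is taken as an
#' N-terminal modification (position 0).
#'
#' @param text Modified sequence string.
#' @return A [peptide()].
#' @export
parse_modified_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty peptide sequence", call. = FALSE)
  pos <- 0L
  chars <- character()
  mods <- list()
  i <- 1L
  n <- nchar(text)
  take_tag <- function(i) {
    # returns list(next_i, unimod_id, delta) for a bracketed tag at i
    close <- regexpr("]", substr(text, i, n), fixed = TRUE)
    if (close < 0) stop("unterminated modification tag in '", text, "'",
                        call. = FALSE)
    tag <- substr(text, i + 1L, i + close - 2L)
    if (grepl("^UniMod:\\d+$", tag)) {
      id <- sub("^UniMod:", "", tag)
      if (!id %in% names(UNIMOD_DELTAS)) {
        stop("unsupported modification UniMod:", id, call. = FALSE)
      }
      list(i = i + close, id = as.integer(id), delta = unname(UNIMOD_DELTAS[id]))
    } else if (grepl("^[+-]?\\d+(\\.\\d+)?$", tag)) {
      delta <- as.numeric(tag)
      hit <- which(abs(UNIMOD_DELTAS - delta) < 0.01)
      if (!length(hit)) {
        stop("unsupported modification mass delta ", tag, call. = FALSE)
      }
      id <- names(UNIMOD_DELTAS)[hit[1L]]
      list(i = i + close, id = as.integer(id), delta = unname(UNIMOD_DELTAS[id]))
    } else {
      stop("unrecognized modification tag '[", tag, "]'", call. = FALSE)
    }
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      tag <- take_tag(i)
      mods[[length(mods) + 1L]] <- data.frame(
        position = pos, unimod_id = tag$id, mass_delta = tag$delta)
      i <- tag$i
    } else {
      if (!ch %in% names(MASS_CONSTANTS$residues)) {
        stop("non-canonical residue '", ch, "' in '", text, "'", call. = FALSE)
      }
      pos <- pos + 1L
      chars[pos] <- ch
      i <- i + 1L
    }
  }
  if (!pos) stop("no residues in '", text, "'", call. = FALSE)
  mods <- if (length(mods)) do.call(rbind, mods) else NULL
  peptide(paste(chars, collapse = ""), mods)
}

#' Format a peptide in canonical UniMod bracket notation
#'
#' @param pep A [peptide()].
#' @return String such as `"C[UniMod:4]AR"`.
#' @export
format_modified_sequence <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  residues <- strsplit(pep$sequence, "")[[1]]
  out <- residues
  if (nrow(pep$mods)) {
    for (k in seq_len(nrow(pep$mods))) {
      p <- pep$mods$position[k]
      tag <- sprintf("[UniMod:%d]", pep$mods$unimod_id[k])
      if (p == 0L) {
        out[1L] <- paste0(tag, out[1L])
      } else {
        out[p] <- paste0(out[p], tag)
      }
    }
  }
  paste(out, collapse = "")
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses, one water, and all modification deltas.
#'
#' @param pep A [peptide()] or a modified-sequence string.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(pep) {
  if (is.character(pep)) pep <- parse_modified_sequence(pep)
  stopifnot(inherits(pep, "peptide"))
  residues <- strsplit(pep$sequence, "")[[1]]
  sum(MASS_CONSTANTS$residues[residues]) + MASS_CONSTANTS$water +
    sum(pep$mods$mass_delta)
}

#' Precursor m/z
#'
#' @param pep A [peptide()] or modified-sequence string.
#' @param charge Positive integer precursor charge.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(pep, charge) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (monoisotopic_mass(pep) + charge * MASS_CONSTANTS$proton) / charge
}

#' Annotate theoretical b/y fragment ions
#'
#' Enumerates all b_i and y_i ions (i in 1..n-1) at fragment charges
#' 1..`max_fragment_charge`. N-terminal modifications are carried by the b
#' series; each internal modification travels with its residue.
#'
#' @param pep A [peptide()] or modified-sequence string.
#' @param max_fragment_charge Highest fragment charge (default 2).
#' @return Data frame with columns `series`, `ordinal`, `charge`, `mz`,
#'   `annotation` (e.g. `"y7^1"`).
#' @export
annotate_fragments <- function(pep, max_fragment_charge = 2L) {
  if (is.character(pep)) pep <- parse_modified_sequence(pep)
  stopifnot(inherits(pep, "peptide"))
  residues <- strsplit(pep$sequence, "")[[1]]
  n <- length(residues)
  if (n < 2L) stop("peptide must have at least 2 residues", call. = FALSE)
  res_mass <- unname(MASS_CONSTANTS$residues[residues])
  mod_at <- numeric(n + 1L)  # index p+1 holds delta at position p (0 = N-term)
  if (nrow(pep$mods)) mod_at[pep$mods$position + 1L] <- pep$mods$mass_delta
  per_res <- res_mass + mod_at[-1L]
  nterm <- mod_at[1L]
  b_neutral <- cumsum(per_res)[seq_len(n - 1L)] + nterm
  y_neutral <- cumsum(rev(per_res))[seq_len(n - 1L)] + MASS_CONSTANTS$water
  out <- do.call(rbind, lapply(seq_len(max_fragment_charge), function(z) {
    rbind(
      data.frame(series = "b", ordinal = seq_len(n - 1L), charge = z,
                 mz = (b_neutral + z * MASS_CONSTANTS$proton) / z),
      data.frame(series = "y", ordinal = seq_len(n - 1L), charge = z,
                 mz = (y_neutral + z * MASS_CONSTANTS$proton) / z)
    )
  }))
  out$annotation <- sprintf("%s%d^%d", out$series, out$ordinal, out$charge)
  rownames(out) <- NULL
  out
}

#' Match theoretical ions against spectrum peaks
#'
#' Greedy nearest-neighbour assignment: ion/peak pairs within `tol` are
#' assigned in order of increasing m/z error; each peak satisfies at most one
#' ion. Exact distance ties are broken by lower ordinal, b before y.
#'
#' @param spectrum A [spectrum()] (or list with numeric `mz`, `intensity`).
#' @param ions Fragment table from [annotate_fragments()].
#' @param tol Match tolerance in Th (default 0.03, the DIA extraction
#'   tolerance used throughout the toolkit).
#' @return `ions` with added columns `peak_index`, `peak_mz`,
#'   `peak_intensity` (NA where unmatched).
#' @export
match_peaks <- function(spectrum, ions, tol = 0.03) {
  stopifnot(tol > 0)
  mz <- spectrum$mz
  ions$peak_index <- NA_integer_
  ions$peak_mz <- NA_real_
  ions$peak_intensity <- NA_real_
  if (!length(mz) || !nrow(ions)) return(ions)
  cand <- do.call(rbind, lapply(seq_len(nrow(ions)), function(i) {
    d <- abs(mz - ions$mz[i])
    j <- which(d <= tol)
    if (!length(j)) return(NULL)
    data.frame(ion = i, peak = j, err = d[j])
  }))
  if (is.null(cand)) return(ions)
  pref <- order(cand$err,
                match(ions$series[cand$ion], c("b", "y")),
                ions$ordinal[cand$ion])
  used_peak <- logical(length(mz))
  used_ion <- logical(nrow(ions))
  for (k in pref) {
    i <- cand$ion[k]; j <- cand$peak[k]
    if (used_ion[i] || used_peak[j]) next
    used_ion[i] <- TRUE
    used_peak[j] <- TRUE
    ions$peak_index[i] <- j
    ions$peak_mz[i] <- mz[j]
    ions$peak_intensity[i] <- spectrum$intensity[j]
  }
  ions
}

#' Construct a centroided spectrum
#'
#' @param mz Numeric vector of peak m/z values (Th).
#' @param intensity Matching non-negative intensities.
#' @param scan_id Scan identifier string.
#' @param rt_seconds Retention time in seconds.
#' @param precursor_mz,precursor_charge Optional precursor annotation.
#' @return An object of class `spectrum` with peaks sorted by m/z.
#' @export
spectrum <- function(mz, intensity, scan_id = "", rt_seconds = NA_real_,
                     precursor_mz = NA_real_, precursor_charge = NA_integer_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  if (length(mz) && any(mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 scan_id = scan_id, rt_seconds = rt_seconds,
                 precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> scan=%s peaks=%d rt=%.1fs\n",
              x$scan_id, length(x$mz), x$rt_seconds))
  invisible(x)
}
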