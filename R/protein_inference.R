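# Parsimony protein grouping, proteotypicity, library statistics and the
# median-intensity protein abundance rollup.
#
# A protein group is either (i) one protein identified by a peptide set not
# contained in any other protein's set, or (ii) several proteins sharing the
# same set, or a subset, of identified peptides. Peptides mapping to exactly
# one accession are proteotypic; a Swiss-Prot-canonical protein with at
# least one proteotypic peptide counts as a proteotypic protein.

#' Build a peptide -> protein map
#'
#' @param peptides Character vector of peptide sequences.
#' @param proteins Parallel vector of `;`-joined accession strings (or a
#'   list of character vectors).
#' @return Named list: peptide -> character vector of accessions.
#' @export
peptide_protein_map <- function(peptides, proteins) {
  if (!is.list(proteins)) proteins <- strsplit(proteins, ";", fixed = TRUE)
  stopifnot(length(peptides) == length(proteins))
  m <- tapply(proteins, peptides, function(x) sort(unique(unlist(x))),
              simplify = FALSE)
  m <- lapply(m, identity)
  if (any(!lengths(m))) stop("peptide with no accession", call. = FALSE)
  m
}

#' Build parsimony protein groups
#'
#' Accessions are inverted to peptide sets; accessions with identical sets
#' are merged; an accession whose set is a strict subset of another's is
#' absorbed into that superset's group (to transitive closure). Where a set
#' is a subset of several incomparable supersets, the group with the larger
#' peptide set wins; ties go to the lexicographically smaller representative.
#'
#' @param map Peptide -> accessions map from [peptide_protein_map()].
#' @return Data frame with one row per group: `representative`, `members`
#'   (`;`-joined), `n_members`, `peptides` (`;`-joined), `n_peptides`.
#' @export
build_protein_groups <- function(map) {
  stopifnot(length(map) > 0L)
  acc2pep <- list()
  for (pep in names(map)) {
    for (acc in map[[pep]]) acc2pep[[acc]] <- c(acc2pep[[acc]], pep)
  }
  acc2pep <- lapply(acc2pep, function(x) sort(unique(x)))
  accs <- sort(names(acc2pep))
  sets <- acc2pep[accs]
  # merge identical sets
  sig <- vapply(sets, paste, character(1), collapse = "\r")
  merged <- split(accs, sig)
  reps <- vapply(merged, `[`, character(1), 1L)
  rep_sets <- sets[reps]
  # absorb strict subsets into their (preferred) superset
  n <- length(reps)
  owner <- seq_len(n)
  size <- lengths(rep_sets)
  for (i in seq_len(n)) {
    supers <- which(vapply(seq_len(n), function(j) {
      j != i && size[j] > size[i] && all(rep_sets[[i]] %in% rep_sets[[j]])
    }, logical(1)))
    if (length(supers)) {
      best <- supers[order(-size[supers], reps[supers])][1L]
      owner[i] <- best
    }
  }
  # transitive closure: follow owner chains to their roots
  root <- function(i) { while (owner[i] != i) i <- owner[i]; i }
  roots <- vapply(seq_len(n), root, integer(1))
  out <- do.call(rbind, lapply(sort(unique(roots)), function(r) {
    members <- sort(unlist(merged[roots == r], use.names = FALSE))
    peps <- sort(unique(unlist(sets[members], use.names = FALSE)))
    data.frame(
      representative = min(members),
      members = paste(members, collapse = ";"),
      n_members = length(members),
      peptides = paste(peps, collapse = ";"),
      n_peptides = length(peps)
    )
  }))
  out <- out[order(out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag proteotypic peptides and proteins
#'
#' @param map Peptide -> accessions map.
#' @param swissprot_canonical Optional character vector of accessions that
#'   are Swiss-Prot canonical; defaults to all accessions in the map.
#' @return List with `peptides` (data frame: `peptide`, `accession` for
#'   each proteotypic pair) and `proteins` (character vector of proteotypic
#'   canonical accessions).
#' @export
flag_proteotypic <- function(map, swissprot_canonical = NULL) {
  single <- lengths(map) == 1L
  pairs <- data.frame(peptide = names(map)[single],
                      accession = unlist(map[single], use.names = FALSE))
  if (is.null(swissprot_canonical)) {
    swissprot_canonical <- sort(unique(unlist(map, use.names = FALSE)))
  }
  prots <- sort(unique(pairs$accession[pairs$accession %in% swissprot_canonical]))
  list(peptides = pairs, proteins = prots)
}

#' Headline library statistics
#'
#' Counts (over target entries only): distinct transition groups (modified
#' sequence x charge), distinct modified peptide sequences (stripped
#' sequences reported alongside), protein groups, and proteotypic
#' Swiss-Prot-canonical proteins.
#'
#' @param library An `assay_library`.
#' @param swissprot_canonical Optional canonical accession vector (see
#'   [flag_proteotypic()]); defaults to accessions with a `sp|` FASTA-style
#'   prefix, or all accessions when none has one.
#' @return List with `n_transition_groups`, `n_peptides`,
#'   `n_stripped_peptides`, `n_protein_groups`, `n_proteotypic_proteins`.
#' @export
library_stats <- function(library, swissprot_canonical = NULL) {
  stopifnot(inherits(library, "assay_library"))
  t <- library$transitions[library$transitions$decoy == 0L, , drop = FALSE]
  if (!nrow(t)) {
    return(list(n_transition_groups = 0L, n_peptides = 0L,
                n_stripped_peptides = 0L, n_protein_groups = 0L,
                n_proteotypic_proteins = 0L))
  }
  groups <- unique(t[c("FullUniModPeptideName", "PrecursorCharge")])
  peptides <- unique(t$FullUniModPeptideName)
  pep_rows <- unique(t[c("PeptideSequence", "ProteinName")])
  map <- peptide_protein_map(pep_rows$PeptideSequence, pep_rows$ProteinName)
  pg <- build_protein_groups(map)
  all_acc <- sort(unique(unlist(map, use.names = FALSE)))
  if (is.null(swissprot_canonical)) {
    sp <- grepl("^sp\\|", all_acc)
    swissprot_canonical <- if (any(sp)) all_acc[sp] else all_acc
  }
  pt <- flag_proteotypic(map, swissprot_canonical)
  list(n_transition_groups = nrow(groups),
       n_peptides = length(peptides),
       n_stripped_peptides = length(unique(t$PeptideSequence)),
       n_protein_groups = nrow(pg),
       n_proteotypic_proteins = length(pt$proteins))
}

#' Library intersections and cumulative growth
#'
#' Set algebra on peptide and protein-group-representative identifiers over
#' an ordered collection of libraries, plus the cumulative count after each
#' union in the given order.
#'
#' @param libraries Named list of `assay_library` objects.
#' @return List with `per_set` (data frame of per-library counts),
#'   `pairwise` (data frame of pairwise intersection sizes) and
#'   `cumulative` (data frame of cumulative peptide/protein counts).
#' @export
intersect_and_cumulate <- function(libraries) {
  stopifnot(length(libraries) >= 1L)
  if (is.null(names(libraries))) {
    names(libraries) <- paste0("lib", seq_along(libraries))
  }
  id_sets <- lapply(libraries, function(lib) {
    t <- lib$transitions[lib$transitions$decoy == 0L, , drop = FALSE]
    pep_rows <- unique(t[c("PeptideSequence", "ProteinName")])
    pg <- if (nrow(pep_rows)) {
      build_protein_groups(
        peptide_protein_map(pep_rows$PeptideSequence, pep_rows$ProteinName))
    } else NULL
    list(peptides = unique(t$FullUniModPeptideName),
         proteins = if (is.null(pg)) character() else pg$representative)
  })
  per_set <- data.frame(
    library = names(libraries),
    n_peptides = vapply(id_sets, function(s) length(s$peptides), integer(1)),
    n_proteins = vapply(id_sets, function(s) length(s$proteins), integer(1))
  )
  pairs <- if (length(libraries) > 1L) t(utils::combn(names(libraries), 2L)) else NULL
  pairwise <- if (is.null(pairs)) NULL else data.frame(
    a = pairs[, 1L], b = pairs[, 2L],
    peptides_shared = apply(pairs, 1L, function(p)
      length(intersect(id_sets[[p[1L]]]$peptides, id_sets[[p[2L]]]$peptides))),
    proteins_shared = apply(pairs, 1L, function(p)
      length(intersect(id_sets[[p[1L]]]$proteins, id_sets[[p[2L]]]$proteins)))
  )
  cum_pep <- character()
  cum_prot <- character()
  cumulative <- do.call(rbind, lapply(seq_along(id_sets), function(i) {
    cum_pep <<- union(cum_pep, id_sets[[i]]$peptides)
    cum_prot <<- union(cum_prot, id_sets[[i]]$proteins)
    data.frame(library = names(libraries)[i],
               cumulative_peptides = length(cum_pep),
               cumulative_proteins = length(cum_prot))
  }))
  list(per_set = per_set, pairwise = pairwise, cumulative = cumulative)
}

#' Protein abundance rollup (median fragment intensity)
#'
#' The abundance of a protein group is the median over all detected fragment
#' intensities of all precursors assigned to it; missing fragments are
#' omitted, never zero-filled.
#'
#' @param fragment_intensities Data frame with columns `protein_group`,
#'   `precursor`, `intensity` (one row per detected fragment).
#' @return Data frame `protein_group`, `abundance`, `n_fragments`.
#' @export
protein_abundance_rollup <- function(fragment_intensities) {
  stopifnot(all(c("protein_group", "intensity") %in% names(fragment_intensities)))
  d <- fragment_intensities[!is.na(fragment_intensities$intensity), , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, d$protein_group), function(g) {
    data.frame(protein_group = g$protein_group[1L],
               abundance = stats::median(g$intensity),
               n_fragments = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Read accession metadata from a FASTA database
#'
#' Swiss-Prot-style headers (`sp|P12345|NAME_HUMAN ...`) are parsed; an
#' accession is flagged canonical when it comes from the `sp|` namespace and
#' carries no isoform suffix (`-2`, ...).
#'
#' @param path FASTA file.
#' @return Data frame with `accession`, `full_header`, `is_swissprot_canonical`,
#'   `sequence`.
#' @export
read_fasta_metadata <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  first <- vapply(strsplit(headers, " ", fixed = TRUE), `[`, character(1), 1L)
  parts <- strsplit(first, "|", fixed = TRUE)
  accession <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L],
                      character(1))
  is_sp <- vapply(parts, function(p) length(p) >= 2L && p[1L] == "sp",
                  logical(1))
  data.frame(accession = accession,
             full_header = headers,
             is_swissprot_canonical = is_sp & !grepl("-\\d+$", accession),
             sequence = as.character(seqs))
}

#' Write library statistics to TSV and JSON
#'
#' @param stats Result of [library_stats()].
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @export
write_library_stats <- function(stats, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
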