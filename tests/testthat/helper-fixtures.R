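# Shared fixtures and independent oracles, built in code at test time.

# Independent residue-mass table, entered separately from the package
# constants (same published values, typed independently as an oracle).
oracle_residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
oracle_peptide_mass <- function(seq) {
  sum(oracle_residue_mass[strsplit(seq, "")[[1]]]) + 18.01056
}

# Brute-force protein-grouping oracle: merge identical peptide sets, then
# assign every accession to a globally maximal superset of its set
# (preference: larger set, then lexicographically smaller representative).
oracle_protein_groups <- function(map) {
  acc2pep <- list()
  for (pep in names(map)) {
    for (acc in map[[pep]]) acc2pep[[acc]] <- union(acc2pep[[acc]], pep)
  }
  acc2pep <- lapply(acc2pep, sort)
  accs <- sort(names(acc2pep))
  sig <- vapply(acc2pep[accs], paste, character(1), collapse = "\r")
  units <- split(accs, sig)
  reps <- vapply(units, `[`, character(1), 1L)
  usets <- acc2pep[reps]
  n <- length(reps)
  is_subset <- function(a, b) length(a) < length(b) && all(a %in% b)
  maximal <- vapply(seq_len(n), function(i)
    !any(vapply(seq_len(n), function(j) is_subset(usets[[i]], usets[[j]]),
                logical(1))), logical(1))
  assign_to <- vapply(seq_len(n), function(i) {
    if (maximal[i]) return(i)
    cand <- which(maximal & vapply(seq_len(n), function(j)
      is_subset(usets[[i]], usets[[j]]), logical(1)))
    cand[order(-lengths(usets[cand]), reps[cand])][1L]
  }, integer(1))
  out <- lapply(sort(unique(assign_to)), function(r) {
    members <- sort(unlist(units[assign_to == r], use.names = FALSE))
    list(representative = min(members), members = members,
         peptides = sort(unique(unlist(acc2pep[members]))))
  })
  out[order(vapply(out, `[[`, character(1), "representative"))]
}

# Random peptide->protein map on <= max_acc accessions.
random_map <- function(max_acc = 12L, n_pep = 15L) {
  accs <- sprintf("P%02d", seq_len(sample(3:max_acc, 1L)))
  peps <- sprintf("PEP%02d", seq_len(n_pep))
  m <- lapply(peps, function(p) sort(sample(accs, sample(1:3, 1L))))
  names(m) <- peps
  m
}

# Minimal single-run PSM table with given per-record fields.
toy_psm_table <- function(n = 6L, charge = 2L, intensity = NULL,
                          rt = NULL, sequence = NULL) {
  if (is.null(sequence)) {
    sequence <- replicate(n, paste(c(sample(c("A", "S", "T", "V", "L",
                                              "E", "D", "F"), 7, TRUE), "K"),
                                   collapse = ""))
  }
  if (is.null(intensity)) intensity <- seq(100, 100 * n, length.out = n)
  if (is.null(rt)) rt <- seq(100, 3500, length.out = n)
  psm_table(data.frame(
    scan_id = sprintf("s%03d", seq_len(n)), run_id = "run1",
    rt_seconds = rt, sequence = sequence,
    charge = rep_len(charge, n),
    proteins = sprintf("sp|Q%05d|X_HUMAN", seq_len(n)),
    score = seq(30, 30 + n - 1),
    precursor_intensity = intensity, sample_type = "toy"
  ), data.frame(run_id = "run1", gradient_seconds = 3600))
}

# A consensus spectrum whose peaks are exactly the theoretical b/y ions of
# the sequence (charge-1 fragments), with the given intensities.
toy_consensus <- function(sequence = "ESDTSYVSLK", charge = 2L,
                          intensities = NULL, irt = 50,
                          proteins = "sp|P00001|TOY_HUMAN") {
  ions <- annotate_fragments(sequence, max_fragment_charge = 1L)
  if (is.null(intensities)) intensities <- seq_len(nrow(ions)) * 10
  o <- order(ions$mz)
  structure(list(sequence = sequence, charge = charge,
                 mz = ions$mz[o], intensity = intensities[o],
                 n_replicates = 3L, best_score = 42,
                 irt = irt, proteins = proteins, sample_type = "toy"),
            class = "consensus_spectrum")
}

# Replicate group built from explicit spectra.
toy_group <- function(spectra, sequence = "ESDTSYVSLK", charge = 2L) {
  n <- length(spectra)
  structure(list(
    sequence = sequence, charge = charge,
    records = data.frame(scan_id = sprintf("s%d", seq_len(n)),
                         score = seq(10, 10 + n - 1)),
    spectra = spectra,
    proteins = "sp|P00001|TOY_HUMAN",
    sample_type = "toy"
  ), class = "replicate_group")
}
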