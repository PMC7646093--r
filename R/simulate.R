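# Seeded simulator of ground-truth proteomes, PSM runs and fragment
# spectra, so every pipeline stage is testable without instrument data.
#
# The simulator emulates the DDA side of library building: tryptic peptides
# with log-normal precursor abundances (the heavy-tailed distribution the
# third-quartile CiRT intensity gate presumes), hidden iRT values on the
# customary [0, 100] scale, per-run affine RT transforms with Gaussian
# jitter, and MS2 spectra composed of a fixed true b/y intensity profile
# plus uniformly placed Poisson-count noise peaks.

#' Generate a random proteome with its tryptic peptide map
#'
#' Sequences are drawn residue-by-residue; the digest cleaves after K/R
#' except before P, with 0-2 missed cleavages.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (residues).
#' @param missed_cleavages Maximum missed cleavages retained (default 0).
#' @param seed Integer seed.
#' @param fasta_path Optional path; when given, the proteome is also
#'   written as FASTA with Swiss-Prot-style `sp|ACC|NAME` headers.
#' @return List with `proteome` (named character: accession -> sequence),
#'   `peptides` (data frame `peptide`, `accession`) and `fasta_path`.
#' @export
generate_proteome <- function(n_proteins = 20L, length_range = c(60L, 200L),
                              missed_cleavages = 0L, seed = 1L,
                              fasta_path = NULL) {
  stopifnot(n_proteins >= 1L)
  set.seed(seed)
  aa <- names(MASS_CONSTANTS$residues)
  # K/R upweighted so tryptic peptides stay short
  w <- rep(1, length(aa))
  w[aa %in% c("K", "R")] <- 2.5
  proteome <- vapply(seq_len(n_proteins), function(i) {
    n <- sample(seq(length_range[1L], length_range[2L]), 1L)
    paste(sample(aa, n, replace = TRUE, prob = w), collapse = "")
  }, character(1))
  names(proteome) <- sprintf("sp|P%05d|SYN%d_HUMAN", seq_len(n_proteins),
                             seq_len(n_proteins))
  acc <- vapply(strsplit(names(proteome), "|", fixed = TRUE), `[`,
                character(1), 2L)
  peptides <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    peps <- digest_tryptic(proteome[[i]], missed_cleavages = missed_cleavages)
    if (!length(peps)) return(NULL)
    data.frame(peptide = peps, accession = acc[i])
  }))
  rownames(peptides) <- NULL
  if (!is.null(fasta_path)) {
    x <- Biostrings::AAStringSet(proteome)
    Biostrings::writeXStringSet(x, fasta_path)
  }
  list(proteome = proteome, peptides = peptides, fasta_path = fasta_path)
}

#' In-silico tryptic digest
#'
#' Cleaves after K or R except when the next residue is P.
#'
#' @param sequence Protein sequence.
#' @param missed_cleavages Maximum missed cleavages (0-2).
#' @param min_length,max_length Peptide length bounds (default 6-30).
#' @return Character vector of peptides.
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 0L,
                           min_length = 6L, max_length = 30L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut <- which(res[-n] %in% c("K", "R") & res[-1L] != "P")
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  frags <- substring(sequence, starts, ends)
  out <- character()
  for (mc in 0:missed_cleavages) {
    k <- length(frags) - mc
    if (k < 1L) break
    out <- c(out, vapply(seq_len(k), function(i)
      paste(frags[i:(i + mc)], collapse = ""), character(1)))
  }
  unique(out[nchar(out) >= min_length & nchar(out) <= max_length])
}

#' Simulate DDA runs from a ground-truth proteome
#'
#' Each peptide precursor gets a hidden iRT (uniform on \[0, 100\]), a
#' log-normal abundance, a charge from a categorical distribution
#' (default 1:2:3:4 = 0.05:0.6:0.3:0.05) and a fixed true b/y fragment
#' intensity profile. Per run, observed RT = run slope x iRT + run
#' intercept + Gaussian noise; spectra are the true profile plus
#' Poisson-count uniform noise peaks.
#'
#' @param truth Result of [generate_proteome()] (or a compatible list).
#' @param n_runs Number of runs.
#' @param gradient_seconds Nominal gradient length (default 3600).
#' @param n_psms PSMs sampled per run (each precursor at most once per run).
#' @param rt_noise_sd Gaussian RT jitter in seconds (default 5).
#' @param noise_peak_lambda Poisson mean of noise peaks per spectrum
#'   (default 5).
#' @param charge_probs Probabilities for charges 1-4.
#' @param sample_type Sample-type tag on the records.
#' @param seed Integer seed.
#' @return List of class `sim_run_set`: `table` (a [psm_table()]),
#'   `spectra` (list of [spectrum()]), and `truth` (data frame per
#'   precursor: `sequence`, `charge`, `accession`, `hidden_irt`,
#'   `abundance`, plus fragment profiles in `fragment_profiles` and per-run
#'   transforms in `run_transforms`).
#' @export
simulate_runs <- function(truth, n_runs = 3L, gradient_seconds = 3600,
                          n_psms = 1000L, rt_noise_sd = 5,
                          noise_peak_lambda = 5,
                          charge_probs = c(0.05, 0.6, 0.3, 0.05),
                          sample_type = "synthetic_tissue", seed = 1L) {
  set.seed(seed)
  peps <- truth$peptides
  # proteotypic assignment: a peptide maps to every protein containing it
  prot_of <- tapply(peps$accession, peps$peptide,
                    function(a) sort(unique(a)), simplify = FALSE)
  sequences <- names(prot_of)
  n_pep <- length(sequences)
  charge <- sample(1:4, n_pep, replace = TRUE, prob = charge_probs)
  precursors <- data.frame(
    sequence = sequences,
    charge = charge,
    proteins = vapply(prot_of, paste, character(1), collapse = ";"),
    hidden_irt = stats::runif(n_pep, 0, 100),
    abundance = stats::rlnorm(n_pep, meanlog = 12, sdlog = 1.2)
  )
  fragment_profiles <- lapply(seq_len(n_pep), function(i) {
    ions <- annotate_fragments(precursors$sequence[i], max_fragment_charge = 1L)
    rel <- stats::runif(nrow(ions), 0.05, 1)
    data.frame(ions, rel_intensity = rel)
  })
  names(fragment_profiles) <- paste(precursors$sequence, precursors$charge,
                                    sep = "/")
  run_transforms <- data.frame(
    run_id = sprintf("run%02d", seq_len(n_runs)),
    slope = gradient_seconds / 100 * stats::runif(n_runs, 0.95, 1.05),
    intercept = stats::runif(n_runs, 0, 0.02 * gradient_seconds),
    noise_sd = rt_noise_sd
  )
  records <- list()
  spectra <- list()
  scan_counter <- 0L
  for (r in seq_len(n_runs)) {
    picked <- unique(sample(n_pep, n_psms, replace = TRUE,
                            prob = precursors$abundance))
    for (i in picked) {
      scan_counter <- scan_counter + 1L
      sid <- sprintf("scan%06d", scan_counter)
      rt <- run_transforms$slope[r] * precursors$hidden_irt[i] +
        run_transforms$intercept[r] + stats::rnorm(1L, 0, rt_noise_sd)
      prof <- fragment_profiles[[i]]
      base <- precursors$abundance[i]
      frag_int <- prof$rel_intensity * base *
        stats::rlnorm(nrow(prof), 0, 0.1)
      n_noise <- stats::rpois(1L, noise_peak_lambda)
      noise_mz <- stats::runif(n_noise, 200, 1500)
      noise_int <- stats::runif(n_noise, 0, 0.2 * base)
      sp <- spectrum(c(prof$mz, noise_mz), c(frag_int, noise_int),
                     scan_id = sid, rt_seconds = rt,
                     precursor_mz = precursor_mz(precursors$sequence[i],
                                                 precursors$charge[i]),
                     precursor_charge = precursors$charge[i])
      spectra[[sid]] <- sp
      records[[scan_counter]] <- data.frame(
        scan_id = sid, run_id = run_transforms$run_id[r],
        rt_seconds = rt, sequence = precursors$sequence[i],
        stripped_sequence = precursors$sequence[i],
        charge = precursors$charge[i],
        proteins = precursors$proteins[i],
        score = stats::runif(1L, 20, 60),
        precursor_intensity = precursors$abundance[i] *
          stats::rlnorm(1L, 0, 0.05),
        sample_type = sample_type
      )
    }
  }
  records <- do.call(rbind, records)
  runs <- data.frame(run_id = run_transforms$run_id,
                     gradient_seconds = gradient_seconds)
  structure(list(
    table = psm_table(records, runs),
    spectra = unname(spectra),
    truth = list(precursors = precursors,
                 fragment_profiles = fragment_profiles,
                 run_transforms = run_transforms,
                 gradient_seconds = gradient_seconds)
  ), class = "sim_run_set")
}

#' Write a simulated run set to disk
#'
#' Emits the PSM table (generic TSV dialect), the spectra (MGF), the
#' proteome (FASTA, when provided) and the ground truth (JSON).
#'
#' @param sim A `sim_run_set` from [simulate_runs()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_run_set <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_run_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_psm_table(sim$table, file.path(dir, "psms.tsv"))
  write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
  jsonlite::write_json(list(
    precursors = sim$truth$precursors,
    run_transforms = sim$truth$run_transforms,
    gradient_seconds = sim$truth$gradient_seconds
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
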