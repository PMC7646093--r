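test_that("protein grouping realizes the identical/subset clauses", {
  # identical peptide sets merge
  m <- peptide_protein_map(c("a", "b"), c("P1;P2", "P1;P2"))
  g <- build_protein_groups(m)
  expect_equal(nrow(g), 1L)
  expect_equal(g$members, "P1;P2")

  # strict subset is absorbed into the superset's group
  m2 <- list(a = c("P1", "P2"), b = c("P1", "P2"), c = "P1")
  g2 <- build_protein_groups(m2)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$members, "P1;P2")
  expect_equal(g2$peptides, "a;b;c")

  # disjoint evidence stays separate
  g3 <- build_protein_groups(list(a = "P1", b = "P2"))
  expect_equal(nrow(g3), 2L)

  # chain P1 > P2 > P3 plus disjoint P4 collapses to 2 groups
  m4 <- list(a = c("P1", "P2", "P3"), b = c("P1", "P2"), c = "P1", d = "P4")
  # P1: {a,b,c}; P2: {a,b}; P3: {a}; P4: {d}
  g4 <- build_protein_groups(m4)
  expect_equal(nrow(g4), 2L)
  expect_equal(g4$members, c("P1;P2;P3", "P4"))
})

test_that("protein grouping matches the brute-force subset-closure oracle", {
  set.seed(77)
  for (i in 1:100) {
    m <- random_map()
    got <- build_protein_groups(m)
    want <- oracle_protein_groups(m)
    expect_equal(nrow(got), length(want))
    expect_equal(got$representative,
                 vapply(want, `[[`, character(1), "representative"))
    expect_equal(got$members,
                 vapply(want, function(w) paste(w$members, collapse = ";"),
                        character(1)))
    expect_equal(got$peptides,
                 vapply(want, function(w) paste(w$peptides, collapse = ";"),
                        character(1)))
    # groups partition the accessions; peptides are covered
    accs <- unlist(strsplit(got$members, ";"))
    expect_false(anyDuplicated(accs) > 0)
    expect_setequal(unique(unlist(strsplit(got$peptides, ";"))), names(m))
  }
})

test_that("proteotypic flags follow the single-accession definition", {
  m <- list(a = "P1", b = c("P1", "P2"), c = "P3")
  pt <- flag_proteotypic(m)
  expect_equal(pt$peptides$peptide, c("a", "c"))
  expect_equal(pt$proteins, c("P1", "P3"))  # P2 has only shared peptides
  # restricting the canonical set restricts the protein count
  pt2 <- flag_proteotypic(m, swissprot_canonical = "P3")
  expect_equal(pt2$proteins, "P3")
})

test_that("library statistics count precursors, peptides, groups, proteotypic", {
  mk_entry <- function(seq, charge, prots) {
    cs <- toy_consensus(seq, charge, proteins = prots)
    select_transitions(cs, transition_config(fragment_mz_min = 200))
  }
  entries <- list(
    mk_entry("ESDTSYVSLK", 2L, "sp|P1|A"),
    mk_entry("ESDTSYVSLK", 3L, "sp|P1|A"),      # same peptide, new precursor
    mk_entry("AADERSTK", 2L, "sp|P1|A"),
    mk_entry("FFGGSSTK", 2L, c("sp|P1|A", "sp|P2|B")),  # shared
    mk_entry("LLMMNNK", 2L, "sp|P3|C")
  )
  lib <- assemble_library(entries, seed = 2)
  s <- library_stats(lib)
  expect_equal(s$n_transition_groups, 5L)
  expect_equal(s$n_peptides, 4L)
  # P2's set {FFGGSSTK} is a strict subset of P1's -> one group; P3 separate
  expect_equal(s$n_protein_groups, 2L)
  # P1 and P3 have proteotypic peptides; P2 does not
  expect_equal(s$n_proteotypic_proteins, 2L)

  # decoys change nothing: stats computed on targets only
  targets_only <- assay_library(
    lib$transitions[lib$transitions$decoy == 0, ], lib$metadata)
  expect_equal(library_stats(targets_only)[1:4], s[1:4])

  empty <- assay_library(lib$transitions[0, ], list())
  expect_equal(library_stats(empty)$n_transition_groups, 0L)
})

test_that("intersections and cumulative growth follow set algebra", {
  mk_lib <- function(seqs, prots) {
    entries <- Map(function(s, p) {
      select_transitions(toy_consensus(s, proteins = p),
                         transition_config(fragment_mz_min = 200))
    }, seqs, prots)
    assemble_library(Filter(Negate(is.null), entries), seed = 3)
  }
  A <- mk_lib(c("ESDTSYVSLK", "AADERSTK"), c("sp|P1|A", "sp|P2|B"))
  B <- mk_lib(c("ESDTSYVSLK", "LLMMNNK"), c("sp|P1|A", "sp|P3|C"))

  same <- intersect_and_cumulate(list(x = A, y = A))
  expect_equal(same$pairwise$peptides_shared, same$per_set$n_peptides[1])
  expect_equal(same$cumulative$cumulative_peptides,
               rep(same$per_set$n_peptides[1], 2))

  two <- intersect_and_cumulate(list(a = A, b = B))
  expect_equal(two$pairwise$peptides_shared, 1L)
  expect_equal(two$cumulative$cumulative_peptides, c(2L, 3L))

  disjointB <- mk_lib(c("WWSSTTK"), c("sp|P9|Z"))
  dj <- intersect_and_cumulate(list(a = A, b = disjointB))
  expect_equal(dj$pairwise$peptides_shared, 0L)
  expect_equal(dj$cumulative$cumulative_peptides,
               cumsum(dj$per_set$n_peptides))
})

test_that("protein abundance is the median of detected fragment intensities", {
  d <- data.frame(protein_group = c("G1", "G1", "G1", "G2", "G2", "G2", "G2"),
                  precursor = c("p1", "p1", "p2", "p3", "p3", "p4", "p4"),
                  intensity = c(10, 20, 30, 10, 20, 30, 100))
  out <- protein_abundance_rollup(d)
  expect_equal(out$abundance[out$protein_group == "G1"], 20)
  expect_equal(out$abundance[out$protein_group == "G2"], 25)  # even-count mean
  # missing values are omitted, not zero-filled
  d2 <- rbind(d, data.frame(protein_group = "G1", precursor = "p2",
                            intensity = NA))
  expect_equal(protein_abundance_rollup(d2)$abundance[1], 20)
  # a protein with no detected fragments is absent
  expect_false("G3" %in% protein_abundance_rollup(d)$protein_group)
})

test_that("FASTA metadata distinguishes Swiss-Prot canonical accessions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P02741|CRP_HUMAN C-reactive protein", "MEKLLCFLVLTSLSHAFGQTDMSR",
    ">sp|P02741-2|CRP_HUMAN Isoform 2", "MEKLLCFLVLTS",
    ">tr|A0A024|TREMBL_HUMAN Uncharacterized", "MSSSSK"
  ), f)
  meta <- read_fasta_metadata(f)
  expect_equal(meta$accession, c("P02741", "P02741-2", "A0A024"))
  expect_equal(meta$is_swissprot_canonical, c(TRUE, FALSE, FALSE))
  expect_equal(meta$sequence[3], "MSSSSK")
})
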