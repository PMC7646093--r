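make_test_library <- function(seqs = c("ESDTSYVSLK", "AADERSTK", "LLMMNNK"),
                              seed = 4L) {
  entries <- lapply(seqs, function(s)
    select_transitions(toy_consensus(s),
                       transition_config(fragment_mz_min = 200)))
  assemble_library(Filter(Negate(is.null), entries), seed = seed)
}

test_that("OpenSWATH TSV round trip is lossless", {
  lib <- make_test_library()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_openswath_tsv(lib, f)
  d <- utils::read.delim(f)
  expect_equal(nrow(d), nrow(lib$transitions))
  expect_true(all(LIBRARY_COLUMNS %in% names(d)))
  expect_equal(d$decoy == 1, startsWith(d$transition_name, "DECOY_"))

  back <- read_openswath_tsv(f)
  o1 <- order(lib$transitions$transition_name)
  o2 <- order(back$transitions$transition_name)
  for (col in LIBRARY_COLUMNS) {
    expect_equal(back$transitions[[col]][o2], lib$transitions[[col]][o1],
                 tolerance = 1e-9, label = col)
  }
})

test_that("reading rejects missing columns and malformed rows with line numbers", {
  lib <- make_test_library()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_openswath_tsv(lib, f)
  d <- utils::read.delim(f, check.names = FALSE)
  d$ProductMz <- NULL
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_openswath_tsv(f2), "ProductMz")

  d2 <- utils::read.delim(f, check.names = FALSE)
  d2$PrecursorMz[3] <- NA
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d2, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_openswath_tsv(f3), "line")
})

test_that("TraML export validates and round trips m/z through an independent parser", {
  lib <- make_test_library()
  f <- withr::local_tempfile(fileext = ".traml")
  write_traml(lib, f)
  expect_true(validate_traml(f))

  # independent parser: Python/lxml reads the document back
  py <- Sys.which("python")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from lxml import etree",
    "ns = {'t': 'http://psi.hupo.org/ms/traml'}",
    "doc = etree.parse(sys.argv[1])",
    "out = []",
    "for tr in doc.findall('.//t:Transition', ns):",
    "    prec = tr.find('t:Precursor/t:cvParam', ns).get('value')",
    "    prod = tr.find('t:Product/t:cvParam', ns).get('value')",
    "    out.append({'id': tr.get('id'), 'prec': float(prec), 'prod': float(prod)})",
    "print(json.dumps(out))"
  ), script)
  res <- system2(py, c(script, f), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""))
  m <- match(lib$transitions$transition_name, parsed$id)
  expect_false(anyNA(m))
  expect_equal(parsed$prec[m], lib$transitions$PrecursorMz, tolerance = 1e-4)
  expect_equal(parsed$prod[m], lib$transitions$ProductMz, tolerance = 1e-4)
})

test_that("TraML export covers landmark sets and empty libraries", {
  lm <- structure(data.frame(
    sequence = sprintf("PEPT%02dK", 1:20), charge = 2L,
    median_rt = seq(100, 3500, length.out = 20), intensity = 1e5,
    reference_irt = seq(0, 100, length.out = 20), source = "CiRT"),
    class = c("landmark_set", "data.frame"))
  f <- withr::local_tempfile(fileext = ".traml")
  write_traml(lm, f)
  expect_true(validate_traml(f))
  doc <- xml2::read_xml(f)
  peps <- xml2::xml_find_all(doc, "//*[local-name() = 'Peptide']")
  expect_length(peps, 20L)
  rts <- xml2::xml_find_all(
    doc, "//*[local-name() = 'cvParam'][@accession = 'MS:1000896']")
  expect_equal(as.numeric(xml2::xml_attr(rts, "value")),
               lm$reference_irt, tolerance = 1e-6)

  empty <- assay_library(make_test_library()$transitions[0, ], list())
  f2 <- withr::local_tempfile(fileext = ".traml")
  write_traml(empty, f2)
  expect_true(validate_traml(f2))
})

test_that("PRM schedules have the configured window width and report misses", {
  lib <- make_test_library()
  fit <- fit_irt_map(seq(0, 3600, length.out = 10),
                     seq(0, 100, length.out = 10))
  sched <- suppressWarnings(
    export_prm_schedule(lib, c("ESDTSYVSLK", "NOTINLIBK"), fit))
  expect_equal(attr(sched, "missing"), "NOTINLIBK")
  expect_equal(sched$`End [min]` - sched$`Start [min]`, rep(10, nrow(sched)))
  # predicted center = inverse calibration of the library iRT, in minutes
  tg <- lib$transitions[lib$transitions$decoy == 0 &
                          lib$transitions$PeptideSequence == "ESDTSYVSLK", ]
  expect_equal(sched$`Start [min]` + 5,
               invert_calibration(tg$Tr_recalibrated[1], fit) / 60)
})

test_that("PRM export warns when concurrent windows exceed the capacity", {
  entries <- lapply(1:21, function(i) {
    s <- paste0(paste(rep(c("A", "S", "T", "V", "L", "E", "D"),
                          length.out = 6 + i %% 5), collapse = ""), "GGYK")
    e <- select_transitions(toy_consensus(s, irt = 50),
                            transition_config(fragment_mz_min = 200))
    e
  })
  entries <- Filter(Negate(is.null), entries)
  entries <- entries[!duplicated(vapply(entries, function(e)
    e$FullUniModPeptideName[1], character(1)))]
  lib <- assemble_library(entries, seed = 8)
  fit <- fit_irt_map(seq(0, 3600, length.out = 10),
                     seq(0, 100, length.out = 10))
  peps <- unique(lib$transitions$PeptideSequence[lib$transitions$decoy == 0])
  expect_warning(
    export_prm_schedule(lib, peps, fit,
                        config = prm_config(max_concurrent_precursors = 3L)),
    "overlap")
})

test_that("merge resolves conflicts by rule and preserves decoy pairing", {
  A <- make_test_library(c("ESDTSYVSLK", "AADERSTK"))
  B <- make_test_library(c("ESDTSYVSLK", "LLMMNNK"))
  # raise B's score for the shared precursor
  B$transitions$best_score <- 99

  self <- merge_libraries(list(A, A))$transitions
  expect_equal(self[order(self$transition_name), ],
               A$transitions[order(A$transitions$transition_name), ],
               ignore_attr = TRUE)

  m <- merge_libraries(list(A, B), conflict_rule = "higher_best_score")
  shared <- m$transitions[m$transitions$PeptideSequence == "ESDTSYVSLK" &
                            m$transitions$decoy == 0, ]
  expect_true(all(shared$best_score == 99))
  s <- library_stats(m)
  expect_equal(s$n_peptides, 3L)

  kf <- merge_libraries(list(A, B), conflict_rule = "keep_first")
  sharedf <- kf$transitions[kf$transitions$PeptideSequence == "ESDTSYVSLK" &
                              kf$transitions$decoy == 0, ]
  expect_false(any(sharedf$best_score == 99))

  # disjoint merge is additive
  C <- make_test_library("WWSSTTK")
  md <- merge_libraries(list(A, C))
  expect_equal(nrow(md$transitions), nrow(A$transitions) + nrow(C$transitions))
})

test_that("subsetting keeps decoys only with their targets and composes", {
  lib <- make_test_library()
  sub <- subset_library(lib, peptides = "ESDTSYVSLK")
  tg <- sub$transitions[sub$transitions$decoy == 0, ]
  dc <- sub$transitions[sub$transitions$decoy == 1, ]
  expect_equal(unique(tg$PeptideSequence), "ESDTSYVSLK")
  expect_setequal(sub("^DECOY_", "", dc$transition_name), tg$transition_name)

  s1 <- subset_library(subset_library(lib, sample_types = "toy"),
                       peptides = c("ESDTSYVSLK", "AADERSTK"))
  s2 <- subset_library(lib, sample_types = "toy",
                       peptides = c("ESDTSYVSLK", "AADERSTK"))
  expect_equal(s1$transitions[order(s1$transitions$transition_name), ],
               s2$transitions[order(s2$transitions$transition_name), ])
})
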