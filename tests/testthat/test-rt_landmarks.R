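# A dense single-run PSM table with controllable candidate structure.
dense_table <- function(n = 400L, seed = 3L, charges = c(2L, 3L)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(c(sample(c("A", "S", "T", "V", "L", "E", "D", "F", "G", "Y"),
                   8, TRUE), "K"), collapse = ""), character(1))
  seqs <- make.unique(seqs, sep = "")  # keep sequences distinct
  seqs <- vapply(strsplit(seqs, ""), function(x)
    paste(x[x %in% names(MASS_CONSTANTS$residues)], collapse = ""), character(1))
  psm_table(data.frame(
    scan_id = sprintf("s%04d", seq_len(n)), run_id = "run1",
    rt_seconds = runif(n, 0, 3600),
    sequence = seqs, charge = sample(charges, n, TRUE),
    proteins = sprintf("sp|P%05d|X_HUMAN", seq_len(n)),
    score = runif(n, 10, 60),
    precursor_intensity = rlnorm(n, 12, 1.2),
    sample_type = "toy"
  ), data.frame(run_id = "run1", gradient_seconds = 3600))
}

test_that("CiRT selection yields one landmark per bin satisfying all criteria", {
  tab <- dense_table(800)
  lm <- select_cirt(tab)
  expect_s3_class(lm, "landmark_set")
  expect_equal(nrow(lm), 20L)
  expect_true(all(lm$charge %in% c(2L, 3L)))
  expect_true(all(lm$sequence == strip_mods(lm$sequence)))
  q3 <- quantile(tab$records$precursor_intensity, 0.75, type = 7)
  expect_true(all(lm$intensity > q3))
  expect_equal(attr(lm, "n_empty_bins"), 0L)
})

test_that("CiRT candidate criteria exclude wrong charges and modified peptides", {
  tab <- dense_table(100, charges = 1L)
  expect_error(select_cirt(tab), "no precursor satisfies")

  tab2 <- dense_table(200)
  tab2$records$sequence <- paste0("C[UniMod:4]", tab2$records$sequence)
  tab2$records$stripped_sequence <- strip_mods(tab2$records$sequence)
  expect_error(select_cirt(tab2), "no precursor satisfies")
  # allowing modified sequences restores selection
  lm <- select_cirt(tab2, config = cirt_config(require_unmodified = FALSE))
  expect_gt(nrow(lm), 0L)

  # shared peptides fail the proteotypic criterion
  tab3 <- dense_table(150)
  tab3$records$proteins <- "sp|P1|A;sp|P2|B"
  expect_error(select_cirt(tab3), "no precursor satisfies")
})

test_that("clustered retention times give one landmark and an empty-bin warning", {
  tab <- dense_table(40)
  tab$records$rt_seconds <- 1000  # zero RT spread: a single occupied bin
  expect_warning(lm <- select_cirt(tab), "bins")
  expect_equal(nrow(lm), 1L)
  expect_equal(attr(lm, "n_empty_bins"), 19L)
  # the single pick is the most intense candidate
  expect_equal(lm$intensity, max(tab$records$precursor_intensity))
})

test_that("reference iRT assignment: affine anchor and min-max fallback", {
  lm <- structure(data.frame(
    sequence = c("AAAK", "CCDK", "EEFK"), charge = 2L,
    median_rt = c(10, 20, 30), intensity = 1, reference_irt = NA_real_,
    source = "CiRT"), class = c("landmark_set", "data.frame"))
  fit <- structure(list(slope = 2, intercept = -10, r_squared = 1,
                        n_points_used = 3L, outlier_keys = character()),
                   class = "calibration_fit")
  anchored <- assign_reference_irt(lm, anchor = fit)
  expect_equal(anchored$reference_irt, c(10, 30, 50))

  scaled <- assign_reference_irt(lm)
  expect_equal(scaled$reference_irt, c(0, 50, 100))

  # a landmark missing from the reference run is dropped with a warning
  ref <- c(`AAAK/2` = 10, `CCDK/2` = 20, `EEFK/2` = 30, `GGHK/2` = 40)
  lm4 <- rbind(lm, data.frame(sequence = "MMNK", charge = 2L, median_rt = 40,
                              intensity = 1, reference_irt = NA_real_,
                              source = "CiRT"))
  class(lm4) <- c("landmark_set", "data.frame")
  expect_warning(out <- assign_reference_irt(lm4, reference_rt = ref),
                 "dropped")
  expect_equal(nrow(out), 3L)
})

test_that("calibration fit recovers exact affine maps and rejects gross outliers", {
  rt <- seq(100, 3500, length.out = 20)
  irt <- 2 * rt - 10
  fit <- fit_irt_map(rt, irt)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, -10, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # planted gross outlier among 20 slightly noisy points
  set.seed(42)
  irt_noisy <- 2 * rt - 10 + rnorm(20, 0, 0.5)
  irt_noisy[7] <- irt_noisy[7] + 25 * 0.5 * 50
  fit2 <- fit_irt_map(rt, irt_noisy, keys = sprintf("p%02d", 1:20))
  expect_equal(fit2$outlier_keys, "p07")
  # brute-force refit excluding the planted outlier as oracle
  oracle <- lm(irt_noisy[-7] ~ rt[-7])
  expect_equal(fit2$slope, unname(coef(oracle)[2]), tolerance = 1e-9)
  expect_lt(abs(fit2$slope - 2) / 2, 0.01)

  expect_error(fit_irt_map(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_irt_map(rep(5, 4), 1:4), "degenerate")
})

test_that("calibration application is affine, invertible and monotone", {
  fit <- structure(list(slope = 2, intercept = -10, r_squared = 1,
                        n_points_used = 3L, outlier_keys = character()),
                   class = "calibration_fit")
  expect_equal(apply_calibration(30, fit), 50)
  x <- c(5, 100, 2000)
  expect_equal(invert_calibration(apply_calibration(x, fit), fit), x)
  expect_true(all(diff(apply_calibration(sort(x), fit)) > 0))
})

test_that("slope and intercept are recovered under realistic retention-time noise", {
  # 20 landmarks, Gaussian RT noise sd 5 s on a 3600 s gradient
  set.seed(2026)
  n_ok <- 0L
  n_rep <- 200L
  true_slope <- 100 / 3600
  true_intercept <- -3
  for (r in seq_len(n_rep)) {
    rt_true <- runif(20, 0, 3600)
    irt <- true_slope * rt_true + true_intercept
    rt_obs <- rt_true + rnorm(20, 0, 5)
    fit <- fit_irt_map(rt_obs, irt)
    ok <- abs(fit$slope - true_slope) / true_slope < 0.02 &&
      abs(fit$intercept - true_intercept) < 2
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / n_rep, 0.95)
})

test_that("landmark sets round trip through TSV", {
  lm <- structure(data.frame(
    sequence = c("AAAK", "CCDK", "EEFK"), charge = c(2L, 2L, 3L),
    median_rt = c(10, 20, 30), intensity = c(1e5, 2e5, 3e5),
    reference_irt = c(0, 50, 100), source = "CiRT"),
    class = c("landmark_set", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(as.data.frame(back), as.data.frame(lm))
})
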