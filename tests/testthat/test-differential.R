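# Quality filtering and the two-state significance caller.

test_that("peptide filter applies inclusive thresholds and logs failures", {
  ids <- tibble::tibble(
    peptide_id = sprintf("p%d", 1:7),
    score = c(6.5, 6.4, 9, 9, 9, 9, 9),
    products_per_aa = c(0.2, 0.3, 0.19, 0.3, 0.3, 0.3, 0.3),
    mh_error_ppm = c(5, 1, 1, 5.1, 1, 1, 1),
    rt_sd_percent = c(5, 1, 1, 1, 5.1, 1, 1),
    runs_observed = c(2, 3, 3, 3, 3, 1, 3)
  )
  kept <- filter_peptides(ids)
  expect_setequal(kept$peptide_id, c("p1", "p7"))  # boundary row retained
  rej <- attr(kept, "rejections")
  expect_equal(rej$failed_rule[rej$peptide_id == "p2"], "score below cutoff")
  expect_equal(rej$failed_rule[rej$peptide_id == "p6"],
               "seen in too few identification runs")
})

test_that("peptide filter equals brute-force row-by-row evaluation", {
  withr::with_seed(29, {
    ids <- tibble::tibble(
      peptide_id = sprintf("p%03d", 1:200),
      score = stats::runif(200, 5, 8),
      products_per_aa = stats::runif(200, 0.1, 0.4),
      mh_error_ppm = stats::runif(200, 0, 8),
      rt_sd_percent = stats::runif(200, 0, 8),
      runs_observed = sample(0:3, 200, replace = TRUE)
    )
    kept <- filter_peptides(ids)
    brute <- vapply(seq_len(nrow(ids)), function(i) {
      r <- ids[i, ]
      r$score >= 6.5 && r$products_per_aa >= 0.2 && r$mh_error_ppm <= 5 &&
        r$rt_sd_percent <= 5 && r$runs_observed >= 2
    }, logical(1))
    expect_identical(kept$peptide_id, ids$peptide_id[brute])
    expect_equal(nrow(attr(kept, "rejections")), sum(!brute))
  })
})

test_that("identical states are not significant; a 1-deuteron shift is", {
  m <- c(1, 2, 3, 4, 5)
  same <- two_state_records(m, m, sd = 0)
  r1 <- suppressWarnings(compare_states(same, "A", "B"))
  expect_equal(r1$verdict, "not-significant")
  expect_equal(r1$t_tests[[1]]$delta_uptake, rep(0, 5))

  shifted <- two_state_records(m, m + 1, sd = 0.05, seed = 4)
  r2 <- compare_states(shifted, "A", "B")
  expect_equal(r2$verdict, "increased")
  expect_lt(r2$anova_p, 1e-6)
  expect_true(all(r2$t_tests[[1]]$p < 1e-4))

  dropped <- two_state_records(m, m - 1, sd = 0.05, seed = 5)
  expect_equal(compare_states(dropped, "A", "B")$verdict, "decreased")
})

test_that("mismatched timepoints are skipped with a log entry", {
  m <- c(1, 2, 3, 4, 5)
  recs <- two_state_records(m, m + 1, sd = 0.05)
  recs <- recs[!(recs$state == "B" & recs$time_s == 120), ]
  ok <- two_state_records(m, m, sd = 0.05, peptide_id = "pep_0002", seed = 2)
  res <- compare_states(dplyr::bind_rows(recs, ok), "A", "B")
  expect_equal(res$peptide_id, "pep_0002")
  expect_match(attr(res, "skipped")$reason, "mismatched")
})

test_that("detection power for a 1-deuteron difference is high", {
  m <- c(1, 2, 3, 4, 5)
  hits <- withr::with_seed(33, vapply(1:200, function(i) {
    recs <- two_state_records(m, m + 1, sd = 0.1,
                              seed = sample.int(1e8, 1))
    compare_states(recs, "A", "B")$verdict == "increased"
  }, logical(1)))
  expect_gt(mean(hits), 0.95)
})

test_that("the combined ANOVA + t-test rule is conservative under the null", {
  m <- c(1, 2, 3, 4, 5)
  verdicts <- withr::with_seed(34, vapply(1:300, function(i) {
    recs <- two_state_records(m, m, sd = 0.1, seed = sample.int(1e8, 1))
    compare_states(recs, "A", "B")$verdict
  }, character(1)))
  # AND of two 0.05-level tests: well under alpha; binomial 99% bound
  expect_lt(mean(verdicts != "not-significant"),
            0.05 + 2.58 * sqrt(0.05 * 0.95 / 300))
})

test_that("monotone back-exchange correction leaves verdicts unchanged", {
  m <- c(1, 2, 3, 4, 5)
  raw <- dplyr::bind_rows(
    two_state_records(m, m + 0.8, sd = 0.08, seed = 6),
    two_state_records(m, m, sd = 0.08, peptide_id = "pep_0002", seed = 7))
  corr <- dplyr::mutate(raw, uptake = correct_uptake(uptake, 0.25, 10))
  v_raw <- compare_states(raw, "A", "B")$verdict
  v_corr <- compare_states(corr, "A", "B")$verdict
  expect_identical(v_raw, v_corr)
})

test_that("residue map follows majority consensus with conflicts flagged", {
  map <- tibble::tibble(peptide_id = c("p1", "p2", "p3"),
                        sequence = NA_character_,
                        start = c(10L, 15L, 30L), end = c(20L, 25L, 40L),
                        max_uptake = 8L)
  res <- tibble::tibble(
    peptide_id = c("p1", "p2", "p3"),
    verdict = c("increased", "decreased", "not-significant"))
  rm <- residue_level_map(res, map)
  expect_true(all(rm$classification[10:14] == "increased"))
  expect_true(all(rm$classification[15:20] == "ambiguous"))  # 1 vs 1
  expect_true(all(rm$classification[21:25] == "decreased"))
  expect_true(all(rm$classification[30:40] == "not-significant"))
  expect_true(all(rm$classification[1:9] == "no-coverage"))
  expect_error(residue_level_map(
    tibble::tibble(peptide_id = "zz", verdict = "increased"), map),
    "absent")
})

test_that("a simulated protection loss is localised to the right residues", {
  sys <- small_system(n = 160, region = c(80, 100), noise_sd = 0.02)
  map <- generate_peptide_map(sys$sequence, 10, 5)
  tab <- simulate_exchange_dataset(sys, map, seed = 19)
  raw <- compute_raw_uptake(tab)
  b <- estimate_back_exchange(raw, map)
  corr <- correct_uptake_table(raw, as.numeric(b))
  res <- compare_states(corr, "apo", "bound")
  rm <- residue_level_map(res, map)
  flagged <- which(rm$classification == "increased")
  region <- contiguous_block(flagged, 80:100)
  overhang <- 9  # a 10-mer overlapping the region by one amide
  expect_true(length(region) > 0)
  expect_true(all(region >= 80 - overhang & region <= 100 + overhang))
  expect_true(all(85:95 %in% region))
})
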