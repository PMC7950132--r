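# Centroid tables -> corrected uptake curves.

make_centroid_table <- function(uptakes, control = 800,
                                peptide_id = "pep_0001", state = "apo",
                                max_uptake = 8) {
  deut <- tibble::tibble(
    peptide_id = peptide_id, state = state,
    time_s = rep(c(15, 30, 45, 60, 120), each = length(uptakes) / 5),
    replicate = rep(seq_len(length(uptakes) / 5), times = 5),
    centroid_da = control + uptakes * MASS_D_MINUS_H,
    is_control = FALSE, max_uptake = max_uptake
  )
  ctrl <- tibble::tibble(peptide_id = peptide_id, state = state, time_s = 0,
                         replicate = 1L, centroid_da = control,
                         is_control = TRUE, max_uptake = max_uptake)
  dplyr::bind_rows(ctrl, deut)
}

test_that("raw uptake is the centroid shift over the deuteron mass", {
  tab <- make_centroid_table(rep(c(0, 1, 2, 3, 4), each = 3))
  raw <- compute_raw_uptake(tab)
  expect_equal(nrow(raw), 15)
  expect_equal(raw$uptake[raw$time_s == 15], rep(0, 3), tolerance = 1e-12)
  expect_equal(raw$uptake[raw$time_s == 120], rep(4, 3), tolerance = 1e-12)
})

test_that("peptides lacking a control are excluded and logged", {
  tab <- dplyr::bind_rows(
    make_centroid_table(rep(1, 15)),
    dplyr::filter(make_centroid_table(rep(2, 15), peptide_id = "pep_0002"),
                  !is_control)
  )
  expect_message(raw <- compute_raw_uptake(tab), "lacking a control")
  expect_false("pep_0002" %in% raw$peptide_id)
  excl <- attr(raw, "exclusions")
  expect_equal(excl$peptide_id, "pep_0002")
  expect_match(excl$reason, "control")
})

test_that("back-exchange estimator averages terminal saturation deficits", {
  map <- tibble::tibble(
    peptide_id = c("nterm", "cterm", "core"),
    sequence = NA_character_,
    start = c(1L, 91L, 40L), end = c(10L, 100L, 49L),
    max_uptake = c(8L, 8L, 8L))
  mk <- function(id, frac) tibble::tibble(
    peptide_id = id, state = "apo", time_s = c(60, 120), replicate = 1L,
    uptake = 8 * frac, max_uptake = 8L)
  recs <- dplyr::bind_rows(mk("nterm", 0.75), mk("cterm", 0.75),
                           mk("core", 0.2))
  expect_equal(as.numeric(estimate_back_exchange(recs, map,
                                                 sequence_length = 100)),
               0.25, tolerance = 1e-12)
  recs100 <- dplyr::bind_rows(mk("nterm", 1), mk("cterm", 1))
  expect_equal(as.numeric(estimate_back_exchange(recs100, map,
                                                 sequence_length = 100)), 0)
  two <- dplyr::bind_rows(mk("nterm", 0.70), mk("cterm", 0.80))
  expect_equal(as.numeric(estimate_back_exchange(two, map,
                                                 sequence_length = 100)),
               0.25, tolerance = 1e-12)
  # no terminal peptides -> estimation refused
  expect_error(
    estimate_back_exchange(mk("core", 0.5), map[3, ], sequence_length = 100),
    "explicit back-exchange")
})

test_that("back-exchange recovery from simulated disordered termini", {
  # noiseless: exact; with 0.02 Da noise: within +/-0.02
  for (noise in c(0, 0.02)) {
    seqv <- random_sequence(110, seed = 61, no_proline = TRUE)
    sys <- ground_truth_system(
      seqv, list(apo = protection_profile(110, 0)),
      back_exchange_fraction = 0.25, centroid_noise_sd = noise,
      disordered_termini = 110, rate_mode = "uniform")
    map <- generate_peptide_map(seqv, 10, 5)
    raw <- compute_raw_uptake(simulate_exchange_dataset(sys, map, seed = 77))
    est <- estimate_back_exchange(raw, map, terminal_window = 55)
    expect_gte(length(attr(est, "terminal_peptides")), 20)
    expect_equal(as.numeric(est), 0.25,
                 tolerance = if (noise == 0) 1e-9 else 0.02)
  }
})

test_that("correction divides by one minus the factor and clips", {
  expect_equal(correct_uptake(3.0, 0.25, 10), 4.0)
  expect_equal(correct_uptake(c(0, 2.5, 7), 0, 8), c(0, 2.5, 7))
  expect_equal(correct_uptake(9.0, 0.25, 10), 10.0)   # clipped above
  expect_equal(correct_uptake(-0.3, 0.25, 10), 0.0)   # clipped below
  expect_error(correct_uptake(1, 1, 10), "\\[0, 1\\)")
  expect_error(correct_uptake(1, 1.2, 10), "\\[0, 1\\)")
})

test_that("correction inverts simulated back exchange exactly when noiseless", {
  sys <- small_system(n = 60, noise_sd = 0, back_exchange = 0.3)
  map <- generate_peptide_map(sys$sequence, 10, 5)
  tab <- simulate_exchange_dataset(sys, map, seed = 2)
  raw <- compute_raw_uptake(tab)
  corr <- correct_uptake_table(raw, 0.3)
  truth <- attr(tab, "truth")
  joined <- dplyr::inner_join(corr, truth,
                              by = c("peptide_id", "state", "time_s"))
  expect_equal(joined$uptake, pmin(joined$true_uptake, joined$max_uptake),
               tolerance = 1e-9)
})

test_that("curve summaries give mean and SEM over technical replicates", {
  recs <- tibble::tibble(peptide_id = "p1", state = "apo",
                         time_s = rep(15, 3), replicate = 1:3,
                         uptake = c(4, 4, 4), max_uptake = 8L)
  c1 <- build_uptake_curves(recs)
  expect_equal(c1$mean_uptake, 4)
  expect_equal(c1$sem, 0)

  recs$uptake <- c(3, 4, 5)
  c2 <- build_uptake_curves(recs)
  expect_equal(c2$mean_uptake, 4)
  expect_equal(c2$sem, 1 / sqrt(3), tolerance = 1e-12)

  single <- recs[1, ]
  c3 <- build_uptake_curves(single)
  expect_equal(c3$mean_uptake, 3)
  expect_true(is.na(c3$sem))
})

test_that("curve summaries match a brute-force recomputation", {
  withr::with_seed(13, {
    recs <- tidyr::expand_grid(peptide_id = sprintf("p%d", 1:6),
                               state = c("A", "B"),
                               time_s = c(15, 30, 60), replicate = 1:3)
    recs$uptake <- stats::runif(nrow(recs), 0, 8)
    curves <- build_uptake_curves(recs)
    for (i in sample(nrow(curves), 10)) {
      sel <- recs$peptide_id == curves$peptide_id[i] &
        recs$state == curves$state[i] & recs$time_s == curves$time_s[i]
      vals <- recs$uptake[sel]
      expect_equal(curves$mean_uptake[i], sum(vals) / length(vals))
      expect_equal(curves$sem[i],
                   sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)) /
                     sqrt(length(vals)))
    }
  })
})

test_that("exponential fits recover known parameters", {
  t <- c(15, 30, 45, 60, 120)
  d <- 5 * (1 - exp(-0.05 * t))
  f <- fit_exponential(t, d, max_uptake = 8)
  expect_true(f$converged)
  expect_equal(f$A, 5, tolerance = 1e-6)
  expect_equal(f$k, 0.05, tolerance = 1e-6)

  z <- fit_exponential(t, rep(0, 5), max_uptake = 8)
  expect_equal(z$A, 0)
  expect_true(is.na(z$k))
  expect_match(z$message, "unidentifiable")
})

test_that("amplitude recovery is stable under replicate-level noise", {
  t <- c(15, 30, 45, 60, 120)
  truth <- 5 * (1 - exp(-0.05 * t))
  ests <- withr::with_seed(17, vapply(1:200, function(i) {
    fit_exponential(t, truth + stats::rnorm(5, 0, 0.1), max_uptake = 8)$A
  }, numeric(1)))
  expect_lt(abs(mean(ests) - 5), 0.3)
  expect_gt(mean(abs(ests - 5) < 0.3), 0.8)
})
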