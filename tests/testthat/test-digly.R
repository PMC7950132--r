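# diGly occupancy, linkage mapping, and mass arithmetic.

test_that("evidence score filter is strict at the cutoff", {
  ev <- tibble::tibble(sequence = "AGK", protein_id = "p", start = 1,
                       end = 3, modifications = "", area = 1,
                       score = c(15.0, 15.1, 40))
  kept <- filter_evidence(ev, 15)
  expect_equal(kept$score, c(15.1, 40))
  expect_equal(attr(kept, "rejections")$score, 15.0)
  empty <- filter_evidence(ev[0, ], 15)
  expect_equal(nrow(empty), 0)
})

test_that("occupancy is the digly area share among covering peptides", {
  prot <- "AAAKAAARGGKGG"  # lysines at 4 and 11
  ev <- tibble::tibble(
    sequence = "AAAKAAAR", protein_id = "p", start = 1, end = 8,
    modifications = c("digly@4", "", "", ""),
    area = c(25, 25, 25, 25), score = 30)
  occ <- site_occupancy(ev, prot)
  expect_equal(occ$occupancy[occ$position == 4], 0.25)
  # K11 uncovered: reported as no-coverage, not zero
  expect_true(is.na(occ$occupancy[occ$position == 11]))
  expect_false(occ$covered[occ$position == 11])
  # covered lysine without digly evidence: occupancy 0
  ev2 <- dplyr::mutate(ev, modifications = "")
  occ2 <- site_occupancy(ev2, prot)
  expect_equal(occ2$occupancy[occ2$position == 4], 0)
})

test_that("digly claims on non-lysine positions are rejected with a log", {
  prot <- "AAAKAAAR"
  ev <- tibble::tibble(
    sequence = c("AAAKAAAR", "AAAKAAAR"), protein_id = "p",
    start = 1, end = 8,
    modifications = c("digly@4", "digly@2"), area = 10, score = 30)
  expect_message(occ <- site_occupancy(ev, prot), "non-lysine")
  expect_equal(nrow(attr(occ, "rejections")), 1)
  # the bad record contributes to neither numerator nor denominator
  expect_equal(occ$total_area_sum[occ$position == 4], 10)
})

test_that("simulated occupancies are recovered within Monte-Carlo tolerance", {
  prot <- as.character(
    read_fasta(system.file("extdata", "demo_substrate_synthetic.fasta",
                           package = "hdxdigly"))[[1]])
  truth <- c(K45 = 0.6, K101 = 0.2, K107 = 0.2, K381 = 0.6)
  ev <- simulate_evidence_table(prot, truth, n_peptides_per_site = 50,
                                area_lognormal_sd = 0.5, seed = 55)
  occ <- site_occupancy(filter_evidence(ev), prot)
  got <- occ$occupancy[match(c(45, 101, 107, 381), occ$position)]
  expect_true(all(abs(got - unname(truth)) < 0.05))
})

test_that("linkage fractions are area-weighted and sum to one", {
  ub <- ubiquitin_sequence()
  expect_equal(nchar(ub), 76)
  expect_equal(substring(ub, 48, 48), "K")
  expect_equal(substring(ub, 63, 63), "K")

  one <- tibble::tibble(sequence = "LIFAGKQLEDGR", protein_id = "ubiquitin",
                        start = 43, end = 54, modifications = "digly@48",
                        area = 5, score = 30)
  l1 <- linkage_summary(one)
  expect_equal(l1$linkage, "K48")
  expect_equal(l1$fraction, 1)

  two <- dplyr::bind_rows(one, tibble::tibble(
    sequence = "TLSDYNIQKESTLHLVLR", protein_id = "ubiquitin",
    start = 55, end = 72, modifications = "digly@63", area = 5, score = 30))
  l2 <- linkage_summary(two)
  expect_equal(sort(l2$fraction), c(0.5, 0.5))
  expect_equal(sum(l2$fraction), 1)
})

test_that("a digly-bearing tryptic peptide spanning 43-54 maps to K48", {
  # oracle: in-silico tryptic digest of the shipped ubiquitin fixture
  ub <- ubiquitin_sequence()
  pep <- digest_trypsin(ub, missed_cleavages = 1)
  span <- pep[pep$start == 43 & pep$end == 54, ]
  expect_equal(nrow(span), 1)
  expect_equal(span$sequence, "LIFAGKQLEDGR")
  internal_k <- 42 + which(strsplit(span$sequence, "")[[1]] == "K")
  internal_k <- internal_k[internal_k < span$end]
  expect_equal(internal_k, 48)
  l <- linkage_summary(tibble::tibble(
    sequence = span$sequence, protein_id = "ubiquitin", start = span$start,
    end = span$end, modifications = paste0("digly@", internal_k),
    area = 1, score = 30))
  expect_equal(l$linkage, "K48")
})

test_that("digly at a non-lysine ubiquitin position is rejected", {
  bad <- tibble::tibble(sequence = "LIFAGKQLEDGR", protein_id = "ubiquitin",
                        start = 43, end = 54, modifications = "digly@50",
                        area = 1, score = 30)
  expect_message(l <- linkage_summary(bad), "non-lysine")
  expect_equal(nrow(l), 0)
  expect_equal(nrow(attr(l, "rejections")), 1)
})

test_that("mass arithmetic reproduces the printed analytic constants", {
  expect_equal(round(unname(MODIFICATION_DELTA["digly"]), 2), 114.04)
  expect_equal(unname(MODIFICATION_DELTA["digly"]), 2 * 57.02146,
               tolerance = 1e-4)
  expect_equal(round(mz(monoisotopic_mass("YGGFL"), 1), 3), 556.277)
  expect_equal(monoisotopic_mass("G"), 75.032, tolerance = 1e-3)
  expect_equal(monoisotopic_mass("AGK", "digly@3") -
                 monoisotopic_mass("AGK"),
               unname(MODIFICATION_DELTA["digly"]))
  expect_error(monoisotopic_mass("AGK", "glycation"), "unknown modification")
  expect_error(mz(500, 0), "positive integer")
})

test_that("monoisotopic mass is additive over all residue pairs", {
  aa <- rownames(RESIDUE_COMPOSITION)
  for (a in aa) {
    ma <- monoisotopic_mass(a)
    for (b in aa) {
      expect_equal(monoisotopic_mass(paste0(a, b)),
                   ma + monoisotopic_mass(b) - MASS_H2O,
                   tolerance = 1e-10)
    }
  }
})
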