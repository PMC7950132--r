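# Shared fixture builders: all synthetic, generated in code.

random_sequence <- function(n, seed, no_proline = FALSE, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y")
  }
  if (no_proline) alphabet <- setdiff(alphabet, "P")
  withr::with_seed(seed, paste(sample(alphabet, n, replace = TRUE),
                               collapse = ""))
}

# A compact two-state system: uniform protection, one destabilised
# region in the second state.
small_system <- function(n = 120, seed = 101, region = c(60, 75),
                         base_P = 4, delta_P = 1, noise_sd = 0.02,
                         back_exchange = 0.25, n_replicates = 3) {
  seqv <- random_sequence(n, seed, no_proline = TRUE)
  region <- pmin(region, n)
  states <- list(
    apo = protection_profile(n, base_P),
    bound = protection_profile(n, base_P, list(list(
      start = region[1], end = region[2],
      log10_P = max(base_P - delta_P, 0))))
  )
  ground_truth_system(seqv, states, back_exchange_fraction = back_exchange,
                      centroid_noise_sd = noise_sd,
                      n_replicates = n_replicates)
}

# The contiguous run of flagged residues that overlaps a core region
# (region calls rest on contiguity; isolated single-peptide calls are
# the expected false positives of an uncorrected alpha = 0.05 caller).
contiguous_block <- function(residues, core) {
  if (length(residues) == 0) return(integer(0))
  residues <- sort(residues)
  grp <- cumsum(c(1, diff(residues) != 1))
  blocks <- split(residues, grp)
  hit <- vapply(blocks, function(b) any(b %in% core), logical(1))
  sort(unique(unlist(blocks[hit])))
}

# Replicate-level uptake records for a single peptide in two states,
# built directly (no simulator) for statistics-level tests.
two_state_records <- function(mean_a, mean_b, sd, n_rep = 3,
                              timepoints = c(15, 30, 45, 60, 120),
                              seed = 1, peptide_id = "pep_0001",
                              start = 1, end = 11, max_uptake = 10) {
  withr::with_seed(seed, {
    grid <- expand.grid(time_idx = seq_along(timepoints),
                        replicate = seq_len(n_rep),
                        state = c("A", "B"), stringsAsFactors = FALSE)
    mu <- ifelse(grid$state == "A", mean_a[grid$time_idx],
                 mean_b[grid$time_idx])
    tibble::tibble(
      peptide_id = peptide_id, state = grid$state,
      time_s = timepoints[grid$time_idx], replicate = grid$replicate,
      uptake = stats::rnorm(nrow(grid), mu, sd),
      start = start, end = end, max_uptake = max_uptake
    )
  })
}
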