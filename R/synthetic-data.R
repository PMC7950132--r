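# Forward simulation of complete HDX-MS experiments and diGly evidence
# tables. The simulator is the package's ground-truth source: every
# downstream stage (uptake, back-exchange correction, differential
# calls, occupancy) is validated against it.

#' Build a per-residue protection-factor profile
#'
#' @param length Protein length (residues).
#' @param default Baseline log10 protection factor.
#' @param regions Optional list of `list(start =, end =, log10_P =)`
#'   entries overriding the baseline on 1-based inclusive intervals.
#' @return Numeric vector of log10 protection factors.
#' @export
protection_profile <- function(length, default = 4, regions = list()) {
  stopifnot(length >= 1, default >= 0)
  prof <- rep(as.numeric(default), length)
  for (r in regions) {
    stopifnot(r$start >= 1, r$end <= length, r$end >= r$start, r$log10_P >= 0)
    prof[r$start:r$end] <- r$log10_P
  }
  prof
}

#' Define a simulated HDX experiment (the simulator's truth object)
#'
#' Bundles the protein sequence, the per-state protection-factor
#' profiles, and the measurement parameters of a labelling experiment:
#' deuteration times, technical replicates, a global back-exchange
#' fraction, and Gaussian centroid noise. The first and last
#' `disordered_termini` residues are forced to log10 P = 0 in every
#' state, emulating the disordered chain ends from which the global
#' back-exchange factor is estimated.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param states Named list of per-residue log10 protection-factor
#'   vectors (see [protection_profile]), one per conformational state.
#' @param back_exchange_fraction Fraction of incorporated deuterium lost
#'   during quench and chromatography, in `[0, 1)`. Default 0.25, the
#'   typical magnitude of the global correction factor.
#' @param centroid_noise_sd Gaussian SD added to deuterated centroids (Da).
#' @param timepoints Deuteration times in seconds, strictly increasing.
#'   Default `c(15, 30, 45, 60, 120)`.
#' @param n_replicates Technical replicates per condition. Default 3.
#' @param disordered_termini Width (residues) of the unprotected
#'   terminal windows. Default 10.
#' @param protein Protein label used in output tables.
#' @param pD,temperature_K Labelling conditions for [intrinsic_rates].
#' @param rate_mode Passed to [intrinsic_rates] (`"reference"` or
#'   `"uniform"`).
#' @return An object of class `ground_truth_system`.
#' @export
ground_truth_system <- function(sequence, states,
                                back_exchange_fraction = 0.25,
                                centroid_noise_sd = 0.02,
                                timepoints = c(15, 30, 45, 60, 120),
                                n_replicates = 3,
                                disordered_termini = 10,
                                protein = "protein1",
                                pD = 8.0, temperature_K = 298.15,
                                rate_mode = "reference") {
  residues <- split_residues(sequence)
  n <- length(residues)
  if (!is.list(states) || length(states) == 0L) {
    stop("states must be a non-empty named list of log10_P profiles",
         call. = FALSE)
  }
  nm <- names(states)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("state names must be unique and non-empty", call. = FALSE)
  }
  states <- lapply(states, function(p) {
    p <- as.numeric(p)
    if (length(p) != n) {
      stop("each log10_P profile must match the sequence length (", n, ")",
           call. = FALSE)
    }
    if (any(p < 0)) stop("log10_P must be >= 0", call. = FALSE)
    if (disordered_termini > 0) {
      w <- min(disordered_termini, n)
      p[seq_len(w)] <- 0
      p[seq.int(n - w + 1L, n)] <- 0
    }
    p
  })
  stopifnot(back_exchange_fraction >= 0, back_exchange_fraction < 1,
            centroid_noise_sd >= 0, n_replicates >= 1,
            length(timepoints) >= 1, all(timepoints > 0),
            !is.unsorted(timepoints, strictly = TRUE))
  structure(
    list(sequence = toupper(sequence), residues = residues, states = states,
         back_exchange_fraction = back_exchange_fraction,
         centroid_noise_sd = centroid_noise_sd,
         timepoints = as.numeric(timepoints),
         n_replicates = as.integer(n_replicates),
         disordered_termini = as.integer(disordered_termini),
         protein = protein, pD = pD, temperature_K = temperature_K,
         rate_mode = rate_mode),
    class = "ground_truth_system"
  )
}

#' @export
print.ground_truth_system <- function(x, ...) {
  cat("<ground_truth_system> ", nchar(x$sequence), " residues, ",
      length(x$states), " state(s): ", paste(names(x$states), collapse = ", "),
      "\n  timepoints (s): ", paste(x$timepoints, collapse = ", "),
      "; replicates: ", x$n_replicates,
      "; back-exchange: ", x$back_exchange_fraction,
      "; noise SD: ", x$centroid_noise_sd, " Da\n", sep = "")
  invisible(x)
}

#' Pepsin-like peptide map by overlapped tiling
#'
#' Tiles a protein with fixed-length, overlapping peptides (a
#' deterministic stand-in for pepsin digestion, whose cleavage is
#' broadly non-specific). Optional length jitter gives more
#' realistic ragged maps while staying reproducible under a seed.
#'
#' @param sequence Protein sequence.
#' @param target_length Peptide length in residues (>= 3).
#' @param overlap Overlap between consecutive peptides (< target_length).
#' @param jitter Maximum +/- perturbation (residues) applied to each
#'   peptide's end. Default 0 (pure tiling).
#' @param seed Integer seed used when `jitter > 0`.
#' @param protein Protein label stored in the map.
#' @return A `peptide_map` tibble with columns `peptide_id`, `sequence`,
#'   `start`, `end`, `max_uptake`; the protein sequence and label are
#'   carried as attributes.
#' @export
generate_peptide_map <- function(sequence, target_length = 10, overlap = 5,
                                 jitter = 0, seed = NULL,
                                 protein = "protein1") {
  residues <- split_residues(sequence)
  n <- length(residues)
  stopifnot(target_length >= 3, overlap >= 0, overlap < target_length,
            jitter >= 0)
  if (n <= target_length) {
    starts <- 1L
    ends <- n
  } else {
    step <- target_length - overlap
    starts <- seq.int(1L, n - target_length + 1L, by = step)
    if (starts[length(starts)] != n - target_length + 1L) {
      starts <- c(starts, n - target_length + 1L)
    }
    ends <- starts + target_length - 1L
    if (jitter > 0) {
      if (is.null(seed)) stop("jitter > 0 requires a seed", call. = FALSE)
      withr::with_seed(as.integer(seed) %% 2147483647L, {
        ends <- ends + sample.int(2L * jitter + 1L, length(ends),
                                  replace = TRUE) - jitter - 1L
      })
      ends <- pmin(pmax(ends, starts + 2L), n)
      ends[length(ends)] <- n  # keep the C-terminus covered
    }
  }
  keep <- !duplicated(paste(starts, ends))
  starts <- starts[keep]
  ends <- ends[keep]
  seqs <- vapply(seq_along(starts), function(i) {
    paste(residues[starts[i]:ends[i]], collapse = "")
  }, character(1))
  map <- tibble::tibble(
    peptide_id = sprintf("pep_%04d", seq_along(starts)),
    sequence = seqs,
    start = as.integer(starts),
    end = as.integer(ends),
    max_uptake = vapply(seqs, exchangeable_amides, integer(1),
                        USE.NAMES = FALSE)
  )
  attr(map, "protein_sequence") <- paste(residues, collapse = "")
  attr(map, "protein") <- protein
  class(map) <- c("peptide_map", class(map))
  map
}

# Deterministic per-record seed: mixes the user seed with record
# coordinates so adding peptides/states never reshuffles existing draws.
cell_seed <- function(seed, ...) {
  mod <- 2147483629
  h <- as.numeric(seed) %% mod
  for (p in list(...)) {
    codes <- if (is.character(p)) utf8ToInt(p) else round(as.numeric(p) * 1000)
    for (x in codes) h <- (h * 48271 + (x %% mod) + 1) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under the record's private stream. The generator is
# warmed up first: the first Mersenne-Twister output after seeding is
# weakly correlated across related seeds, which would miscalibrate
# replicate noise.
with_cell_stream <- function(seed, components, expr) {
  withr::with_seed(do.call(cell_seed, c(list(seed), components)), {
    stats::runif(10)
    expr
  })
}

#' Simulate a centroid table for a full HDX-MS experiment
#'
#' For every (peptide, state, timepoint, replicate) cell the measured
#' deuterated centroid is the peptide's natural-envelope centroid plus
#' `1.00628 * (1 - back_exchange) * sum(per-amide deuterium fractions)`
#' plus Gaussian centroid noise. Per-amide fractions follow the EX2
#' forward model ([intrinsic_rates], [deuterium_fraction]) under the
#' state's protection profile. One noiseless undeuterated control row
#' per (peptide, state) is included; the control is treated as known
#' exactly (in practice it is averaged over many scans and checked
#' manually), so measurement noise enters through the deuterated rows.
#'
#' @param system A [ground_truth_system].
#' @param map A peptide map from [generate_peptide_map] (must be
#'   consistent with the system's sequence).
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return A centroid-table tibble with columns `protein`, `peptide_id`,
#'   `sequence`, `start`, `end`, `state`, `time_s`, `replicate`,
#'   `centroid_da`, `is_control`, `max_uptake`. Ground-truth per-cell
#'   uptake (before back exchange and noise) is attached as attribute
#'   `"truth"`.
#' @export
simulate_exchange_dataset <- function(system, map, seed) {
  stopifnot(inherits(system, "ground_truth_system"))
  check_map_against_sequence(map, system$sequence)
  residues <- system$residues
  rates <- intrinsic_rates(system$sequence, pD = system$pD,
                           temperature_K = system$temperature_K,
                           mode = system$rate_mode)
  k_int <- rates$k_int

  # per-state, per-timepoint residue-level deuterium fractions
  frac <- lapply(system$states, function(prof) {
    k_obs <- k_int / 10^prof
    sapply(system$timepoints, function(t) {
      f <- -expm1(-k_obs * t)
      f[!rates$exchangeable] <- 0
      f
    })
  })

  control_centroid <- vapply(map$sequence,
                             function(s) centroid(natural_envelope(s)),
                             numeric(1), USE.NAMES = FALSE)

  b <- system$back_exchange_fraction
  n_pep <- nrow(map)
  tp <- system$timepoints
  state_names <- names(system$states)

  # ground-truth uptake per (state, peptide, timepoint), before back
  # exchange and noise
  sum_frac <- lapply(state_names, function(s) {
    t(vapply(seq_len(n_pep), function(i) {
      pos <- amide_positions(map$start[i], map$end[i], residues)
      pos <- pos[rates$exchangeable[pos]]
      if (length(pos) == 0L) rep(0, length(tp))
      else colSums(frac[[s]][pos, , drop = FALSE])
    }, numeric(length(tp))))
  })
  names(sum_frac) <- state_names

  truth <- tidyr::expand_grid(peptide_idx = seq_len(n_pep),
                              state = state_names,
                              time_idx = seq_along(tp))
  truth$peptide_id <- map$peptide_id[truth$peptide_idx]
  truth$time_s <- tp[truth$time_idx]
  truth$true_uptake <- mapply(function(s, i, j) sum_frac[[s]][i, j],
                              truth$state, truth$peptide_idx, truth$time_idx)

  deut <- tidyr::expand_grid(peptide_idx = seq_len(n_pep),
                             state = state_names,
                             time_idx = seq_along(tp),
                             replicate = seq_len(system$n_replicates))
  deut$peptide_id <- map$peptide_id[deut$peptide_idx]
  deut$time_s <- tp[deut$time_idx]
  deut$true_uptake <- mapply(function(s, i, j) sum_frac[[s]][i, j],
                             deut$state, deut$peptide_idx, deut$time_idx)
  noise <- if (system$centroid_noise_sd > 0) {
    vapply(seq_len(nrow(deut)), function(i) {
      with_cell_stream(
        seed,
        list(deut$peptide_id[i], deut$state[i], deut$time_s[i],
             deut$replicate[i]),
        stats::rnorm(1, 0, system$centroid_noise_sd)
      )
    }, numeric(1))
  } else 0
  deut$centroid_da <- control_centroid[deut$peptide_idx] +
    MASS_D_MINUS_H * (1 - b) * deut$true_uptake + noise
  deut$is_control <- FALSE

  ctrl <- tidyr::expand_grid(peptide_idx = seq_len(n_pep),
                             state = state_names)
  ctrl$peptide_id <- map$peptide_id[ctrl$peptide_idx]
  ctrl$time_s <- 0
  ctrl$replicate <- 1L
  ctrl$centroid_da <- control_centroid[ctrl$peptide_idx]
  ctrl$is_control <- TRUE

  keep_cols <- c("peptide_id", "state", "time_s", "replicate",
                 "centroid_da", "is_control", "peptide_idx")
  out <- dplyr::bind_rows(ctrl[, keep_cols], deut[, keep_cols])
  out <- dplyr::arrange(out, .data$peptide_idx, .data$state,
                        dplyr::desc(.data$is_control), .data$time_s,
                        .data$replicate)
  out$peptide_idx <- NULL
  out <- dplyr::left_join(
    out,
    dplyr::mutate(tibble::as_tibble(map), protein = attr(map, "protein")),
    by = "peptide_id"
  )
  out <- dplyr::select(out, "protein", "peptide_id", "sequence", "start",
                       "end", "state", "time_s", "replicate", "centroid_da",
                       "is_control", "max_uptake")
  attr(out, "truth") <- dplyr::select(truth, "peptide_id", "state", "time_s",
                                      "true_uptake")
  out
}

check_map_against_sequence <- function(map, sequence) {
  stopifnot(inherits(map, "peptide_map") || all(
    c("peptide_id", "sequence", "start", "end", "max_uptake") %in% names(map)))
  n <- nchar(sequence)
  if (any(map$start < 1) || any(map$end > n) || any(map$end < map$start)) {
    stop("peptide map coordinates fall outside the protein sequence",
         call. = FALSE)
  }
  slices <- substring(sequence, map$start, map$end)
  if (any(slices != map$sequence)) {
    stop("peptide map sequences do not match the protein sequence",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a diGly peptide-evidence table
#'
#' Emulates a label-free, acetylated, trypsin-digested evidence table:
#' for each lysine with a specified ubiquitylation occupancy, a
#' missed-cleavage tryptic peptide carrying the lysine internally is
#' selected, and paired diGly-modified / acetylated (unmodified-lysine)
#' evidence rows are generated whose expected area ratio equals the
#' occupancy. Areas are `area_scale` times independent log-normal
#' deviates; scores are drawn well above the usual identification
#' cutoff.
#'
#' @param protein Protein sequence.
#' @param site_occupancy Named numeric vector of occupancies in
#'   `[0, 1]`; names are lysine positions, either bare integers or
#'   `"K45"`-style labels.
#' @param n_peptides_per_site Evidence rows generated per site and form.
#' @param area_scale Median ion-current area.
#' @param area_lognormal_sd SD (log scale) of the multiplicative area
#'   noise; 0 gives exact areas.
#' @param seed Integer seed; fixed seed gives a deterministic table.
#' @param protein_id Protein label for the `protein_id` column.
#' @return An evidence tibble with columns `sequence`, `protein_id`,
#'   `start`, `end`, `modifications`, `area`, `score`.
#' @export
simulate_evidence_table <- function(protein, site_occupancy = numeric(0),
                                    n_peptides_per_site = 10,
                                    area_scale = 1e6,
                                    area_lognormal_sd = 0.5,
                                    seed = 1, protein_id = "protein1") {
  residues <- split_residues(protein)
  sites <- parse_lysine_sites(site_occupancy, residues)
  peptides <- digest_trypsin(protein, missed_cleavages = 3)
  rows <- list()
  for (i in seq_along(sites$position)) {
    p <- sites$position[i]
    occ <- sites$occupancy[i]
    cand <- peptides[peptides$start <= p & peptides$end >= p &
                       peptides$end > p, , drop = FALSE]
    if (nrow(cand) == 0L) {
      cand <- peptides[peptides$start <= p & peptides$end >= p, , drop = FALSE]
    }
    pep <- cand[which.min(cand$end - cand$start), , drop = FALSE]
    for (form in c("digly", "acetyl")) {
      share <- if (form == "digly") occ else 1 - occ
      if (share <= 0) next
      for (r in seq_len(n_peptides_per_site)) {
        noise <- if (area_lognormal_sd > 0) {
          with_cell_stream(seed, list(p, form, r),
                           stats::rlnorm(1, 0, area_lognormal_sd))
        } else 1
        score <- with_cell_stream(seed, list(p, form, r, 7L),
                                  stats::runif(1, 20, 60))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sequence = pep$sequence, protein_id = protein_id,
          start = pep$start, end = pep$end,
          modifications = paste0(form, "@", p),
          area = share * area_scale * noise,
          score = score
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(sequence = character(0), protein_id = character(0),
                          start = integer(0), end = integer(0),
                          modifications = character(0), area = numeric(0),
                          score = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

parse_lysine_sites <- function(site_occupancy, residues) {
  if (length(site_occupancy) == 0L) {
    return(list(position = integer(0), occupancy = numeric(0)))
  }
  nm <- names(site_occupancy)
  if (is.null(nm)) stop("site_occupancy must be named by lysine position",
                        call. = FALSE)
  pos <- as.integer(sub("^[Kk]", "", nm))
  if (any(is.na(pos))) stop("unparseable lysine labels: ",
                            paste(nm[is.na(pos)], collapse = ", "),
                            call. = FALSE)
  if (any(pos < 1 | pos > length(residues))) {
    stop("lysine positions outside the protein", call. = FALSE)
  }
  not_k <- pos[residues[pos] != "K"]
  if (length(not_k) > 0L) {
    stop("occupancy specified on non-lysine position(s): ",
         paste(not_k, collapse = ", "), call. = FALSE)
  }
  occ <- as.numeric(site_occupancy)
  if (any(occ < 0 | occ > 1)) stop("occupancies must lie in [0, 1]",
                                   call. = FALSE)
  list(position = pos, occupancy = occ)
}

#' In-silico tryptic digest
#'
#' Cleaves after K or R, except before proline; returns all peptides
#' with up to `missed_cleavages` internal missed cleavage sites.
#'
#' @param sequence Protein sequence.
#' @param missed_cleavages Maximum internal missed cleavages.
#' @return Tibble with `start`, `end`, `sequence`, `n_missed`.
#' @export
digest_trypsin <- function(sequence, missed_cleavages = 2) {
  residues <- split_residues(sequence)
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & residues[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  starts0 <- bounds[-length(bounds)] + 1L
  ends0 <- bounds[-1]
  rows <- list()
  n_frag <- length(starts0)
  for (i in seq_len(n_frag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > n_frag) break
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = starts0[i], end = ends0[j], n_missed = m
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sequence <- substring(paste(residues, collapse = ""), out$start, out$end)
  dplyr::select(out, "start", "end", "sequence", "n_missed")
}
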