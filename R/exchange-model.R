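# Residue-level forward model of backbone-amide H/D exchange under the
# EX2 limit: each amide exchanges with first-order rate
# k_obs = k_int / P, where k_int is the intrinsic (unstructured-context)
# rate and P >= 1 the protection factor.

# Side-chain inductive corrections to the poly-DL-alanine reference
# rates (log10, relative to alanine). For the amide NH of residue i,
# acid- and base-catalysed rates are scaled by the residue's own side
# chain ("own") and by the preceding residue's side chain ("next", its
# effect on the following amide). Ionisable side chains (D, E, H) use
# their high-pD forms, appropriate near the pD 8 labelling conditions.
BAI_SIDE_CHAIN <- local({
  m <- rbind(
    #     acid_own acid_next base_own base_next
    A = c( 0.00,  0.00,  0.00,  0.00),
    C = c(-0.54, -0.46,  0.62,  0.55),
    D = c( 0.90,  0.58, -0.30, -0.18),
    E = c(-0.90,  0.31, -0.51, -0.15),
    F = c(-0.52, -0.43, -0.24,  0.06),
    G = c(-0.22,  0.22,  0.27,  0.17),
    H = c( 0.00,  0.00, -0.10,  0.14),
    I = c(-0.91, -0.59, -0.73, -0.23),
    K = c(-0.56, -0.29, -0.04,  0.12),
    L = c(-0.57, -0.13, -0.58, -0.21),
    M = c(-0.64, -0.28, -0.01,  0.11),
    N = c(-0.58, -0.13,  0.49,  0.32),
    P = c(   NA, -0.19,    NA, -0.24),
    Q = c(-0.47, -0.27,  0.06,  0.20),
    R = c(-0.59, -0.32,  0.08,  0.22),
    S = c(-0.44, -0.39,  0.37,  0.30),
    T = c(-0.79, -0.47, -0.07,  0.20),
    V = c(-0.74, -0.30, -0.70, -0.14),
    W = c(-0.40, -0.44, -0.41, -0.11),
    Y = c(-0.41, -0.37, -0.27,  0.05)
  )
  colnames(m) <- c("acid_own", "acid_next", "base_own", "base_next")
  m
})

# Poly-DL-alanine reference rate constants in D2O at 293 K (log10 of
# rates in min^-1, with catalyst terms in M^-1 min^-1), activation
# energies in cal/mol, and the D2O autoionisation pK.
BAI_REFERENCE <- list(
  lg_kA = 1.62, lg_kB = 10.18, lg_kW = -1.5,
  Ea_A = 14000, Ea_B = 17000, Ea_W = 19000,
  pKD = 15.05, T_ref = 293, R_gas = 1.9872,
  # charged-terminus corrections (log10): protonated N-terminal amine on
  # the second residue's amide; C-terminal carboxylate on the last amide
  nterm_acid = -1.32, nterm_base = 1.62,
  cterm_acid = 0.96, cterm_base = -1.80
)

#' Intrinsic amide exchange rates for a sequence
#'
#' Computes per-residue intrinsic hydrogen-deuterium exchange rates for
#' backbone amides in an unstructured context, using poly-DL-alanine
#' reference rates with published side-chain inductive corrections,
#' acid/base/water catalysis and Arrhenius temperature scaling. The
#' first residue (no backbone amide in a chain context, only an
#' alpha-amine) and prolines (no amide hydrogen) are flagged
#' non-exchanging.
#'
#' @param sequence Protein or peptide sequence (one-letter codes).
#' @param pD Corrected pD of the labelling buffer. Default 8.0, matching
#'   Tris-HCl pH 8.0 labelling conditions.
#' @param temperature_K Labelling temperature in kelvin. Default 298.15
#'   (25 C).
#' @param mode `"reference"` (default) for the sequence-dependent model,
#'   or `"uniform"` for a flat rate at every exchangeable position
#'   (useful in unit tests).
#' @param uniform_rate Rate (1/s) used when `mode = "uniform"`.
#' @return A tibble with columns `residue_index`, `amino_acid`,
#'   `exchangeable` (logical) and `k_int` (1/s; `NA` where
#'   non-exchanging).
#' @examples
#' intrinsic_rates("AGAMDE")
#' @export
intrinsic_rates <- function(sequence, pD = 8.0, temperature_K = 298.15,
                            mode = c("reference", "uniform"),
                            uniform_rate = 1) {
  mode <- match.arg(mode)
  res <- split_residues(sequence)
  n <- length(res)
  stopifnot(is.numeric(pD), length(pD) == 1L, is.finite(pD),
            is.numeric(temperature_K), length(temperature_K) == 1L,
            temperature_K > 0)
  exchangeable <- rep(TRUE, n)
  exchangeable[1] <- FALSE          # alpha-amine, not a backbone amide
  exchangeable[res == "P"] <- FALSE # proline has no amide hydrogen

  k <- rep(NA_real_, n)
  if (mode == "uniform") {
    stopifnot(is.numeric(uniform_rate), uniform_rate >= 0)
    k[exchangeable] <- uniform_rate
  } else {
    ref <- BAI_REFERENCE
    arr <- function(Ea) exp(-Ea / ref$R_gas * (1 / temperature_K - 1 / ref$T_ref))
    conc_D <- 10^(-pD)
    conc_OD <- 10^(pD - ref$pKD)
    for (i in which(exchangeable)) {
      lgFA <- BAI_SIDE_CHAIN[res[i], "acid_own"] +
        BAI_SIDE_CHAIN[res[i - 1], "acid_next"]
      lgFB <- BAI_SIDE_CHAIN[res[i], "base_own"] +
        BAI_SIDE_CHAIN[res[i - 1], "base_next"]
      if (i == 2L) {
        lgFA <- lgFA + ref$nterm_acid
        lgFB <- lgFB + ref$nterm_base
      }
      if (i == n) {
        lgFA <- lgFA + ref$cterm_acid
        lgFB <- lgFB + ref$cterm_base
      }
      kA <- 10^(ref$lg_kA + lgFA) * conc_D * arr(ref$Ea_A)
      kB <- 10^(ref$lg_kB + lgFB) * conc_OD * arr(ref$Ea_B)
      kW <- 10^(ref$lg_kW + lgFB) * arr(ref$Ea_W)
      k[i] <- (kA + kB + kW) / 60  # table rates are per minute
    }
  }
  tibble::tibble(
    residue_index = seq_len(n),
    amino_acid = res,
    exchangeable = exchangeable,
    k_int = k
  )
}

#' Deuterium fraction under first-order exchange
#'
#' Fraction of an amide population carrying deuterium after labelling
#' time `t` under EX2 first-order kinetics: `1 - exp(-k_obs * t)`.
#'
#' @param k_obs Observed exchange rate(s), 1/s (`k_int / P`).
#' @param t Labelling time(s) in seconds.
#' @return Numeric fraction(s) in `[0, 1]`; vectorised with the usual
#'   recycling rules.
#' @examples
#' deuterium_fraction(0.01, 120)
#' @export
deuterium_fraction <- function(k_obs, t) {
  if (any(!is.finite(k_obs)) || any(k_obs < 0)) {
    stop("k_obs must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and non-negative", call. = FALSE)
  }
  -expm1(-k_obs * t)
}

#' Number of exchangeable backbone amides in a peptide
#'
#' The convention used for uptake-plot y-limits: the peptide's first
#' residue is excluded (its amide deuterium is lost too rapidly during
#' quench and chromatography to be observed), as are all prolines.
#'
#' @param peptide Peptide sequence (one-letter codes).
#' @return Integer count, never negative.
#' @examples
#' exchangeable_amides("APPLE") # 2
#' @export
exchangeable_amides <- function(peptide) {
  res <- split_residues(peptide, "peptide")
  if (length(res) == 1L) return(0L)
  tail_res <- res[-1]
  length(tail_res) - sum(tail_res == "P")
}

#' Positions (within a protein) of a peptide's exchangeable amides
#'
#' @param start,end 1-based inclusive residue coordinates.
#' @param residues Character vector of the protein's residues.
#' @return Integer vector of residue indices carrying observable amides.
#' @keywords internal
#' @noRd
amide_positions <- function(start, end, residues) {
  pos <- seq.int(start + 1L, length.out = max(end - start, 0L))
  pos[residues[pos] != "P"]
}
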