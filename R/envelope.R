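# Isotope envelopes and mass-envelope centroids. Uptake is measured as
# the centroid shift of the deuterated envelope relative to the
# undeuterated control, divided by the 2H-1H mass difference.

#' Construct an isotope envelope
#'
#' @param masses Strictly increasing numeric vector of neutral masses (Da).
#' @param intensities Non-negative weights; normalised to sum to 1.
#' @param charge Optional positive integer charge for m/z views.
#' @return An object of class `isotope_envelope`.
#' @export
isotope_envelope <- function(masses, intensities, charge = NULL) {
  stopifnot(is.numeric(masses), is.numeric(intensities),
            length(masses) == length(intensities), length(masses) > 0)
  if (any(!is.finite(masses)) || any(!is.finite(intensities))) {
    stop("masses and intensities must be finite", call. = FALSE)
  }
  if (is.unsorted(masses, strictly = TRUE)) {
    stop("masses must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  tot <- sum(intensities)
  if (tot <= 0) stop("total intensity must be positive", call. = FALSE)
  if (!is.null(charge)) {
    stopifnot(is.numeric(charge), length(charge) == 1L, charge >= 1)
    charge <- as.integer(charge)
  }
  structure(
    list(masses = as.numeric(masses), intensities = intensities / tot,
         charge = charge),
    class = "isotope_envelope"
  )
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat("<isotope_envelope> ", length(x$masses), " peaks, centroid ",
      format(centroid(x), digits = 9), " Da\n", sep = "")
  invisible(x)
}

# Aggregated (unit-resolution) isotopologue classes, indexed by total
# nominal mass offset k = 0, 1, 2, ...: element `p[k+1]` is the class
# probability and `m[k+1]` its probability-weighted mean mass.

dist_single_atom <- function(element) {
  iso <- ELEMENT_ISOTOPES[[element]]
  off <- round(iso$mass - iso$mass[1])
  p <- numeric(max(off) + 1)
  m <- numeric(max(off) + 1)
  p[off + 1] <- iso$abundance
  m[off + 1] <- iso$mass
  list(p = p, m = m)
}

# Convolve two aggregated distributions; classes beyond `cap` offsets
# or below 1e-15 total probability are dropped (they are invisible at
# peptide scale).
convolve_dist <- function(a, b, cap = 64L) {
  ka <- length(a$p)
  kb <- length(b$p)
  k <- min(ka + kb - 1L, cap)
  p <- numeric(k)
  pm <- numeric(k)
  for (i in seq_len(ka)) {
    if (a$p[i] == 0) next
    jmax <- min(kb, k - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    w <- a$p[i] * b$p[seq_len(jmax)]
    p[idx] <- p[idx] + w
    pm[idx] <- pm[idx] + w * (a$m[i] + b$m[seq_len(jmax)])
  }
  m <- ifelse(p > 0, pm / p, 0)
  keep <- max(which(p > 1e-15), 1L)
  list(p = p[seq_len(keep)], m = m[seq_len(keep)])
}

# n-fold self-convolution by binary exponentiation.
element_distribution <- function(element, n) {
  base <- dist_single_atom(element)
  result <- list(p = 1, m = 0)
  while (n > 0L) {
    if (n %% 2L == 1L) result <- convolve_dist(result, base)
    n <- n %/% 2L
    if (n > 0L) base <- convolve_dist(base, base)
  }
  result
}

#' Natural (undeuterated) isotope envelope of a peptide
#'
#' Builds the aggregated isotopic distribution from the peptide's
#' elemental composition (residue formulas plus one water), with exact
#' isotope masses and natural abundances. The lightest peak is the
#' monoisotopic mass; peaks are unit-mass isotopologue classes at their
#' abundance-weighted mean masses, which is sufficient for centroid
#' work.
#'
#' @param peptide Peptide sequence (one-letter codes).
#' @param prune Drop isotopologue classes below this total probability.
#' @return An [isotope_envelope].
#' @examples
#' natural_envelope("YGGFL")
#' @export
natural_envelope <- function(peptide, prune = 1e-10) {
  res <- split_residues(peptide, "peptide")
  counts <- colSums(RESIDUE_COMPOSITION[res, , drop = FALSE])
  counts["H"] <- counts["H"] + 2  # terminal water
  counts["O"] <- counts["O"] + 1
  dist <- list(p = 1, m = 0)
  for (el in names(counts)) {
    if (counts[[el]] > 0) {
      dist <- convolve_dist(dist, element_distribution(el,
                                                       as.integer(counts[[el]])))
    }
  }
  keep <- dist$p > prune
  isotope_envelope(dist$m[keep], dist$p[keep])
}

#' Exact Poisson-binomial distribution
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with probabilities `probs`, computed by iterative convolution.
#'
#' @param probs Vector of success probabilities in `[0, 1]`.
#' @return Numeric vector of length `length(probs) + 1`; element `d + 1`
#'   is `P(D = d)`.
#' @export
poisson_binomial <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("per-amide fractions must lie in [0, 1]", call. = FALSE)
  }
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Deuterate an isotope envelope
#'
#' Convolves the natural envelope with the exact Poisson-binomial
#' distribution of incorporated deuteron counts given per-amide
#' deuterium fractions. The centroid shifts by exactly
#' `sum(per_amide_fractions)` times the 2H-1H mass difference
#' (1.00628 Da).
#'
#' @param env An [isotope_envelope].
#' @param per_amide_fractions Deuterium fractions, one per exchangeable
#'   amide, each in `[0, 1]`.
#' @param prune Drop combined peaks below this intensity.
#' @return A new normalised [isotope_envelope].
#' @export
deuterate_envelope <- function(env, per_amide_fractions, prune = 1e-12) {
  stopifnot(inherits(env, "isotope_envelope"))
  if (length(per_amide_fractions) == 0L) return(env)
  pmf <- poisson_binomial(per_amide_fractions)
  d <- seq_along(pmf) - 1
  masses <- as.vector(outer(env$masses, d * MASS_D_MINUS_H, `+`))
  wts <- as.vector(outer(env$intensities, pmf))
  agg <- tapply(wts, masses, sum)
  keep <- agg > prune
  m <- as.numeric(names(agg))[keep]
  w <- as.numeric(agg[keep])
  ord <- order(m)
  isotope_envelope(m[ord], w[ord], charge = env$charge)
}

#' Centroid (intensity-weighted mean mass) of an envelope
#'
#' @param env An [isotope_envelope].
#' @return Centroid mass in Da.
#' @export
centroid <- function(env) {
  stopifnot(inherits(env, "isotope_envelope"))
  sum(env$masses * env$intensities)
}

#' Deuterons incorporated, from centroid difference
#'
#' Converts the shift between a deuterated centroid and its undeuterated
#' control into a deuteron count by dividing by the 2H-1H mass
#' difference. Small negative values can arise from measurement noise
#' and are reported as-is (correction and clipping happen downstream).
#'
#' @param deuterated_centroid,control_centroid Centroid masses (Da).
#' @return Deuterons (may be fractional or slightly negative).
#' @export
uptake_from_centroids <- function(deuterated_centroid, control_centroid) {
  if (any(!is.finite(deuterated_centroid)) || any(!is.finite(control_centroid))) {
    stop("centroids must be finite", call. = FALSE)
  }
  (deuterated_centroid - control_centroid) / MASS_D_MINUS_H
}

#' Write an envelope to a two-column CSV
#'
#' @param env An [isotope_envelope].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "isotope_envelope"))
  readr::write_csv(tibble::tibble(mass = env$masses,
                                  intensity = env$intensities), path)
  invisible(path)
}
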