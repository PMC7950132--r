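# Monoisotopic masses, isotope abundances, residue compositions and
# modification deltas used throughout the package. All masses in Da.

# Exact isotope masses and natural abundances (IUPAC/CIAAW values).
ELEMENT_ISOTOPES <- list(
  C = list(mass = c(12, 13.0033548350), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017779), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984), abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Elemental composition (C, H, N, O, S) of amino-acid residues
# (i.e. amino acid minus water, as they occur in a chain).
RESIDUE_COMPOSITION <- rbind(
  G = c(2, 3, 1, 1, 0),
  A = c(3, 5, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),
  V = c(5, 9, 1, 1, 0),
  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),
  L = c(6, 11, 1, 1, 0),
  I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0),
  E = c(5, 7, 1, 3, 0),
  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),
  F = c(9, 9, 1, 1, 0),
  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),
  W = c(11, 10, 2, 1, 0)
)
colnames(RESIDUE_COMPOSITION) <- c("C", "H", "N", "O", "S")

AMINO_ACIDS <- rownames(RESIDUE_COMPOSITION)

# Monoisotopic residue masses derived from the compositions above.
RESIDUE_MASS <- drop(RESIDUE_COMPOSITION %*%
                       vapply(colnames(RESIDUE_COMPOSITION),
                              function(el) ELEMENT_ISOTOPES[[el]]$mass[1],
                              numeric(1)))

MASS_H2O <- 2 * ELEMENT_ISOTOPES$H$mass[1] + ELEMENT_ISOTOPES$O$mass[1]
MASS_PROTON <- 1.00727646688
# Mass gained when an amide H is replaced by D (2H - 1H).
MASS_D_MINUS_H <- ELEMENT_ISOTOPES$H$mass[2] - ELEMENT_ISOTOPES$H$mass[1]

# Modification monoisotopic deltas. The diGly remnant is two glycine
# residues left on a ubiquitylated lysine after tryptic cleavage of
# ubiquitin's C-terminal -LRGG.
MODIFICATION_DELTA <- c(
  digly = 2 * 57.0214637,
  acetyl = 42.0105646863,
  carbamidomethyl = 57.0214637,
  other = 0
)

#' Validate an amino-acid sequence
#'
#' @param sequence Single string of one-letter amino-acid codes.
#' @param what Label used in error messages.
#' @return Character vector of single residues.
#' @keywords internal
#' @noRd
split_residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(what, " must be a non-empty string of one-letter amino-acid codes",
         call. = FALSE)
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop("unknown residue code '", res[bad[1]], "' at position ", bad[1],
         " of ", what, call. = FALSE)
  }
  res
}
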