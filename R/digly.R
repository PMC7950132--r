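# Per-lysine ubiquitylation occupancy and ubiquitin chain-linkage usage
# from diGly-remnant peptide evidence, by the label-free area-ratio
# statistic: summed area of diGly-bearing peptides at a lysine divided
# by summed area of all peptides covering that lysine.

#' Filter evidence rows by identification score
#'
#' Retains rows with `-10 log P` score strictly greater than the
#' cutoff.
#'
#' @param records Evidence tibble (see [read_evidence]).
#' @param score_cutoff Strict lower bound on the score. Default 15.
#' @return Retained subset; rejected rows attached as attribute
#'   `"rejections"`.
#' @export
filter_evidence <- function(records, score_cutoff = 15) {
  if (!"score" %in% names(records)) {
    stop("evidence table lacks a 'score' column", call. = FALSE)
  }
  keep <- records$score > score_cutoff
  retained <- records[keep, , drop = FALSE]
  attr(retained, "rejections") <- records[!keep, , drop = FALSE]
  retained
}

# Parse a "type@pos;type@pos" modification string into a tibble.
parse_modifications <- function(mods) {
  if (is.na(mods) || mods == "" || mods == "none") {
    return(tibble::tibble(type = character(0), position = integer(0)))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*([A-Za-z]+)\\s*@\\s*([0-9]+)\\s*$",
                                 parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("unparseable modification entry: '", parts[bad][1], "'",
         call. = FALSE)
  }
  type <- tolower(vapply(m, `[`, character(1), 2))
  unknown <- setdiff(unique(type), names(MODIFICATION_DELTA))
  if (length(unknown) > 0L) {
    stop("unknown modification name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(type = type,
                 position = as.integer(vapply(m, `[`, character(1), 3)))
}

# diGly positions for each record; validates that positions fall inside
# the record's coordinates.
record_digly_positions <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    mods <- parse_modifications(records$modifications[i])
    if (nrow(mods) > 0L &&
        (any(mods$position < records$start[i]) ||
         any(mods$position > records$end[i]))) {
      stop("modification position outside peptide coordinates in row ", i,
           call. = FALSE)
    }
    mods$position[mods$type == "digly"]
  })
}

#' Per-lysine ubiquitylation occupancy
#'
#' For every lysine in the protein sequence, sums the areas of evidence
#' rows carrying a diGly remnant at that position and divides by the
#' summed area of all rows whose coordinates cover the position
#' (whatever their modification state, acetylated and missed-cleavage
#' forms included). Records claiming a diGly on a non-lysine position
#' are rejected and logged.
#'
#' @param records Evidence tibble with `start`, `end`, `modifications`,
#'   `area` (1-based inclusive coordinates on `sequence`).
#' @param sequence Protein sequence the records are mapped to.
#' @return Tibble with one row per lysine: `position`,
#'   `digly_area_sum`, `total_area_sum`, `occupancy` (`NA` when the
#'   lysine has no covering evidence), `n_evidence`, `covered`.
#'   Rejected records are attached as attribute `"rejections"`.
#' @export
site_occupancy <- function(records, sequence) {
  residues <- split_residues(sequence)
  lys <- which(residues == "K")
  digly_pos <- record_digly_positions(records)
  bad <- vapply(digly_pos, function(p) any(residues[p] != "K"), logical(1))
  if (any(bad)) {
    message("site_occupancy: rejected ", sum(bad),
            " record(s) with a diGly on a non-lysine position")
  }
  rec <- records[!bad, , drop = FALSE]
  digly_pos <- digly_pos[!bad]
  out <- lapply(lys, function(p) {
    covering <- rec$start <= p & rec$end >= p
    with_digly <- covering &
      vapply(digly_pos, function(q) p %in% q, logical(1))
    total <- sum(rec$area[covering])
    dig <- sum(rec$area[with_digly])
    tibble::tibble(
      position = p,
      digly_area_sum = dig,
      total_area_sum = total,
      occupancy = if (any(covering) && total > 0) dig / total else NA_real_,
      n_evidence = sum(covering),
      covered = any(covering)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "rejections") <- records[bad, , drop = FALSE]
  out
}

#' Ubiquitin chain-linkage usage from diGly evidence
#'
#' Classifies diGly positions on ubiquitin-mapped evidence by the
#' lysine they sit on (K6, K11, K27, K29, K33, K48, K63) or by M1
#' (linear linkage) and reports area fractions per linkage, summing to
#' 1 over observed linkages.
#'
#' @param records Evidence tibble mapped to ubiquitin coordinates.
#' @param ubiquitin Ubiquitin sequence; defaults to the canonical
#'   76-residue human ubiquitin shipped with the package.
#' @return Tibble with `linkage`, `area_sum`, `fraction`. Records with
#'   a diGly at a non-lysine, non-M1 position are rejected and attached
#'   as attribute `"rejections"`.
#' @export
linkage_summary <- function(records, ubiquitin = ubiquitin_sequence()) {
  residues <- split_residues(ubiquitin)
  valid_pos <- c(1L, which(residues == "K"))
  digly_pos <- record_digly_positions(records)
  bad <- vapply(digly_pos, function(p) length(p) > 0 && any(!p %in% valid_pos),
                logical(1))
  if (any(bad)) {
    message("linkage_summary: rejected ", sum(bad),
            " record(s) with a diGly at a non-lysine, non-M1 position")
  }
  rec <- records[!bad, , drop = FALSE]
  digly_pos <- digly_pos[!bad]
  rows <- list()
  for (i in seq_along(digly_pos)) {
    for (p in digly_pos[[i]]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        linkage = if (p == 1L) "M1" else paste0("K", p),
        area = rec$area[i])
    }
  }
  if (length(rows) == 0L) {
    out <- tibble::tibble(linkage = character(0), area_sum = numeric(0),
                          fraction = numeric(0))
  } else {
    out <- dplyr::bind_rows(rows) |>
      dplyr::group_by(.data$linkage) |>
      dplyr::summarise(area_sum = sum(.data$area), .groups = "drop") |>
      dplyr::mutate(fraction = .data$area_sum / sum(.data$area_sum)) |>
      dplyr::arrange(dplyr::desc(.data$fraction))
  }
  attr(out, "rejections") <- records[bad, , drop = FALSE]
  out
}

#' Canonical human ubiquitin sequence (76 residues)
#'
#' @return Single string; read from the FASTA fixture shipped with the
#'   package.
#' @export
ubiquitin_sequence <- function() {
  path <- system.file("extdata", "ubiquitin_human.fasta",
                      package = "hdxdigly", mustWork = TRUE)
  as.character(read_fasta(path)[[1]])
}

#' Monoisotopic peptide mass with modifications
#'
#' Sum of residue monoisotopic masses plus one water plus modification
#' deltas (diGly 114.043, acetyl 42.011, carbamidomethyl 57.021 Da).
#'
#' @param peptide Peptide sequence.
#' @param modifications Either a `"type@pos"` semicolon string or a
#'   character vector of modification names.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' monoisotopic_mass("YGGFL")
#' @export
monoisotopic_mass <- function(peptide, modifications = character(0)) {
  res <- split_residues(peptide, "peptide")
  mods <- if (is.character(modifications) && length(modifications) == 1L &&
              grepl("@", modifications)) {
    parse_modifications(modifications)$type
  } else if (length(modifications) == 0L) {
    character(0)
  } else {
    tolower(as.character(modifications))
  }
  unknown <- setdiff(mods, names(MODIFICATION_DELTA))
  if (length(unknown) > 0L) {
    stop("unknown modification name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(RESIDUE_MASS[res]) + MASS_H2O + sum(MODIFICATION_DELTA[mods])
}

#' m/z of a peptide ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return `(mass + charge * 1.007276) / charge`.
#' @examples
#' mz(monoisotopic_mass("YGGFL"), 1) # leu-enkephalin [M+H]+
#' @export
mz <- function(mass, charge) {
  stopifnot(is.numeric(mass), is.numeric(charge))
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (mass + charge * MASS_PROTON) / charge
}
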