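# File formats: FASTA sequences, the long-format state-data CSV
# (centroid tables), evidence CSVs, and the YAML experiment config.

STATE_DATA_COLUMNS <- c("protein", "peptide_id", "sequence", "start", "end",
                        "state", "time_s", "replicate", "centroid_da",
                        "is_control", "max_uptake")

EVIDENCE_COLUMNS <- c("sequence", "protein_id", "start", "end",
                      "modifications", "area", "score")

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  Biostrings::readAAStringSet(path)
}

#' Write a centroid table as long-format state-data CSV
#'
#' @param table Centroid table ([simulate_exchange_dataset]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_data <- function(table, path) {
  missing <- setdiff(STATE_DATA_COLUMNS, names(table))
  if (length(missing) > 0L) {
    stop("state-data table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table[, STATE_DATA_COLUMNS], path)
  invisible(path)
}

#' Read a long-format state-data CSV
#'
#' Validates the header (all mandatory columns must be present, by
#' name) and drops malformed rows (unparseable numbers, inverted
#' coordinates), logging how many were rejected.
#'
#' @param path CSV with the [write_state_data] layout. Exposure times
#'   are seconds.
#' @return Centroid-table tibble; rejected rows are attached as
#'   attribute `"rejected_rows"` and reported via `message()`.
#' @export
read_state_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    stop("state-data file is empty: ", path, call. = FALSE)
  }
  missing <- setdiff(STATE_DATA_COLUMNS, names(raw))
  if (length(missing) > 0L) {
    stop("state-data file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("state-data file has no rows: ", path,
                            call. = FALSE)
  conv <- dplyr::mutate(
    raw,
    start = suppressWarnings(as.integer(.data$start)),
    end = suppressWarnings(as.integer(.data$end)),
    time_s = suppressWarnings(as.numeric(.data$time_s)),
    replicate = suppressWarnings(as.integer(.data$replicate)),
    centroid_da = suppressWarnings(as.numeric(.data$centroid_da)),
    is_control = tolower(.data$is_control) %in% c("true", "t", "1"),
    max_uptake = suppressWarnings(as.integer(.data$max_uptake))
  )
  ok <- !is.na(conv$start) & !is.na(conv$end) & conv$end >= conv$start &
    !is.na(conv$time_s) & !is.na(conv$replicate) &
    is.finite(conv$centroid_da) & !is.na(conv$max_uptake) &
    !is.na(conv$peptide_id) & !is.na(conv$state)
  if (any(!ok)) {
    message("read_state_data: rejected ", sum(!ok), " malformed row(s)")
  }
  out <- conv[ok, STATE_DATA_COLUMNS]
  attr(out, "rejected_rows") <- raw[!ok, , drop = FALSE]
  out
}

#' Write / read evidence tables
#'
#' Minimal PEAKS-style evidence dialect: `sequence`, `protein_id`,
#' `start`, `end`, `modifications` (semicolon-separated `type@pos`,
#' empty for none), `area`, `score` (-10 log P).
#'
#' @param records Evidence tibble.
#' @param path CSV path.
#' @return `path` (write) or the evidence tibble (read).
#' @export
write_evidence <- function(records, path) {
  missing <- setdiff(EVIDENCE_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(records[, EVIDENCE_COLUMNS], path)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      sequence = readr::col_character(),
      protein_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      modifications = readr::col_character(),
      area = readr::col_double(),
      score = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(EVIDENCE_COLUMNS, names(out))
  if (length(missing) > 0L) {
    stop("evidence file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out$modifications[is.na(out$modifications)] <- ""
  out
}

#' Read an experiment configuration (YAML)
#'
#' The config defines a [ground_truth_system] plus peptide-map
#' parameters and, optionally, a diGly simulation block. Layout:
#'
#' ```yaml
#' sequence: MKT...          # or: fasta: path/to/file.fasta
#' states:
#'   - name: apo
#'     default_log10_P: 4
#'     regions: [{start: 439, end: 450, log10_P: 3}]
#' back_exchange: 0.25
#' noise_sd: 0.02
#' timepoints: [15, 30, 45, 60, 120]
#' n_replicates: 3
#' disordered_termini: 10
#' map: {target_length: 10, overlap: 5}
#' digly:                    # optional
#'   occupancy: {K45: 0.6, K101: 0.2}
#'   n_peptides_per_site: 50
#' ```
#'
#' @param path YAML file.
#' @param base_dir Directory for resolving a relative `fasta:` entry;
#'   defaults to the config's directory.
#' @return List with elements `system` ([ground_truth_system]), `map`
#'   (peptide-map parameter list) and `digly` (list or `NULL`).
#' @export
read_system_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  sequence <- if (!is.null(cfg$sequence)) {
    cfg$sequence
  } else if (!is.null(cfg$fasta)) {
    fp <- cfg$fasta
    if (!file.exists(fp)) fp <- file.path(base_dir, cfg$fasta)
    as.character(read_fasta(fp)[[1]])
  } else {
    stop("config must provide 'sequence' or 'fasta'", call. = FALSE)
  }
  n <- nchar(sequence)
  if (is.null(cfg$states) || length(cfg$states) == 0L) {
    stop("config must define at least one state", call. = FALSE)
  }
  states <- list()
  for (s in cfg$states) {
    if (is.null(s$name)) stop("every state needs a name", call. = FALSE)
    regions <- lapply(s$regions, function(r) {
      list(start = r$start, end = r$end, log10_P = r$log10_P)
    })
    states[[s$name]] <- protection_profile(
      n, default = s$default_log10_P %||% 4, regions = regions %||% list())
  }
  system <- ground_truth_system(
    sequence, states,
    back_exchange_fraction = cfg$back_exchange %||% 0.25,
    centroid_noise_sd = cfg$noise_sd %||% 0.02,
    timepoints = unlist(cfg$timepoints %||% c(15, 30, 45, 60, 120)),
    n_replicates = cfg$n_replicates %||% 3,
    disordered_termini = cfg$disordered_termini %||% 10,
    protein = cfg$protein %||% "protein1"
  )
  map_params <- list(
    target_length = cfg$map$target_length %||% 10,
    overlap = cfg$map$overlap %||% 5,
    jitter = cfg$map$jitter %||% 0
  )
  list(system = system, map = map_params, digly = cfg$digly)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
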