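# From centroid tables to back-exchange-corrected uptake curves:
# centroid differencing against undeuterated controls, the global
# back-exchange correction estimated from disordered termini, per-
# timepoint means +/- SEM over technical replicates, and bounded
# exponential fits for display.

#' Raw deuterium uptake from a centroid table
#'
#' Subtracts each (peptide, state) undeuterated control centroid from
#' the deuterated centroids and converts the shift to deuterons.
#' Peptides lacking a control row for a state are excluded and logged.
#'
#' @param table Centroid table as produced by
#'   [simulate_exchange_dataset] or [read_state_data] (long format with
#'   `is_control` flag).
#' @return Tibble of deuterated rows with an `uptake` column (deuterons,
#'   uncorrected; may be slightly negative under noise). Control rows
#'   are consumed, not emitted. Exclusions are attached as attribute
#'   `"exclusions"` (tibble of `peptide_id`, `state`, `reason`).
#' @export
compute_raw_uptake <- function(table) {
  required <- c("peptide_id", "state", "time_s", "replicate", "centroid_da",
                "is_control")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    stop("centroid table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  controls <- table |>
    dplyr::filter(.data$is_control) |>
    dplyr::group_by(.data$peptide_id, .data$state) |>
    dplyr::summarise(control_centroid = mean(.data$centroid_da),
                     .groups = "drop")
  deut <- dplyr::filter(table, !.data$is_control)
  joined <- dplyr::left_join(deut, controls, by = c("peptide_id", "state"))
  excluded <- joined |>
    dplyr::filter(is.na(.data$control_centroid)) |>
    dplyr::distinct(.data$peptide_id, .data$state) |>
    dplyr::mutate(reason = "missing undeuterated control")
  if (nrow(excluded) > 0L) {
    message("compute_raw_uptake: excluded ", nrow(excluded),
            " (peptide, state) cell(s) lacking a control row")
  }
  out <- joined |>
    dplyr::filter(!is.na(.data$control_centroid)) |>
    dplyr::mutate(uptake = uptake_from_centroids(.data$centroid_da,
                                                 .data$control_centroid)) |>
    dplyr::select(-"control_centroid", -"is_control")
  attr(out, "exclusions") <- excluded
  out
}

#' Estimate the global back-exchange correction factor
#'
#' Uses peptides lying wholly within a terminal window of the protein,
#' where the chain is disordered and exchange saturates well before the
#' longest deuteration time. The factor is one minus the mean
#' fraction-of-maximum uptake of those peptides at the longest
#' timepoint, i.e. the average fraction of label lost to back exchange.
#'
#' @param uptake_records Output of [compute_raw_uptake].
#' @param map Peptide map ([generate_peptide_map]) giving coordinates
#'   and `max_uptake`; the protein length is taken from its attributes
#'   unless `sequence_length` is supplied.
#' @param terminal_window Width (residues) of the terminal windows.
#'   Default 10.
#' @param sequence_length Protein length override.
#' @return Estimated fraction in `[0, 0.9]`. The terminal peptide ids
#'   used are attached as attribute `"terminal_peptides"`.
#' @export
estimate_back_exchange <- function(uptake_records, map, terminal_window = 10,
                                   sequence_length = NULL) {
  if (is.null(sequence_length)) {
    seq_attr <- attr(map, "protein_sequence")
    if (is.null(seq_attr)) {
      stop("supply sequence_length or a map carrying its protein sequence",
           call. = FALSE)
    }
    sequence_length <- nchar(seq_attr)
  }
  terminal <- map[(map$end <= terminal_window) |
                    (map$start >= sequence_length - terminal_window + 1L), ,
                  drop = FALSE]
  terminal <- terminal[terminal$max_uptake > 0, , drop = FALSE]
  if (nrow(terminal) == 0L) {
    stop("no peptide lies wholly within ", terminal_window,
         " residues of a protein end; supply an explicit back-exchange ",
         "factor instead", call. = FALSE)
  }
  t_max <- max(uptake_records$time_s)
  rows <- uptake_records |>
    dplyr::filter(.data$peptide_id %in% terminal$peptide_id,
                  .data$time_s == t_max) |>
    dplyr::left_join(terminal[, c("peptide_id", "max_uptake")],
                     by = "peptide_id", suffix = c("", ".map"))
  mu <- if ("max_uptake" %in% names(uptake_records)) rows$max_uptake
        else rows$max_uptake.map
  if (nrow(rows) == 0L) {
    stop("no uptake measurements at the longest timepoint for terminal ",
         "peptides", call. = FALSE)
  }
  factor <- 1 - mean(rows$uptake / mu)
  factor <- min(max(factor, 0), 0.9)
  attr(factor, "terminal_peptides") <- unique(rows$peptide_id)
  factor
}

#' Apply the global back-exchange correction
#'
#' Divides raw uptake by `1 - factor`, restoring saturated disordered
#' regions to 100% of their exchangeable amides, then clips to
#' `[0, max_uptake]` (noise can drive raw values slightly negative or
#' the corrected value slightly above the amide count).
#'
#' @param raw Raw uptake (deuterons); vectorised.
#' @param factor Back-exchange fraction in `[0, 1)`.
#' @param max_uptake Exchangeable-amide count(s) used as the upper clip.
#' @return Corrected uptake (deuterons).
#' @export
correct_uptake <- function(raw, factor, max_uptake) {
  stopifnot(is.numeric(factor), length(factor) == 1L)
  if (!is.finite(factor) || factor < 0 || factor >= 1) {
    stop("back-exchange factor must lie in [0, 1)", call. = FALSE)
  }
  corrected <- raw / (1 - factor)
  pmin(pmax(corrected, 0), max_uptake)
}

#' Correct every row of an uptake table
#'
#' Convenience wrapper applying [correct_uptake] to the `uptake` column,
#' using each row's `max_uptake`.
#'
#' @param uptake_records Output of [compute_raw_uptake] (must carry
#'   `max_uptake`).
#' @param factor Back-exchange fraction.
#' @return The records with `uptake` replaced by corrected values and a
#'   `corrected` flag column.
#' @export
correct_uptake_table <- function(uptake_records, factor) {
  stopifnot("max_uptake" %in% names(uptake_records))
  uptake_records |>
    dplyr::mutate(uptake = correct_uptake(.data$uptake, factor,
                                          .data$max_uptake),
                  corrected = TRUE)
}

#' Summarise replicate uptake into curves
#'
#' @param records Replicate-level uptake records (raw or corrected).
#' @return Tibble with one row per (peptide, state, timepoint): `n`
#'   replicates, `mean_uptake`, `sem` (`NA` when fewer than 2
#'   replicates; SD over technical replicates divided by sqrt(n)), plus
#'   coordinates and `max_uptake` when available.
#' @export
build_uptake_curves <- function(records) {
  extra <- intersect(c("protein", "sequence", "start", "end", "max_uptake"),
                     names(records))
  curves <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("peptide_id", "state", "time_s", extra)))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_uptake = mean(.data$uptake),
      sem = if (dplyr::n() >= 2L) {
        stats::sd(.data$uptake) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$peptide_id, .data$state, .data$time_s)
  curves
}

#' Fit a bounded single exponential to an uptake curve
#'
#' Fits `D(t) = A * (1 - exp(-k * t))` by bounded Levenberg-Marquardt
#' least squares with `0 <= A <= max_uptake` and `k > 0`. This is the
#' display-level summary used on uptake plots; it is not a kinetic
#' decomposition.
#'
#' @param time_s Timepoints (seconds).
#' @param mean_uptake Mean uptake at each timepoint (deuterons).
#' @param max_uptake Upper bound for the amplitude.
#' @return List with `A`, `k`, `converged` (logical), `rss` and
#'   `message`. An all-zero curve returns `A = 0` with `k = NA`
#'   (unidentifiable) and `converged = TRUE`.
#' @export
fit_exponential <- function(time_s, mean_uptake, max_uptake) {
  stopifnot(length(time_s) == length(mean_uptake), length(time_s) >= 3)
  if (all(abs(mean_uptake) < 1e-12)) {
    return(list(A = 0, k = NA_real_, converged = TRUE, rss = 0,
                message = "all-zero curve; rate unidentifiable"))
  }
  df <- data.frame(t = time_s, d = mean_uptake)
  a0 <- min(max(max(mean_uptake), 1e-6), max_uptake)
  # crude initial rate from the earliest positive uptake
  first_pos <- which(mean_uptake > 0)[1]
  k0 <- if (!is.na(first_pos) && mean_uptake[first_pos] < 0.95 * a0) {
    -log(1 - min(mean_uptake[first_pos] / a0, 0.95)) / time_s[first_pos]
  } else 1 / min(time_s)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ A * (1 - exp(-k * t)), data = df,
                      start = list(A = a0, k = max(k0, 1e-6)),
                      lower = c(0, 1e-9), upper = c(max_uptake, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(A = NA_real_, k = NA_real_, converged = FALSE, rss = NA_real_,
                message = conditionMessage(fit)))
  }
  est <- stats::coef(fit)
  list(A = unname(est["A"]), k = unname(est["k"]), converged = TRUE,
       rss = sum(stats::resid(fit)^2), message = "ok")
}

#' Fit exponentials to every curve in a summary table
#'
#' @param curves Output of [build_uptake_curves].
#' @return Tibble with one row per (peptide, state): `A`, `k`,
#'   `converged`, `rss`, `fit_message`.
#' @export
fit_uptake_curves <- function(curves) {
  curves |>
    dplyr::group_by(.data$peptide_id, .data$state) |>
    dplyr::group_modify(function(d, key) {
      mu <- if ("max_uptake" %in% names(d)) d$max_uptake[1] else Inf
      f <- fit_exponential(d$time_s, d$mean_uptake, mu)
      tibble::tibble(A = f$A, k = f$k, converged = f$converged,
                     rss = f$rss, fit_message = f$message)
    }) |>
    dplyr::ungroup()
}
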