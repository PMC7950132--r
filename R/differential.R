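# Peptide-quality filtering and state-vs-state significance calling:
# two-way ANOVA (state x time) on replicate uptake plus per-timepoint
# Welch t-tests, with verdicts mapped down to residue level.

#' Filter peptide identifications by quality thresholds
#'
#' Retains peptides meeting all of: identification score at least
#' `score_cutoff`, products per amino acid at least `min_products`,
#' MH+ error at most `max_mh_error_ppm`, retention-time SD at most
#' `max_rt_sd_percent`, and observation in at least `min_runs` of the
#' identification runs. Thresholds are inclusive.
#'
#' @param ids Tibble with columns `peptide_id`, `score`,
#'   `products_per_aa`, `mh_error_ppm`, `rt_sd_percent`, `runs_observed`.
#' @param score_cutoff,min_products,max_mh_error_ppm,max_rt_sd_percent,min_runs
#'   Quality thresholds; defaults are the conventional DynamX-style
#'   values (6.5, 0.2, 5 ppm, 5%, 2 of 3 runs).
#' @return The retained subset. Rejections, with the first failed rule,
#'   are attached as attribute `"rejections"`.
#' @export
filter_peptides <- function(ids, score_cutoff = 6.5, min_products = 0.2,
                            max_mh_error_ppm = 5, max_rt_sd_percent = 5,
                            min_runs = 2) {
  required <- c("peptide_id", "score", "products_per_aa", "mh_error_ppm",
                "rt_sd_percent", "runs_observed")
  missing <- setdiff(required, names(ids))
  if (length(missing) > 0L) {
    stop("identification table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rule <- dplyr::case_when(
    ids$score < score_cutoff ~ "score below cutoff",
    ids$products_per_aa < min_products ~ "too few products per amino acid",
    ids$mh_error_ppm > max_mh_error_ppm ~ "MH+ error above tolerance",
    ids$rt_sd_percent > max_rt_sd_percent ~ "retention-time SD above tolerance",
    ids$runs_observed < min_runs ~ "seen in too few identification runs",
    TRUE ~ NA_character_
  )
  retained <- ids[is.na(rule), , drop = FALSE]
  rejections <- dplyr::mutate(ids[!is.na(rule), , drop = FALSE],
                              failed_rule = rule[!is.na(rule)])
  attr(retained, "rejections") <- rejections
  retained
}

#' Compare deuterium uptake between two states
#'
#' For each peptide shared by both states, runs a two-way ANOVA
#' (state x timepoint) on replicate-level uptake and a Welch two-sample
#' t-test at every shared timepoint. A peptide is called significant
#' when the ANOVA state effect and at least one per-timepoint t-test
#' fall below `alpha`; the verdict direction follows the sign of the
#' uptake difference (B minus A) at the most significant timepoint.
#' Both p-value layers are reported so alternative composite rules can
#' be audited.
#'
#' @param records Replicate-level uptake records (ideally
#'   back-exchange-corrected; the correction is monotone so verdicts
#'   are unchanged) covering both states, with columns `peptide_id`,
#'   `state`, `time_s`, `replicate`, `uptake`.
#' @param state_a,state_b State labels; differences are `state_b -
#'   state_a`, so "increased" means more exchange in `state_b`.
#' @param alpha Significance cutoff. Default 0.05.
#' @param t_variant `"student"` (default) for the pooled-variance
#'   two-sample t-test, whose size is exact at n = 3 technical
#'   replicates when the two states share measurement noise — the case
#'   the simulator realises — or `"welch"` for the unequal-variance
#'   form.
#' @param p_adjust Multiple-testing adjustment applied across peptides
#'   to the ANOVA p-values (`"none"`, the default, or any
#'   [stats::p.adjust] method such as `"BH"`).
#' @return Tibble with one row per peptide: `anova_p`, list-column
#'   `t_tests` (per-timepoint `time_s`, `delta_uptake`, `p`),
#'   `delta_max` (delta at the most significant timepoint), `verdict`
#'   (`"increased"`, `"decreased"`, `"not-significant"`), and peptide
#'   coordinates when present. Skipped peptides are attached as
#'   attribute `"skipped"`.
#' @export
compare_states <- function(records, state_a, state_b, alpha = 0.05,
                           t_variant = c("student", "welch"),
                           p_adjust = "none") {
  stopifnot(alpha > 0, alpha < 1)
  t_variant <- match.arg(t_variant)
  recs <- dplyr::filter(records, .data$state %in% c(state_a, state_b))
  if (nrow(recs) == 0L) stop("no records for the requested states",
                             call. = FALSE)
  skipped <- list()
  results <- list()
  coord_cols <- intersect(c("start", "end", "sequence", "max_uptake"),
                          names(recs))
  for (pid in unique(recs$peptide_id)) {
    d <- recs[recs$peptide_id == pid, , drop = FALSE]
    ta <- sort(unique(d$time_s[d$state == state_a]))
    tb <- sort(unique(d$time_s[d$state == state_b]))
    if (length(ta) == 0L || length(tb) == 0L || !identical(ta, tb)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        peptide_id = pid, reason = "timepoints missing or mismatched between states")
      next
    }
    reps_ok <- d |>
      dplyr::count(.data$state, .data$time_s) |>
      dplyr::pull(.data$n)
    if (any(reps_ok < 2L)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        peptide_id = pid, reason = "fewer than 2 replicates in a cell")
      next
    }
    d$state_f <- factor(d$state, levels = c(state_a, state_b))
    d$time_f <- factor(d$time_s)
    an <- stats::anova(stats::lm(uptake ~ state_f * time_f, data = d))
    anova_p <- an[trimws(rownames(an)) == "state_f", "Pr(>F)"]
    tt <- lapply(ta, function(t) {
      ua <- d$uptake[d$state == state_a & d$time_s == t]
      ub <- d$uptake[d$state == state_b & d$time_s == t]
      delta <- mean(ub) - mean(ua)
      # a t-test on (near-)constant replicates is degenerate: call the
      # difference itself
      p <- tryCatch(stats::t.test(ub, ua,
                                  var.equal = t_variant == "student")$p.value,
                    error = function(e) if (abs(delta) > 1e-12) 0 else 1)
      tibble::tibble(time_s = t, delta_uptake = delta, p = p)
    })
    tt <- dplyr::bind_rows(tt)
    res <- tibble::tibble(peptide_id = pid, anova_p = anova_p,
                          t_tests = list(tt),
                          delta_max = tt$delta_uptake[which.min(tt$p)])
    for (cc in coord_cols) res[[cc]] <- d[[cc]][1]
    results[[length(results) + 1L]] <- res
  }
  if (length(results) == 0L) stop("no peptide could be compared", call. = FALSE)
  out <- dplyr::bind_rows(results)
  out$anova_p_adj <- stats::p.adjust(out$anova_p, method = p_adjust)
  out$verdict <- vapply(seq_len(nrow(out)), function(i) {
    tt <- out$t_tests[[i]]
    if (out$anova_p_adj[i] < alpha && any(tt$p < alpha)) {
      if (out$delta_max[i] > 0) "increased" else "decreased"
    } else "not-significant"
  }, character(1))
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  attr(out, "states") <- c(state_a, state_b)
  attr(out, "alpha") <- alpha
  out
}

#' Project peptide-level differential calls onto residues
#'
#' Classifies each residue by consensus over the significant peptides
#' covering it: the strict majority direction wins; an exact tie (or
#' any residue where increased and decreased calls balance) is flagged
#' `"ambiguous"`. Residues covered only by non-significant peptides are
#' `"not-significant"`; residues with no covering peptide are
#' `"no-coverage"`.
#'
#' @param results Output of [compare_states].
#' @param map Peptide map giving coordinates for every peptide in
#'   `results`.
#' @return Tibble with one row per residue: `residue`, `amino_acid`
#'   (when the map carries its protein sequence), `n_covering`,
#'   `n_increased`, `n_decreased`, `classification`.
#' @export
residue_level_map <- function(results, map) {
  if (!all(results$peptide_id %in% map$peptide_id)) {
    stop("results reference peptides absent from the map", call. = FALSE)
  }
  res <- dplyr::left_join(
    results[, c("peptide_id", "verdict")],
    map[, c("peptide_id", "start", "end")], by = "peptide_id")
  seq_attr <- attr(map, "protein_sequence")
  n <- if (!is.null(seq_attr)) nchar(seq_attr) else max(map$end)
  n_cov <- integer(n); n_inc <- integer(n); n_dec <- integer(n)
  for (i in seq_len(nrow(res))) {
    idx <- res$start[i]:res$end[i]
    n_cov[idx] <- n_cov[idx] + 1L
    if (res$verdict[i] == "increased") n_inc[idx] <- n_inc[idx] + 1L
    if (res$verdict[i] == "decreased") n_dec[idx] <- n_dec[idx] + 1L
  }
  classification <- dplyr::case_when(
    n_cov == 0L ~ "no-coverage",
    n_inc == 0L & n_dec == 0L ~ "not-significant",
    n_inc > n_dec ~ "increased",
    n_dec > n_inc ~ "decreased",
    TRUE ~ "ambiguous"
  )
  out <- tibble::tibble(residue = seq_len(n), n_covering = n_cov,
                        n_increased = n_inc, n_decreased = n_dec,
                        classification = classification)
  if (!is.null(seq_attr)) {
    out <- dplyr::mutate(out,
                         amino_acid = strsplit(seq_attr, "")[[1]],
                         .after = "residue")
  }
  out
}

#' Flatten differential results for CSV export
#'
#' @param results Output of [compare_states].
#' @return Wide tibble with per-timepoint `delta_<t>s` and `p_<t>s`
#'   columns alongside `anova_p` and `verdict`.
#' @export
flatten_differential <- function(results) {
  long <- results |>
    dplyr::select(dplyr::any_of(c("peptide_id", "start", "end", "anova_p",
                                  "verdict", "t_tests"))) |>
    tidyr::unnest("t_tests")
  wide <- long |>
    tidyr::pivot_wider(
      names_from = "time_s",
      values_from = c("delta_uptake", "p"),
      names_glue = "{.value}_{time_s}s"
    )
  wide
}
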