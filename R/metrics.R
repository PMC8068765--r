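#' Precision, recall and F1 from TP/FP/FN counts
#'
#' Vectorized over counts. Undefined ratios (zero denominators) are returned
#' as `NA`, never as 0: a pipeline that called nothing has no precision, and
#' coercing it to 0 would distort every downstream average. F1 is computed
#' from the raw counts (`2*tp / (2*tp + fp + fn)`), which equals the harmonic
#' mean of precision and recall without double rounding, and is `NA` whenever
#' either component is undefined or both are 0.
#'
#' @param tp,fp,fn Non-negative integer vectors of equal length.
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' prf(tp = 9, fp = 1, fn = 27)  # precision 0.9, recall 0.25, f1 ~ 0.391
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0, na.rm = TRUE), all(fp >= 0, na.rm = TRUE),
            all(fn >= 0, na.rm = TRUE))
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * tp / (2 * tp + fp + fn), NA_real_)
  tibble(precision = precision, recall = recall, f1 = f1)
}

#' Score classifications into per-unit metric records
#'
#' @param classification Output of [classify_calls()] (or any tibble with
#'   `tp`, `fp`, `fn` counts and unit identifiers).
#' @return The input with `n_calls` (= tp + fp), `precision`, `recall`, `f1`
#'   columns appended; key list-columns are dropped.
#' @export
score_metrics <- function(classification) {
  out <- classification %>%
    select(-dplyr::any_of(c("tp_keys", "fp_keys", "fn_keys"))) %>%
    mutate(n_calls = .data$tp + .data$fp)
  dplyr::bind_cols(out, prf(out$tp, out$fp, out$fn))
}

aggregate_by_token <- function(records, token, expected_per_group) {
  ids <- split_pipeline_id(records$pipeline_id)
  records <- records %>% mutate(.group = ids[[token]])
  grp <- records %>%
    group_by(.data$.group, .data$sample_id) %>%
    summarise(
      n_pipelines = dplyr::n_distinct(.data$pipeline_id),
      across(dplyr::any_of(c("n_calls", "tp", "fp", "fn")),
             ~ mean(.x, na.rm = TRUE)),
      across(dplyr::any_of(c("precision", "recall", "f1")),
             ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    rename(!!token := ".group")
  short <- grp %>% filter(.data$n_pipelines < expected_per_group)
  if (nrow(short) > 0) {
    warn(paste0(nrow(short), " (", token, ", sample) group(s) are missing ",
                "pipelines; means taken over those present"))
  }
  grp
}

#' Aggregate per-pipeline records by mapping algorithm
#'
#' For each (mapper, sample), the mean over the callers sharing that mapper
#' — call counts and every metric — mirroring the per-mapper averages used
#' to compare aligners. Missing pipelines are flagged with a warning and the
#' mean is taken over those present; undefined metrics are excluded from the
#' mean rather than counted as 0.
#'
#' @param records Output of [score_metrics()] (one row per pipeline x
#'   sample, with a `pipeline_id` column).
#' @return A tibble with one row per (mapper, sample).
#' @export
aggregate_by_mapper <- function(records) {
  aggregate_by_token(records, "mapper", length(default_callers()))
}

#' Aggregate per-pipeline records by variant caller
#'
#' Symmetric to [aggregate_by_mapper()]: for each (caller, sample), the mean
#' over the mappers sharing that caller.
#'
#' @inheritParams aggregate_by_mapper
#' @return A tibble with one row per (caller, sample).
#' @export
aggregate_by_caller <- function(records) {
  aggregate_by_token(records, "caller", length(default_mappers()))
}

#' Samples-by-pipelines matrix of call counts
#'
#' @param calls A filtered call tibble.
#' @param units Optional tibble of expected (pipeline_id, sample_id) pairs;
#'   pairs listed there but absent from `calls` are reported as 0 (an empty
#'   call set), pairs not listed are `NA` (never run). Defaults to the pairs
#'   present in `calls`.
#' @return A tibble, one row per sample, one column per pipeline, suitable
#'   for heatmap rendering via [plot_count_heatmap()].
#' @export
count_matrix <- function(calls, units = NULL) {
  counts <- calls %>% count(.data$sample_id, .data$pipeline_id, name = "n_calls")
  if (!is.null(units)) {
    counts <- units %>%
      distinct(.data$sample_id, .data$pipeline_id) %>%
      left_join(counts, by = c("sample_id", "pipeline_id")) %>%
      mutate(n_calls = dplyr::coalesce(.data$n_calls, 0L))
  }
  counts %>%
    tidyr::pivot_wider(names_from = "pipeline_id", values_from = "n_calls") %>%
    arrange(.data$sample_id)
}
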