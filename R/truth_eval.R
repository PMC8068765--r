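#' Score call sets against a known per-sample truth
#'
#' Exact set algebra against simulation truth: per (pipeline, sample),
#' TP = calls intersect truth, FP = calls minus truth, FN = truth minus
#' calls. The truth for a sample is the set of variants carried by that
#' sample's active clones — a pipeline cannot find a variant absent from
#' the sample's cells, matching the per-sample FN scoping used on real
#' data.
#'
#' @param calls A filtered call tibble.
#' @param sample_truth Tibble (sample_id, key) of per-sample truth
#'   variants, e.g. `study$sample_truth` from [generate_study()], or a
#'   truth VCF parsed per sample.
#' @param units Optional tibble (pipeline_id, sample_id, sample_type) so
#'   zero-call units are scored; defaults to units present in `calls`.
#' @return A tibble, one row per unit: `tp`, `fp`, `fn`, `n_calls`,
#'   `precision`, `recall`, `f1` (recall is `NA` when the sample's truth is
#'   empty).
#' @export
score_vs_truth <- function(calls, sample_truth, units = NULL) {
  if (is.null(units)) {
    units <- calls %>%
      distinct(.data$pipeline_id, .data$sample_id, .data$sample_type)
  }
  truth_split <- split(sample_truth$key, sample_truth$sample_id)
  calls_split <- split(calls$key,
                       paste(calls$pipeline_id, calls$sample_id, sep = "\r"))
  res <- purrr::pmap_dfr(
    list(units$pipeline_id, units$sample_id),
    function(pid, sid) {
      ck <- unique(calls_split[[paste(pid, sid, sep = "\r")]] %||% character())
      tk <- truth_split[[sid]] %||% character()
      tp <- sum(ck %in% tk)
      tibble(tp = tp, fp = length(ck) - tp, fn = length(tk) - tp)
    }
  )
  out <- dplyr::bind_cols(units, res) %>% mutate(n_calls = .data$tp + .data$fp)
  dplyr::bind_cols(out, prf(out$tp, out$fp, out$fn))
}

#' Compare validation-based with truth-based metrics
#'
#' Joins the two metric tables per (pipeline-or-combination, sample) and
#' reports the deltas `validation - truth` for precision and recall. On a
#' clean simulation (no recurrent artifacts) validation-based precision
#' tracks truth-based precision; recurrent shared artifacts inflate
#' validation-based precision above truth — the failure mode of the
#' cross-sample validation statistic that this comparison is designed to
#' expose.
#'
#' @param validation_metrics Per-unit metrics scored against the validated
#'   set ([score_metrics()] output).
#' @param truth_metrics Per-unit metrics from [score_vs_truth()].
#' @return A tibble with per-unit `delta_precision`, `delta_recall`,
#'   `delta_f1`; attribute `summary` holds the per-pipeline mean deltas.
#' @export
compare_validation_to_truth <- function(validation_metrics, truth_metrics) {
  keys <- c("pipeline_id", "sample_id")
  miss_v <- truth_metrics %>% anti_join(validation_metrics, by = keys)
  miss_t <- validation_metrics %>% anti_join(truth_metrics, by = keys)
  if (nrow(miss_v) > 0 || nrow(miss_t) > 0) {
    bad <- bind_rows(miss_v[keys], miss_t[keys]) %>% distinct()
    abort(paste0("validation and truth metrics do not cover the same units; ",
                 "unmatched: ",
                 paste(utils::head(paste(bad$pipeline_id, bad$sample_id), 5),
                       collapse = "; "),
                 if (nrow(bad) > 5) " ..."))
  }
  joined <- validation_metrics %>%
    select(all_of(keys), dplyr::any_of("sample_type"),
           val_precision = "precision", val_recall = "recall",
           val_f1 = "f1") %>%
    inner_join(
      truth_metrics %>%
        select(all_of(keys), truth_precision = "precision",
               truth_recall = "recall", truth_f1 = "f1"),
      by = keys
    ) %>%
    mutate(
      delta_precision = .data$val_precision - .data$truth_precision,
      delta_recall = .data$val_recall - .data$truth_recall,
      delta_f1 = .data$val_f1 - .data$truth_f1
    )
  summary <- joined %>%
    group_by(.data$pipeline_id) %>%
    summarise(
      mean_val_precision = mean(.data$val_precision, na.rm = TRUE),
      mean_truth_precision = mean(.data$truth_precision, na.rm = TRUE),
      mean_delta_precision = mean(.data$delta_precision, na.rm = TRUE),
      mean_delta_recall = mean(.data$delta_recall, na.rm = TRUE),
      .groups = "drop"
    )
  attr(joined, "summary") <- summary
  joined
}
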