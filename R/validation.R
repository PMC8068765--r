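#' Build the cross-(pipeline, sample) detection index
#'
#' Indexes every variant seen in any call set with its full detection
#' support: which (pipeline, sample) pairs detected it, and the projections
#' onto samples and pipelines. This index is the substrate of the
#' cross-sample validation rule.
#'
#' @param calls A filtered call tibble covering all call sets (one row per
#'   pipeline x sample x variant).
#' @return A tibble of class `snv_index`, one row per distinct variant, with
#'   columns `key`, `chrom`, `pos`, `ref`, `alt`, `n_samples`, `n_pipelines`
#'   and list-columns `samples`, `pipelines`; attribute `detections` holds
#'   the distinct (pipeline_id, sample_id, key) triples.
#' @seealso [validate_variants()], [classify_calls()]
#' @export
build_index <- function(calls) {
  det <- calls %>%
    distinct(.data$pipeline_id, .data$sample_id, .data$key,
             .data$chrom, .data$pos, .data$ref, .data$alt)
  idx <- det %>%
    group_by(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      samples = list(sort(unique(.data$sample_id))),
      pipelines = list(sort(unique(.data$pipeline_id))),
      .groups = "drop"
    ) %>%
    mutate(
      n_samples = lengths(.data$samples),
      n_pipelines = lengths(.data$pipelines)
    ) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  attr(idx, "detections") <- det %>%
    select("pipeline_id", "sample_id", "key")
  class(idx) <- c("snv_index", class(idx))
  idx
}

#' Compute the validated-variant set
#'
#' A variant is validated when it was detected in at least `min_samples`
#' independent samples (the cross-sample concordance rule: an identical
#' false discovery recurring in independent samples is unlikely) and by at
#' least `min_pipelines` pipelines. The default (2 samples, any pipeline)
#' reproduces the two-independent-samples rule; the pipeline-support axis is
#' kept separate so the stricter single-pipeline-FP reading can be expressed
#' without conflating the two.
#'
#' @param index An `snv_index` from [build_index()].
#' @param min_samples Minimum number of distinct samples, >= 1.
#' @param min_pipelines Minimum number of distinct pipelines, >= 1.
#' @return A tibble of validated variants (subset of index rows) with the
#'   rule recorded in attribute `rule`.
#' @export
validate_variants <- function(index, min_samples = 2, min_pipelines = 1) {
  if (min_samples < 1 || min_pipelines < 1) {
    abort("min_samples and min_pipelines must both be >= 1")
  }
  out <- index %>%
    filter(.data$n_samples >= min_samples,
           .data$n_pipelines >= min_pipelines)
  attr(out, "rule") <- list(min_samples = min_samples,
                            min_pipelines = min_pipelines)
  class(out) <- setdiff(class(out), "snv_index")
  out
}

#' Classify each call set's detections as TP/FP/FN
#'
#' For every (pipeline, sample) unit: a true positive is a called variant
#' that is validated; a false positive is a called variant that is not; a
#' false negative is a validated variant the unit failed to call. Under
#' `fn_scope = "per_sample"` (default) a unit is only penalized for
#' validated variants that some pipeline detected in that same sample —
#' samples genuinely differ, so a variant absent from a sample's cells is
#' not a miss there. `fn_scope = "global"` charges every validated variant
#' to every unit, for sensitivity analysis.
#'
#' @param calls The filtered call tibble the index was built from.
#' @param validated Output of [validate_variants()].
#' @param index The `snv_index` the validated set came from.
#' @param fn_scope `"per_sample"` or `"global"`.
#' @param units Optional tibble of (pipeline_id, sample_id, sample_type)
#'   units to classify, so that call sets with zero surviving calls are
#'   still scored; defaults to the units present in `calls`.
#' @return A tibble with one row per unit: counts `tp`, `fp`, `fn` and
#'   list-columns `tp_keys`, `fp_keys`, `fn_keys`.
#' @export
classify_calls <- function(calls, validated, index,
                           fn_scope = c("per_sample", "global"),
                           units = NULL) {
  fn_scope <- match.arg(fn_scope)
  det <- attr(index, "detections")
  if (is.null(det)) abort("index lacks detections; build it with build_index()")
  if (nrow(calls) > 0) {
    extra <- calls %>%
      distinct(.data$pipeline_id, .data$sample_id, .data$key) %>%
      anti_join(det, by = c("pipeline_id", "sample_id", "key"))
    if (nrow(extra) > 0) {
      abort("calls contain detections absent from the index; rebuild the index")
    }
  }
  if (is.null(units)) {
    units <- calls %>%
      distinct(.data$pipeline_id, .data$sample_id, .data$sample_type)
  }
  vkeys <- validated$key
  # validated variants present in each sample (detected there by any pipeline)
  sample_val <- det %>%
    filter(.data$key %in% vkeys) %>%
    distinct(.data$sample_id, .data$key)
  sv_split <- split(sample_val$key, sample_val$sample_id)
  calls_split <- split(calls$key,
                       paste(calls$pipeline_id, calls$sample_id, sep = "\r"))
  res <- purrr::pmap(
    list(units$pipeline_id, units$sample_id),
    function(pid, sid) {
      ck <- unique(calls_split[[paste(pid, sid, sep = "\r")]] %||% character())
      tp <- ck[ck %in% vkeys]
      fp <- setdiff(ck, vkeys)
      fn_base <- if (fn_scope == "per_sample") {
        sv_split[[sid]] %||% character()
      } else {
        vkeys
      }
      keys_tp <- sort(tp); keys_fp <- sort(fp); keys_fn <- sort(setdiff(fn_base, ck))
      tibble(tp = length(keys_tp), fp = length(keys_fp), fn = length(keys_fn),
             tp_keys = list(keys_tp), fp_keys = list(keys_fp),
             fn_keys = list(keys_fn))
    }
  )
  out <- bind_rows(res)
  out <- dplyr::bind_cols(units, out)
  attr(out, "fn_scope") <- fn_scope
  out
}
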