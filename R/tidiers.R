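#' Tidy a simulated study into per-unit call counts
#'
#' @param x An `snv_study`.
#' @param ... Unused.
#' @return A tibble, one row per (pipeline, sample): `n_calls` plus the
#'   number of truth variants carried by the sample.
#' @method tidy snv_study
#' @export
tidy.snv_study <- function(x, ...) {
  n_truth <- x$sample_truth %>% count(.data$sample_id, name = "n_truth")
  x$manifest %>%
    left_join(
      x$calls %>% count(.data$pipeline_id, .data$sample_id, name = "n_calls"),
      by = c("pipeline_id", "sample_id")
    ) %>%
    mutate(n_calls = dplyr::coalesce(.data$n_calls, 0L)) %>%
    left_join(n_truth, by = "sample_id")
}

#' One-row summary of a simulated study
#'
#' @param x An `snv_study`.
#' @param ... Unused.
#' @return A tibble: numbers of pipelines, samples, call sets, truth
#'   variants, clones, plus purity, coverage and seed.
#' @method glance snv_study
#' @export
glance.snv_study <- function(x, ...) {
  tibble(
    n_pipelines = dplyr::n_distinct(x$manifest$pipeline_id),
    n_samples = dplyr::n_distinct(x$manifest$sample_id),
    n_callsets = nrow(x$manifest),
    n_truth_variants = nrow(x$truth),
    n_clones = x$params$K,
    purity = x$params$purity,
    coverage = x$params$coverage,
    seed = x$seed
  )
}

#' Tidy a pipeline clustering into merge steps
#'
#' @param x An `snv_clustering`.
#' @param ... Unused.
#' @return A tibble of agglomeration steps (step, height) plus the leaf
#'   order as attribute `order`.
#' @method tidy snv_clustering
#' @export
tidy.snv_clustering <- function(x, ...) {
  out <- tibble(step = seq_along(x$hclust$height), height = x$hclust$height)
  attr(out, "order") <- x$order
  out
}
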