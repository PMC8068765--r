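#' Canonical combination identifier
#'
#' @param members Character vector of pipeline ids.
#' @return The order-independent id: members sorted, joined by `"+"`.
#' @export
combination_id <- function(members) {
  paste(sort(unique(members)), collapse = "+")
}

#' Enumerate pipeline-union combinations
#'
#' Yields every non-empty subset of the pipeline list up to `max_size`,
#' each exactly once, ordered by size then lexicographic canonical id.
#' For 12 pipelines and `max_size = Inf` that is 4095 combinations.
#'
#' @param pipelines Character vector of pipeline ids.
#' @param max_size Largest subset size, or `Inf` for all sizes.
#' @return A tibble with columns `size`, `combo_id` and list-column
#'   `members`.
#' @export
enumerate_combinations <- function(pipelines, max_size = Inf) {
  if (length(pipelines) < 1) abort("need at least one pipeline")
  if (max_size < 1) abort("max_size must be >= 1")
  pipelines <- sort(unique(pipelines))
  sizes <- seq_len(min(length(pipelines), max_size))
  purrr::map_dfr(sizes, function(k) {
    sets <- combn(pipelines, k, simplify = FALSE)
    tibble(
      size = k,
      combo_id = purrr::map_chr(sets, combination_id),
      members = sets
    ) %>% arrange(.data$combo_id)
  })
}

#' Union call set of several pipelines for one sample
#'
#' The union of the member pipelines' variant keys; per-variant metadata
#' (depth, alt reads, VAF) is taken from the member with the highest depth
#' and is informational only — identity for all scoring is the variant key.
#'
#' @param calls A filtered call tibble.
#' @param members Pipeline ids to union.
#' @param sample_id The sample to union within.
#' @return A call tibble whose `pipeline_id` is the canonical combination
#'   id.
#' @export
union_callset <- function(calls, members, sample_id) {
  members <- unique(members)
  sub <- calls %>%
    filter(.data$sample_id == !!sample_id, .data$pipeline_id %in% members)
  missing <- setdiff(members, unique(calls$pipeline_id[calls$sample_id == sample_id]))
  # a member may legitimately have an empty (all-filtered) call set only if
  # it exists elsewhere in the table; a wholly unknown member is an error
  unknown <- setdiff(missing, unique(calls$pipeline_id))
  if (length(unknown) > 0) {
    abort(paste0("no call set for pipeline(s) ", paste(unknown, collapse = ", "),
                 " in sample ", sample_id))
  }
  sub %>%
    group_by(.data$key) %>%
    arrange(dplyr::desc(.data$depth), .data$pipeline_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    mutate(pipeline_id = combination_id(members)) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
}

# Collapse one sample's detections to bitmask pattern counts.  Each variant's
# detection profile across the n pipelines is a bit pattern; scoring a union
# S then only needs, per pattern, whether pattern AND mask(S) is non-zero.
# This makes all 2^n - 1 unions scorable in vectorized time.
sample_patterns <- function(det_sample, pipelines, vkeys) {
  bit <- setNames(bitwShiftL(1L, seq_along(pipelines) - 1L), pipelines)
  pat <- tapply(bit[det_sample$pipeline_id], det_sample$key, function(b) {
    Reduce(bitwOr, b, 0L)
  })
  keys <- names(pat)
  pat <- as.integer(pat)
  validated <- keys %in% vkeys
  agg <- rowsum(cbind(val = as.integer(validated),
                      nonval = as.integer(!validated)),
                group = pat)
  list(pattern = as.integer(rownames(agg)),
       n_val = agg[, "val"], n_nonval = agg[, "nonval"],
       n_val_total = sum(validated))
}

#' Score every pipeline-union combination for every sample
#'
#' Computes TP/FP/FN and precision/recall/F1 for the union call set of every
#' combination (up to `max_size`) in every sample, against a fixed validated
#' set. The validated set is computed once from the individual pipelines and
#' held fixed: unions never feed back into validation, otherwise combination
#' scores would be self-referential. FN scoping follows
#' [classify_calls()]: `"per_sample"` counts only validated variants
#' detected in that sample, `"global"` all validated variants.
#'
#' Internally each variant's detection profile across pipelines is packed
#' into a bit pattern so all 4095 unions of 12 pipelines score in seconds;
#' the result is identical to scoring [union_callset()] outputs one by one.
#'
#' @param calls A filtered call tibble.
#' @param validated Output of [validate_variants()].
#' @param pipelines Pipelines to combine; defaults to those in `calls`.
#' @param max_size Largest combination size (`Inf` = all).
#' @param fn_scope `"per_sample"` or `"global"`.
#' @param index The `snv_index` (required for `fn_scope = "global"` only to
#'   count validated variants; optional otherwise).
#' @param samples Optional tibble (sample_id, sample_type) restricting and
#'   annotating the samples scored; defaults to those in `calls`.
#' @return A tibble with one row per (sample, combination): `sample_id`,
#'   `sample_type`, `combo_id`, `size`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
score_combinations <- function(calls, validated, pipelines = NULL,
                               max_size = Inf,
                               fn_scope = c("per_sample", "global"),
                               index = NULL, samples = NULL) {
  fn_scope <- match.arg(fn_scope)
  pipelines <- sort(pipelines %||% unique(calls$pipeline_id))
  n <- length(pipelines)
  if (n > 20) abort("more than 20 pipelines; exhaustive enumeration refused")
  if (max_size < 1) abort("max_size must be >= 1")
  combos <- enumerate_combinations(pipelines, max_size)
  bit <- setNames(bitwShiftL(1L, seq_len(n) - 1L), pipelines)
  combos$mask <- purrr::map_int(combos$members, function(m) {
    Reduce(bitwOr, bit[m], 0L)
  })
  vkeys <- validated$key
  n_val_global <- length(vkeys)
  if (is.null(samples)) {
    samples <- calls %>% distinct(.data$sample_id, .data$sample_type)
  }
  det <- calls %>%
    filter(.data$pipeline_id %in% pipelines) %>%
    distinct(.data$sample_id, .data$pipeline_id, .data$key)
  out <- purrr::pmap_dfr(
    list(samples$sample_id, samples$sample_type),
    function(sid, stype) {
      ds <- det %>% filter(.data$sample_id == sid)
      if (nrow(ds) == 0) {
        fn0 <- rep(if (fn_scope == "global") n_val_global else 0L,
                   nrow(combos))
        zero <- rep(0L, nrow(combos))
        return(dplyr::bind_cols(
          tibble(sample_id = sid, sample_type = stype,
                 combo_id = combos$combo_id, size = combos$size,
                 tp = zero, fp = zero, fn = fn0),
          prf(zero, zero, fn0)))
      }
      ps <- sample_patterns(ds, pipelines, vkeys)
      hitmat <- outer(ps$pattern, combos$mask, bitwAnd) != 0
      tp <- as.integer(colSums(ps$n_val * hitmat))
      fp <- as.integer(colSums(ps$n_nonval * hitmat))
      fn_base <- if (fn_scope == "per_sample") ps$n_val_total else n_val_global
      fn <- fn_base - tp
      dplyr::bind_cols(
        tibble(sample_id = sid, sample_type = stype,
               combo_id = combos$combo_id, size = combos$size,
               tp = tp, fp = fp, fn = fn),
        prf(tp, fp, fn)
      )
    }
  )
  attr(out, "fn_scope") <- fn_scope
  attr(out, "pipelines") <- pipelines
  out
}

#' Best-F1 combination per sample
#'
#' Selects, for each sample, the combination with the highest F1; with
#' `by_size = TRUE`, additionally the best combination of each exact size.
#' Ties are broken toward the smaller combination, then lexicographic id —
#' parsimony, since union gains saturate as combinations grow.
#'
#' @param results Output of [score_combinations()].
#' @param by_size Also return the per-size winners.
#' @return A tibble of winning rows; overall winners carry `scope =
#'   "overall"`, per-size winners `scope = "by_size"`. Samples where every
#'   F1 is undefined are skipped with a warning.
#' @export
best_per_sample <- function(results, by_size = FALSE) {
  defined <- results %>% filter(!is.na(.data$f1))
  skipped <- setdiff(unique(results$sample_id), unique(defined$sample_id))
  if (length(skipped) > 0) {
    warn(paste0("no defined F1 for sample(s): ",
                paste(skipped, collapse = ", "), "; skipped"))
  }
  pick <- function(d) {
    d %>%
      arrange(dplyr::desc(.data$f1), .data$size, .data$combo_id) %>%
      dplyr::slice(1)
  }
  overall <- defined %>%
    group_by(.data$sample_id) %>%
    pick() %>%
    ungroup() %>%
    mutate(scope = "overall")
  if (!by_size) return(overall)
  per_size <- defined %>%
    group_by(.data$sample_id, .data$size) %>%
    pick() %>%
    ungroup() %>%
    mutate(scope = "by_size")
  bind_rows(overall, per_size)
}

#' Tally winning combinations across samples
#'
#' Counts, per combination size, how often each combination is a sample's
#' per-size best-F1 choice, broken down by sample type — the machine analog
#' of a "top combinations by occurrences" table.
#'
#' @param winners Output of `best_per_sample(results, by_size = TRUE)`.
#' @param tally_sizes Combination sizes to tabulate.
#' @return A tibble (size, combo_id, one column per sample type, total),
#'   sorted by size then descending total.
#' @export
tally_winners <- function(winners, tally_sizes = c(1, 2, 3)) {
  per_size <- winners %>%
    filter(.data$scope == "by_size", .data$size %in% tally_sizes)
  tal <- per_size %>%
    count(.data$size, .data$combo_id, .data$sample_type) %>%
    tidyr::pivot_wider(names_from = "sample_type", values_from = "n",
                       values_fill = 0L)
  type_cols <- setdiff(names(tal), c("size", "combo_id"))
  tal %>%
    mutate(total = rowSums(across(all_of(type_cols)))) %>%
    arrange(.data$size, dplyr::desc(.data$total), .data$combo_id)
}

#' Best F1 per sample as a function of combination size
#'
#' For each sample and size k, the best F1 achievable with exactly k
#' pipelines — the distribution behind the question of how many pipelines a
#' union needs before gains saturate. No unimodality is asserted: the curve
#' is reported as observed.
#'
#' @param results Output of [score_combinations()].
#' @return A long tibble (sample_id, sample_type, size, best_f1, combo_id).
#' @export
f1_by_size <- function(results) {
  results %>%
    filter(!is.na(.data$f1)) %>%
    group_by(.data$sample_id, .data$sample_type, .data$size) %>%
    arrange(dplyr::desc(.data$f1), .data$combo_id, .by_group = TRUE) %>%
    summarise(best_f1 = first(.data$f1), combo_id = first(.data$combo_id),
              .groups = "drop")
}
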