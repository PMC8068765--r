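#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_study()]: `manifest`,
#' `outdir`, `min_depth`, `pass_only`, `min_samples`, `min_pipelines`,
#' `fn_scope`, `max_size`, `tally_sizes`, `similarity_metrics`, `seed`,
#' `simulate` (logical: generate the study instead of reading a manifest)
#' and `strip_chr_prefix`. Unknown keys are a schema error listing the
#' offenders.
#'
#' @param path Path to a YAML file.
#' @return A named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("manifest", "outdir", "min_depth", "pass_only", "min_samples",
             "min_pipelines", "fn_scope", "max_size", "tally_sizes",
             "similarity_metrics", "seed", "simulate", "strip_chr_prefix")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg
}

output_header <- function(config_hash) {
  c(paste0("# snvconcord ", as.character(utils::packageVersion("snvconcord"))),
    paste0("# config_hash ", config_hash))
}

write_table <- function(x, path, header) {
  con <- file(path, open = "wb")
  writeLines(header, con, sep = "\n")
  close(con)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full concordance analysis end to end
#'
#' Orchestrates parse, filter, cross-sample validation, per-pipeline
#' scoring, mapper/caller aggregation, per-type similarity and clustering,
#' exhaustive union-combination scoring, and — when a truth is available
#' (simulated studies) — truth-based scoring and the validation-vs-truth
#' comparison. All result tables are returned, and written as TSV (with a
#' header line naming the package version and a config hash) when `outdir`
#' is given, together with a status file listing every artifact and its
#' checksum.
#'
#' @param study Either an `snv_study` from [generate_study()] or a manifest
#'   (path or tibble) describing VCFs on disk.
#' @param outdir Optional output directory for TSV artifacts.
#' @param min_depth,pass_only Filter settings ([apply_filters()]).
#' @param min_samples,min_pipelines Validation rule ([validate_variants()]).
#' @param fn_scope FN scoping ([classify_calls()]).
#' @param max_size Largest union size scored ([score_combinations()]).
#' @param tally_sizes Sizes tabulated by [tally_winners()].
#' @param similarity_metrics Similarity metrics computed per sample type.
#' @param scored_only Restrict metrics/combinations to manifest rows with
#'   `scored = TRUE` (validation always uses all samples).
#' @param ... Passed to [read_callsets()] when `study` is a manifest.
#' @return A list of result tables: `calls`, `index` sizes, `validated`,
#'   `classification`, `metrics`, `by_mapper`, `by_caller`, `counts`,
#'   `similarity` (nested per type/metric), `combination_results`,
#'   `winners`, `tally`, `f1_by_size`, and for simulated studies
#'   `truth_metrics` and `validation_vs_truth`.
#' @export
run_study <- function(study, outdir = NULL,
                      min_depth = 10, pass_only = TRUE,
                      min_samples = 2, min_pipelines = 1,
                      fn_scope = c("per_sample", "global"),
                      max_size = Inf, tally_sizes = c(1, 2, 3),
                      similarity_metrics = c("cosine", "jaccard", "pearson"),
                      scored_only = TRUE, ...) {
  fn_scope <- match.arg(fn_scope)
  if (inherits(study, "snv_study")) {
    calls <- apply_filters(study$calls, min_depth = min_depth,
                           pass_only = pass_only)
    manifest <- study$manifest
    sample_truth <- study$sample_truth
    config_seed <- study$seed
  } else {
    manifest <- if (is.character(study)) read_manifest(study) else study
    calls <- read_callsets(manifest, min_depth = min_depth,
                           pass_only = pass_only, ...)
    sample_truth <- NULL
    config_seed <- NA
  }
  units <- manifest %>%
    select("pipeline_id", "sample_id", "sample_type", "scored")
  cfg_hash <- rlang::hash(list(min_depth, pass_only, min_samples,
                               min_pipelines, fn_scope, max_size,
                               tally_sizes, similarity_metrics, config_seed))

  index <- build_index(calls)
  validated <- validate_variants(index, min_samples = min_samples,
                                 min_pipelines = min_pipelines)
  if (nrow(validated) == 0) {
    warn("validated set is empty (min_samples unreachable?); all calls will score as false positives")
  }
  scored_units <- if (scored_only) filter(units, .data$scored) else units
  scored_calls <- calls %>%
    semi_join(scored_units, by = c("pipeline_id", "sample_id"))
  cls <- classify_calls(scored_calls, validated, index, fn_scope = fn_scope,
                        units = select(scored_units, -"scored"))
  metrics <- score_metrics(cls)
  by_mapper <- aggregate_by_mapper(metrics)
  by_caller <- aggregate_by_caller(metrics)
  counts <- count_matrix(calls, units = units)

  sims <- list()
  for (st in intersect(sample_type_levels(), unique(calls$sample_type))) {
    inc <- build_incidence(calls, st)
    sims[[st]] <- purrr::map(
      setNames(similarity_metrics, similarity_metrics),
      function(m) {
        sm <- similarity_matrix(inc, m)
        cl <- tryCatch(cluster_pipelines(sm), error = function(e) NULL)
        list(matrix = sm, clustering = cl)
      }
    )
  }

  combo <- score_combinations(
    scored_calls, validated,
    pipelines = sort(unique(manifest$pipeline_id)),
    max_size = max_size, fn_scope = fn_scope, index = index,
    samples = distinct(scored_units, .data$sample_id, .data$sample_type)
  )
  winners <- best_per_sample(combo, by_size = TRUE)
  tally <- tally_winners(winners, tally_sizes = tally_sizes)
  f1_size <- f1_by_size(combo)

  out <- list(
    calls = calls, index = index, validated = validated,
    classification = cls, metrics = metrics,
    by_mapper = by_mapper, by_caller = by_caller, counts = counts,
    similarity = sims, combination_results = combo,
    winners = winners, tally = tally, f1_by_size = f1_size
  )
  if (!is.null(sample_truth)) {
    tm <- score_vs_truth(scored_calls, sample_truth,
                         units = select(scored_units, -"scored"))
    out$truth_metrics <- tm
    out$validation_vs_truth <- compare_validation_to_truth(metrics, tm)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- output_header(cfg_hash)
    tables <- list(
      metrics = metrics, by_mapper = by_mapper, by_caller = by_caller,
      counts = counts,
      validated = as_tibble(validated) %>%
        select("key", "chrom", "pos", "ref", "alt",
               "n_samples", "n_pipelines"),
      support = as_tibble(index) %>%
        mutate(validated = .data$key %in% validated$key) %>%
        select("key", "n_samples", "n_pipelines", "validated"),
      winners = select(winners, -dplyr::any_of("mask")),
      tally = tally, f1_by_size = f1_size,
      combination_results = combo
    )
    if (!is.null(out$truth_metrics)) {
      tables$truth_metrics <- out$truth_metrics
      tables$validation_vs_truth <- out$validation_vs_truth
    }
    paths <- character()
    for (nm in names(tables)) {
      p <- file.path(outdir, paste0(nm, ".tsv"))
      write_table(tables[[nm]], p, hdr)
      paths <- c(paths, p)
    }
    vv <- file.path(outdir, "validated.vcf")
    write_vcf(as_tibble(validated), vv)
    paths <- c(paths, vv)
    for (st in names(sims)) {
      for (m in names(sims[[st]])) {
        p <- file.path(outdir, paste0("similarity.", st, ".", m, ".tsv"))
        sm <- sims[[st]][[m]]$matrix
        write_table(
          as_tibble(unclass(sm), rownames = "pipeline_id"), p, hdr
        )
        paths <- c(paths, p)
        cl <- sims[[st]][[m]]$clustering
        if (!is.null(cl)) {
          pn <- file.path(outdir, paste0("dendrogram.", st, ".", m, ".nwk"))
          writeLines(cl$newick, pn)
          paths <- c(paths, pn)
        }
      }
    }
    status <- tibble(
      artifact = basename(paths),
      md5 = unname(tools::md5sum(paths))
    )
    readr::write_tsv(status, file.path(outdir, "status.tsv"))
    out$artifacts <- status
  }
  out
}
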