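#' Build the detection-incidence matrix for one sample type
#'
#' Rows are (sample, variant) detection events — every variant any pipeline
#' detected in any sample of the type, resolved per sample so the same
#' variant in two samples contributes two rows. Columns are pipelines;
#' cells are 0/1 detection indicators. Events are pooled within the sample
#' type (one matrix per type); set `per_sample = TRUE` to obtain one matrix
#' per sample instead, for the average-of-per-sample-similarities variant.
#'
#' @param calls A filtered call tibble.
#' @param sample_type The sample type to pool over.
#' @param pipelines Column order; defaults to the sorted pipelines present.
#' @param per_sample If `TRUE`, return a named list of per-sample incidence
#'   matrices instead of one pooled matrix.
#' @return An integer 0/1 matrix of class `snv_incidence` with rownames
#'   `"<sample>|<key>"` and pipeline columns, and attribute `sample_type`
#'   (or a list of such matrices).
#' @export
build_incidence <- function(calls, sample_type, pipelines = NULL,
                            per_sample = FALSE) {
  if (!sample_type %in% sample_type_levels()) {
    abort(paste0("unknown sample_type: ", sample_type))
  }
  sub <- calls %>% filter(.data$sample_type == !!sample_type)
  if (nrow(sub) == 0) abort(paste0("no calls for sample_type ", sample_type))
  pipelines <- pipelines %||% sort(unique(sub$pipeline_id))
  build_one <- function(d) {
    ev <- d %>% distinct(.data$sample_id, .data$key, .data$pipeline_id)
    rows <- sort(unique(paste(ev$sample_id, ev$key, sep = "|")))
    m <- matrix(0L, nrow = length(rows), ncol = length(pipelines),
                dimnames = list(rows, pipelines))
    m[cbind(match(paste(ev$sample_id, ev$key, sep = "|"), rows),
            match(ev$pipeline_id, pipelines))] <- 1L
    class(m) <- c("snv_incidence", class(m))
    attr(m, "sample_type") <- sample_type
    m
  }
  if (per_sample) {
    lapply(split(sub, sub$sample_id), build_one)
  } else {
    build_one(sub)
  }
}

#' Pairwise pipeline similarity on a detection-incidence matrix
#'
#' Cosine: `dot(x, y) / (|x| |y|)`. Jaccard: `|x & y| / (x | y)|`. Pearson:
#' the sample correlation of the 0/1 columns. Identical columns score 1
#' under all three; disjoint ones score 0 under cosine and Jaccard. Pairs
#' whose value is undefined (an all-zero column under cosine/Jaccard, a
#' constant column under Pearson) are reported as `NA`.
#'
#' @param incidence An `snv_incidence` matrix from [build_incidence()].
#' @param metric `"cosine"`, `"jaccard"` or `"pearson"`.
#' @return An object of class `snv_similarity`: the symmetric pipelines x
#'   pipelines matrix with attributes `metric` and `sample_type`.
#' @export
similarity_matrix <- function(incidence,
                              metric = c("cosine", "jaccard", "pearson")) {
  metric <- match.arg(metric)
  m <- unclass(incidence)
  if (ncol(m) < 2) abort("need at least two pipelines")
  storage.mode(m) <- "double"
  values <- switch(metric,
    cosine = {
      cp <- crossprod(m)                     # |x & y| for 0/1 columns
      norms <- sqrt(diag(cp))
      denom <- outer(norms, norms)
      out <- ifelse(denom > 0, cp / denom, NA_real_)
      out
    },
    jaccard = {
      cp <- crossprod(m)
      sizes <- diag(cp)
      un <- outer(sizes, sizes, "+") - cp    # |x | y|
      ifelse(un > 0, cp / un, NA_real_)
    },
    pearson = suppressWarnings(cor(m))
  )
  dimnames(values) <- list(colnames(m), colnames(m))
  structure(values, class = "snv_similarity",
            metric = metric, sample_type = attr(incidence, "sample_type"))
}

#' @export
print.snv_similarity <- function(x, ...) {
  cat("<snv_similarity> metric =", attr(x, "metric"),
      "| sample_type =", attr(x, "sample_type") %||% "?", "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Hierarchically cluster pipelines on a similarity matrix
#'
#' Agglomerative clustering (average linkage / UPGMA) on the distance
#' `1 - similarity`. Ties are resolved by the input column order, so the
#' result is deterministic. Missing similarity cells make the distance
#' undefined and clustering is refused.
#'
#' @param sm An `snv_similarity` matrix.
#' @return An object of class `snv_clustering`: a list with the `hclust`
#'   tree, `order` (leaf labels left to right) and `newick` (the dendrogram
#'   as a Newick string, via \pkg{ape}).
#' @export
cluster_pipelines <- function(sm) {
  v <- unclass(sm)
  if (anyNA(v)) {
    abort("similarity matrix has missing cells (an all-zero or constant pipeline column); clustering refused")
  }
  d <- as.dist(1 - v)
  hc <- hclust(d, method = "average")
  # deterministic tie rule: within the merge topology, leaves are ordered
  # by their input column position (so all-equidistant inputs keep input order)
  dend <- stats::reorder(stats::as.dendrogram(hc), seq_len(ncol(v)),
                         agglo.FUN = mean)
  ord <- labels(dend)
  phy <- ape::as.phylo(hc)
  structure(
    list(hclust = hc, order = ord,
         newick = ape::write.tree(phy)),
    class = "snv_clustering",
    metric = attr(sm, "metric"), sample_type = attr(sm, "sample_type")
  )
}

#' @export
print.snv_clustering <- function(x, ...) {
  cat("<snv_clustering> leaves:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a pipeline clustering into k groups
#'
#' @param cl An `snv_clustering`.
#' @param k Number of groups.
#' @return A tibble (pipeline_id, cluster).
#' @export
cut_clusters <- function(cl, k) {
  grp <- stats::cutree(cl$hclust, k = k)
  tibble(pipeline_id = names(grp), cluster = unname(grp))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity matrix into long pair form
#'
#' @param x An `snv_similarity`.
#' @param ... Unused.
#' @return A tibble (pipeline_a, pipeline_b, similarity, metric,
#'   sample_type) over unordered pairs (upper triangle, no diagonal).
#' @method tidy snv_similarity
#' @export
tidy.snv_similarity <- function(x, ...) {
  v <- unclass(x)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  tibble(
    pipeline_a = rownames(v)[idx[, 1]],
    pipeline_b = colnames(v)[idx[, 2]],
    similarity = v[idx],
    metric = attr(x, "metric"),
    sample_type = attr(x, "sample_type") %||% NA_character_
  )
}

#' One-row summary of a similarity matrix
#'
#' @param x An `snv_similarity`.
#' @param ... Unused.
#' @return A tibble with the metric, sample type, number of pipelines and
#'   mean/min/max off-diagonal similarity.
#' @method glance snv_similarity
#' @export
glance.snv_similarity <- function(x, ...) {
  p <- tidy(x)
  tibble(
    metric = attr(x, "metric"),
    sample_type = attr(x, "sample_type") %||% NA_character_,
    n_pipelines = ncol(unclass(x)),
    mean_similarity = mean(p$similarity, na.rm = TRUE),
    min_similarity = min(p$similarity, na.rm = TRUE),
    max_similarity = max(p$similarity, na.rm = TRUE)
  )
}
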