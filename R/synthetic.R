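#' Tumor purity implied by coverage mixing
#'
#' When a tumor read set is merged with a normal read set, the fraction of
#' reads (equivalently, cells) of tumor origin is
#' `tumor_coverage / (tumor_coverage + normal_coverage)`. Mixing a 20x tumor
#' file into 80x of normal reads gives 20% purity; 80x into 80x gives 50%;
#' an unmixed tumor file is 100% pure. This is the call-level analog of the
#' read-mixing design used to build low/medium/high-purity benchmarks.
#'
#' @param tumor_coverage Tumor read coverage (> 0).
#' @param normal_coverage Normal read coverage mixed in (>= 0).
#' @return The tumor purity as a fraction in (0, 1].
#' @examples
#' purity_from_mixing(20, 80)  # 0.2
#' purity_from_mixing(80, 80)  # 0.5
#' purity_from_mixing(80, 0)   # 1
#' @export
purity_from_mixing <- function(tumor_coverage, normal_coverage) {
  if (any(tumor_coverage <= 0)) abort("tumor_coverage must be > 0")
  if (any(normal_coverage < 0)) abort("normal_coverage must be >= 0")
  tumor_coverage / (tumor_coverage + normal_coverage)
}

#' Toy exome intervals
#'
#' A small synthetic exome: 10 contigs x 10 intervals x 10 kb (1 Mb total),
#' enough positional room for the default truth pool with no reference
#' genome required (reference bases are simulated). The same intervals ship
#' as a BED fixture in `inst/extdata/toy_exome.bed`.
#'
#' @param n_contigs,intervals_per_contig,interval_width Layout parameters.
#' @return A tibble (chrom, start, end), 1-based inclusive coordinates.
#' @export
default_exome <- function(n_contigs = 10, intervals_per_contig = 10,
                          interval_width = 10000) {
  gap <- interval_width  # unsequenced spacer between intervals
  tidyr::expand_grid(
    chrom = sprintf("ctg%02d", seq_len(n_contigs)),
    iv = seq_len(intervals_per_contig)
  ) %>%
    mutate(
      start = (.data$iv - 1L) * (interval_width + gap) + 1L,
      end = .data$start + interval_width - 1L
    ) %>%
    select("chrom", "start", "end")
}

#' Read BED intervals into the 1-based tibble form
#'
#' @param path A 3+ column BED file (0-based half-open, as standard).
#' @return A tibble (chrom, start, end), 1-based inclusive.
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (ncol(b) < 3) abort("BED file needs at least 3 columns")
  tibble(chrom = as.character(b[[1]]),
         start = as.integer(b[[2]]) + 1L,
         end = as.integer(b[[3]]))
}

#' Generate a clone-structured somatic truth pool
#'
#' Places `n_variants` SNVs uniformly at distinct positions within the exome
#' intervals; the reference base is drawn uniformly from A/C/G/T and the
#' alternate uniformly from the remaining three. Each variant is assigned to
#' one of `K` clones by a multinomial draw with Dirichlet-distributed clone
#' weights, giving the clonal structure that sample heterogeneity is built
#' from.
#'
#' @param n_variants Number of truth variants (default 4800, the size of
#'   the simulated somatic pool).
#' @param exome Interval tibble (chrom, start, end); see [default_exome()].
#' @param K Number of clones.
#' @param seed Integer seed (all randomness here flows from it).
#' @param dirichlet_alpha Concentration of the clone-weight prior.
#' @return A tibble of class `snv_truth` (chrom, pos, ref, alt, key, clone)
#'   with attributes `clone_weights`, `K`, `seed`.
#' @export
generate_truth <- function(n_variants = 4800, exome = default_exome(),
                           K = 8, seed = 1, dirichlet_alpha = 2) {
  if (n_variants < 1) abort("n_variants must be >= 1")
  if (nrow(exome) == 0) abort("exome intervals are empty")
  widths <- exome$end - exome$start + 1
  total <- sum(widths)
  if (total < n_variants) {
    abort(paste0("exome has only ", total, " positions for ",
                 n_variants, " distinct variants"))
  }
  bases <- c("A", "C", "G", "T")
  with_substream(seed, "truth", {
    flat <- sample.int(total, n_variants, replace = FALSE)
    iv <- findInterval(flat - 1, cumsum(c(0, widths))[seq_len(nrow(exome))])
    pos <- exome$start[iv] + (flat - 1 - cumsum(c(0, widths))[iv]) - 0
    ref <- sample(bases, n_variants, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
    w <- rgamma(K, shape = dirichlet_alpha)
    w <- w / sum(w)
    clone <- sample.int(K, n_variants, replace = TRUE, prob = w)
    out <- tibble(
      chrom = exome$chrom[iv], pos = as.integer(pos),
      ref = ref, alt = alt,
      key = variant_key(exome$chrom[iv], pos, ref, alt),
      clone = clone
    ) %>% arrange(.data$chrom, .data$pos)
    structure(out, clone_weights = w, K = K, seed = seed,
              class = c("snv_truth", class(out)))
  })
}

#' Study sample design
#'
#' The default multi-sample design: 7 parental (primary tumor regions),
#' 13 in vivo polyclones, 7 in vitro polyclones, 19 monoclones and 4
#' secondary monoclones — 50 samples spanning four heterogeneity levels.
#'
#' @param parental,invivo_polyclone,invitro_polyclone,monoclone,secondary_monoclone
#'   Sample counts per type.
#' @return A tibble (sample_id, sample_type, scored).
#' @export
sample_design <- function(parental = 7, invivo_polyclone = 13,
                          invitro_polyclone = 7, monoclone = 19,
                          secondary_monoclone = 4) {
  counts <- c(parental = parental, invivo_polyclone = invivo_polyclone,
              invitro_polyclone = invitro_polyclone, monoclone = monoclone,
              secondary_monoclone = secondary_monoclone)
  if (any(counts < 0)) abort("sample counts must be >= 0")
  purrr::imap_dfr(counts, function(n, type) {
    if (n == 0) return(tibble())
    tibble(
      sample_id = sprintf("%s_%02d", type, seq_len(n)),
      sample_type = type, scored = TRUE
    )
  })
}

# Per-sample clone cell fractions by heterogeneity level:
#   monoclone / secondary monoclone — a single clone at fraction 1;
#   polyclones — 2..4 active clones, Dirichlet fractions;
#   parental — all K clones (Dirichlet) scaled by (1 - contamination),
#   modeling normal-cell contamination of primary tissue.
clone_fractions_for <- function(sample_type, K, master_seed, sample_id,
                                parental_contamination = 0.3) {
  with_substream(master_seed, paste0("clones/", sample_id), {
    frac <- numeric(K)
    if (K == 1) {
      contam <- if (sample_type == "parental") parental_contamination else 0
      frac[1] <- 1 - contam
    } else if (sample_type %in% c("monoclone", "secondary_monoclone")) {
      frac[sample.int(K, 1)] <- 1
    } else if (sample_type %in% c("invivo_polyclone", "invitro_polyclone")) {
      k <- sample(2:min(4, K), 1)
      act <- sample.int(K, k)
      w <- rgamma(k, 2)
      frac[act] <- w / sum(w)
    } else { # parental
      w <- rgamma(K, 2)
      frac <- (w / sum(w)) * (1 - parental_contamination)
    }
    frac
  })
}

#' Simulate per-site sequencing evidence for one sample
#'
#' For each truth variant carried by the sample's active clones the expected
#' VAF is `purity * clone_fraction * 0.5` (heterozygous diploid); site depth
#' is Poisson with the coverage mean and alt-supporting reads are binomial
#' in the expected VAF. Variants of inactive clones get zero alt reads.
#'
#' @param truth An `snv_truth` pool from [generate_truth()].
#' @param clone_fractions Numeric vector of per-clone cell fractions for
#'   this sample (length K, sums to <= 1).
#' @param purity Tumor purity in (0, 1].
#' @param coverage Mean sequencing depth.
#' @param seed Integer seed for this sample's draws.
#' @return A tibble: truth columns plus `clone_fraction`, `expected_vaf`,
#'   `depth`, `alt_reads`, `vaf_obs`, `active`.
#' @export
simulate_sample <- function(truth, clone_fractions, purity = 1,
                            coverage = 80, seed = 1) {
  if (purity <= 0 || purity > 1) abort("purity must be in (0, 1]")
  if (sum(clone_fractions) > 1 + 1e-9) abort("clone fractions sum to > 1")
  n <- nrow(truth)
  frac <- clone_fractions[truth$clone]
  evaf <- purity * frac * 0.5
  set.seed(seed)
  depth <- rpois(n, coverage)
  alt_reads <- rbinom(n, depth, evaf)
  out <- tibble::as_tibble(truth)
  out$clone_fraction <- frac
  out$expected_vaf <- evaf
  out$depth <- depth
  out$alt_reads <- alt_reads
  out$vaf_obs <- ifelse(depth > 0, alt_reads / depth, 0)
  out$active <- frac > 0
  out
}

#' Default per-pipeline detection behaviors
#'
#' A behavioral stand-in for real mapper/caller stacks (re-running them is
#' out of scope): each pipeline has a logistic sensitivity curve in observed
#' VAF — detection probability `plogis((vaf - v50) / w)` — a minimum
#' alt-read requirement, and a Poisson false-call rate of which a fraction
#' `fp_shared_prob` recurs from a shared artifact pool (alignment artifacts
#' hit the same sites in every sample; such artifacts are what break
#' cross-sample validation).
#'
#' Caller tokens set the base sensitivity/false-call profile; mapper tokens
#' shift it. The `"caller_dominant"` preset (default) makes caller choice
#' the main axis of between-pipeline disagreement; `"mapper_dominant"`
#' makes mapper choice dominate. The defaults encode the qualitative field
#' regime: one permissive high-recall/low-precision mapper stack
#' (Novoalign-like) versus stricter ones, and callers spanning permissive
#' (Strelka2-like) to conservative (SomaticSniper-like).
#'
#' @param preset `"caller_dominant"` or `"mapper_dominant"`.
#' @param mappers,callers Token lists.
#' @param fp_rate Mean false calls per sample per pipeline (before mapper
#'   modifiers).
#' @param fp_shared_prob Probability a false call is drawn from the shared
#'   artifact pool rather than placed at a fresh random position.
#' @return A tibble, one row per pipeline: `pipeline_id`, `mapper`,
#'   `caller`, `v50`, `w`, `fp_rate`, `fp_shared_prob`, `min_alt_reads`.
#' @export
pipeline_behaviors <- function(preset = c("caller_dominant", "mapper_dominant"),
                               mappers = default_mappers(),
                               callers = default_callers(),
                               fp_rate = 40,
                               fp_shared_prob = 0.25) {
  preset <- match.arg(preset)
  # FP load scales with permissiveness: callers (or mappers) that call more
  # also emit proportionally more false calls, reproducing the observed
  # precision/recall trade-off across pipelines (permissive = high recall,
  # low precision; conservative = the reverse).
  if (preset == "caller_dominant") {
    caller_par <- tibble(
      caller = callers,
      v50 = c(0.10, 0.12, 0.20, 0.06)[seq_along(callers)],
      w = c(0.030, 0.035, 0.045, 0.025)[seq_along(callers)],
      fp_mult = c(1.5, 2.0, 0.3, 3.0)[seq_along(callers)]
    )
    mapper_par <- tibble(
      mapper = mappers,
      v50_shift = c(0, 0.01, -0.02)[seq_along(mappers)],
      fp_mult = c(1.0, 0.9, 1.6)[seq_along(mappers)]
    )
  } else {
    caller_par <- tibble(
      caller = callers,
      v50 = 0.10,
      w = 0.030,
      fp_mult = c(1.0, 1.05, 0.95, 1.0)[seq_along(callers)]
    )
    mapper_par <- tibble(
      mapper = mappers,
      v50_shift = c(0, 0.06, -0.06)[seq_along(mappers)],
      fp_mult = c(1.5, 0.5, 3.5)[seq_along(mappers)]
    )
  }
  out <- tidyr::expand_grid(mapper = mappers, caller = callers) %>%
    left_join(caller_par, by = "caller") %>%
    left_join(mapper_par, by = "mapper", suffix = c("_caller", "_mapper")) %>%
    mutate(
      pipeline_id = paste(.data$mapper, .data$caller, sep = "_"),
      v50 = pmax(0.01, .data$v50 + .data$v50_shift),
      fp_rate = fp_rate * .data$fp_mult_caller * .data$fp_mult_mapper,
      fp_shared_prob = fp_shared_prob,
      min_alt_reads = 3L
    ) %>%
    select("pipeline_id", "mapper", "caller", "v50", "w", "fp_rate",
           "fp_shared_prob", "min_alt_reads")
  # detection noise is correlated along the dominant axis: pipelines sharing
  # that token miss the same borderline sites (a property of the shared
  # algorithm given the evidence, not an independent coin flip per pipeline)
  attr(out, "noise_axis") <- if (preset == "caller_dominant") "caller" else "mapper"
  attr(out, "detect_cor") <- 0.8
  out
}

# Shared artifact pool: recurrent non-truth sites every pipeline can emit as
# false calls.  Kept off truth positions so truth/artifact sets are disjoint.
make_artifact_pool <- function(n, exome, truth, seed) {
  widths <- exome$end - exome$start + 1
  total <- sum(widths)
  bases <- c("A", "C", "G", "T")
  with_substream(seed, "artifact_pool", {
    repeat {
      flat <- sample.int(total, n, replace = FALSE)
      iv <- findInterval(flat - 1, cumsum(c(0, widths))[seq_len(nrow(exome))])
      pos <- exome$start[iv] + (flat - 1 - cumsum(c(0, widths))[iv])
      ref <- sample(bases, n, replace = TRUE)
      alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
      pool <- tibble(chrom = exome$chrom[iv], pos = as.integer(pos),
                     ref = ref, alt = alt,
                     key = variant_key(exome$chrom[iv], pos, ref, alt))
      pool <- pool %>% filter(!.data$key %in% truth$key)
      if (nrow(pool) >= ceiling(n * 0.8)) return(pool)
    }
  })
}

#' Draw false-call candidates for one sample
#'
#' Candidates are drawn at `candidate_rate` (Poisson count); each is a
#' shared-artifact-pool site with probability `shared_prob`, else a fresh
#' random non-truth site, with simulated depth (>= 10), artifact VAF
#' (uniform on 0.05–0.25) and alt reads. The `accept_u` column carries a
#' uniform mark per candidate so pipelines with lower false-call rates can
#' keep a thinned, nested subset. Uses the current RNG state.
#'
#' @param candidate_rate Poisson mean of the candidate count.
#' @param shared_prob Probability a candidate comes from the artifact pool.
#' @param artifact_pool Tibble of recurrent artifact sites.
#' @param sites The sample's simulated truth sites (used to avoid truth
#'   collisions).
#' @param coverage Mean depth.
#' @return A tibble of candidates with attribute `candidate_rate`.
#' @export
make_fp_candidates <- function(candidate_rate, shared_prob, artifact_pool,
                               sites, coverage = 80) {
  n_fp <- rpois(1, candidate_rate)
  out <- tibble(chrom = character(), pos = integer(), ref = character(),
                alt = character(), key = character(), depth = integer(),
                alt_reads = integer(), vaf = double(), accept_u = double())
  if (n_fp > 0) {
    shared <- runif(n_fp) < shared_prob
    n_sh <- sum(shared)
    picks <- list()
    if (n_sh > 0) {
      picks$sh <- artifact_pool[sample.int(nrow(artifact_pool),
                                           min(n_sh, nrow(artifact_pool))), ]
    }
    n_fresh <- n_fp - n_sh
    if (n_fresh > 0) {
      # fresh random artifacts; collisions with truth keys are discarded
      bases <- c("A", "C", "G", "T")
      chrom <- sample(unique(artifact_pool$chrom), n_fresh, replace = TRUE)
      pos <- sample.int(200000L, n_fresh, replace = TRUE)
      ref <- sample(bases, n_fresh, replace = TRUE)
      alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
      picks$fr <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         key = variant_key(chrom, pos, ref, alt)) %>%
        filter(!.data$key %in% sites$key)
    }
    fp <- bind_rows(picks) %>% distinct(.data$key, .keep_all = TRUE)
    if (nrow(fp) > 0) {
      fp$depth <- as.integer(pmax(10L, rpois(nrow(fp), coverage)))
      fp$vaf <- runif(nrow(fp), 0.05, 0.25)
      fp$alt_reads <- as.integer(pmin(fp$depth, rbinom(nrow(fp), fp$depth, fp$vaf)))
      fp$accept_u <- runif(nrow(fp))
      out <- fp
    }
  }
  attr(out, "candidate_rate") <- candidate_rate
  out
}

#' Apply one pipeline's detection behavior to simulated site data
#'
#' A truth variant is called iff its alt reads reach `min_alt_reads` and a
#' Bernoulli draw with probability `plogis((vaf_obs - v50) / w)` succeeds.
#' False calls are added as a Poisson count with mean `fp_rate`; each comes
#' from the shared artifact pool with probability `fp_shared_prob`, else
#' from a fresh random non-truth site. Called records with depth below 10
#' are dropped so the emitted call set is filtered-ready.
#'
#' @param sites Output of [simulate_sample()].
#' @param behavior One row of [pipeline_behaviors()].
#' @param artifact_pool Tibble of shared artifact variants (chrom, pos,
#'   ref, alt, key).
#' @param sample_id,sample_type Labels for the emitted call set.
#' @param coverage Mean depth used for false-call site depths.
#' @param seed Integer seed for this (pipeline, sample) unit's draws.
#' @param shared_z Optional standard-normal vector (one value per site)
#'   shared between pipelines along the dominant behaviour axis; combined
#'   with the pipeline's own noise by a Gaussian copula so the marginal
#'   detection probability is unchanged while same-axis pipelines miss the
#'   same sites.
#' @param detect_cor Correlation weight of `shared_z` in the copula, in
#'   `[0, 1]`; 0 (default) means fully independent detection noise.
#' @param fp_candidates Optional pre-drawn false-call candidate table (from
#'   [make_fp_candidates()]) shared between pipelines along the dominant
#'   axis; each pipeline keeps the Poisson-thinned subset with
#'   `accept_u < fp_rate / candidate_rate`, so marginal false-call rates
#'   are preserved while same-axis pipelines share nested false-call sets.
#'   Default `NULL` draws this pipeline's own candidates at its own rate.
#' @return A call tibble in the same shape as [parse_vcf()] output.
#' @export
apply_pipeline <- function(sites, behavior, artifact_pool,
                           sample_id, sample_type, coverage = 80, seed = 1,
                           shared_z = NULL, detect_cor = 0,
                           fp_candidates = NULL) {
  set.seed(seed)
  p_det <- plogis((sites$vaf_obs - behavior$v50) / behavior$w)
  z_own <- stats::rnorm(nrow(sites))
  z <- if (!is.null(shared_z) && detect_cor > 0) {
    sqrt(detect_cor) * shared_z + sqrt(1 - detect_cor) * z_own
  } else {
    z_own
  }
  called <- sites$alt_reads >= behavior$min_alt_reads &
    stats::pnorm(z) < p_det
  tp <- sites[called & sites$depth >= 10, , drop = FALSE]
  if (is.null(fp_candidates)) {
    fp_candidates <- make_fp_candidates(behavior$fp_rate,
                                        behavior$fp_shared_prob,
                                        artifact_pool, sites, coverage)
  }
  cand_rate <- attr(fp_candidates, "candidate_rate")
  fp <- fp_candidates %>%
    filter(.data$accept_u < behavior$fp_rate / cand_rate,
           !.data$key %in% tp$key)
  out <- bind_rows(
    tp %>%
      select("chrom", "pos", "ref", "alt", "key", "depth", "alt_reads") %>%
      mutate(vaf = ifelse(.data$depth > 0, .data$alt_reads / .data$depth, NA_real_)),
    if (nrow(fp) > 0) {
      fp %>% select("chrom", "pos", "ref", "alt", "key", "depth",
                    "alt_reads", "vaf")
    }
  )
  out %>%
    mutate(pipeline_id = behavior$pipeline_id, sample_id = sample_id,
           sample_type = sample_type, filter = "PASS",
           depth = as.integer(.data$depth),
           alt_reads = as.integer(.data$alt_reads)) %>%
    select("pipeline_id", "sample_id", "sample_type", "chrom", "pos",
           "ref", "alt", "key", "depth", "alt_reads", "vaf", "filter") %>%
    arrange(.data$chrom, .data$pos, .data$alt)
}

#' Generate a full truth-known multi-pipeline study
#'
#' Simulates the complete study: a clone-structured truth pool, the
#' multi-sample heterogeneity design, per-sample sequencing evidence at the
#' given purity and coverage, and one call set per (pipeline, sample) under
#' the per-pipeline behavioral model — 12 pipelines x 50 samples = 600 call
#' sets under the defaults. All randomness flows from `seed` through named
#' substreams (truth, per-sample, per-unit), so adding a pipeline does not
#' perturb other outputs and identical seeds give identical studies.
#'
#' @param design Sample design tibble from [sample_design()].
#' @param behaviors Pipeline behavior tibble from [pipeline_behaviors()].
#' @param n_variants Truth pool size.
#' @param K Number of clones.
#' @param purity Tumor purity applied to every sample.
#' @param coverage Mean depth.
#' @param exome Interval tibble.
#' @param artifact_pool_size Size of the shared artifact pool.
#' @param parental_contamination Normal-cell fraction in parental samples.
#' @param seed Master seed.
#' @return An object of class `snv_study`: a list with `calls` (long call
#'   tibble over all units), `truth` (the `snv_truth` pool), `sample_truth`
#'   (tibble sample_id x key of variants carried by each sample's active
#'   clones), `manifest`, `clone_fractions` (samples x clones matrix),
#'   `params` and `seed`.
#' @export
generate_study <- function(design = sample_design(),
                           behaviors = pipeline_behaviors(),
                           n_variants = 4800, K = 8,
                           purity = 1, coverage = 80,
                           exome = default_exome(),
                           artifact_pool_size = 400,
                           parental_contamination = 0.3,
                           seed = 1) {
  truth <- generate_truth(n_variants, exome, K = K, seed = seed)
  pool <- make_artifact_pool(artifact_pool_size, exome, truth, seed)
  frac_m <- matrix(0, nrow(design), K,
                   dimnames = list(design$sample_id, NULL))
  calls <- vector("list", nrow(design) * nrow(behaviors))
  truth_rows <- vector("list", nrow(design))
  idx <- 0L
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    stype <- design$sample_type[i]
    frac <- clone_fractions_for(stype, K, seed, sid, parental_contamination)
    frac_m[i, ] <- frac
    sites <- simulate_sample(
      truth, frac, purity = purity, coverage = coverage,
      seed = substream_seed(seed, paste0("sample/", sid))
    )
    truth_rows[[i]] <- tibble(sample_id = sid,
                              key = sites$key[sites$active])
    noise_axis <- attr(behaviors, "noise_axis") %||% "caller"
    detect_cor <- attr(behaviors, "detect_cor") %||% 0
    tokens <- unique(behaviors[[noise_axis]])
    shared_z <- lapply(setNames(tokens, tokens), function(tok) {
      with_substream(seed, paste0("noise/", sid, "/", tok),
                     stats::rnorm(nrow(truth)))
    })
    fp_cands <- lapply(setNames(tokens, tokens), function(tok) {
      grp <- behaviors[behaviors[[noise_axis]] == tok, ]
      with_substream(seed, paste0("fp/", sid, "/", tok),
                     make_fp_candidates(max(grp$fp_rate),
                                        grp$fp_shared_prob[1],
                                        pool, sites, coverage))
    })
    for (j in seq_len(nrow(behaviors))) {
      idx <- idx + 1L
      calls[[idx]] <- apply_pipeline(
        sites, behaviors[j, ], pool, sid, stype, coverage = coverage,
        seed = substream_seed(seed, paste0("unit/", sid, "/",
                                           behaviors$pipeline_id[j])),
        shared_z = shared_z[[behaviors[[noise_axis]][j]]],
        detect_cor = detect_cor,
        fp_candidates = fp_cands[[behaviors[[noise_axis]][j]]]
      )
    }
  }
  manifest <- tidyr::expand_grid(
    pipeline_id = behaviors$pipeline_id,
    design
  ) %>% select("pipeline_id", "sample_id", "sample_type", "scored")
  structure(
    list(
      calls = bind_rows(calls),
      truth = truth,
      sample_truth = bind_rows(truth_rows),
      manifest = manifest,
      clone_fractions = frac_m,
      params = list(n_variants = n_variants, K = K, purity = purity,
                    coverage = coverage, exome = exome,
                    artifact_pool_size = artifact_pool_size,
                    parental_contamination = parental_contamination,
                    behaviors = behaviors, design = design),
      seed = seed
    ),
    class = "snv_study"
  )
}

#' @export
print.snv_study <- function(x, ...) {
  cat("<snv_study> ", nrow(x$manifest), " call sets (",
      dplyr::n_distinct(x$manifest$pipeline_id), " pipelines x ",
      dplyr::n_distinct(x$manifest$sample_id), " samples), ",
      nrow(x$truth), " truth variants, purity ", x$params$purity,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Materialise a simulated study on disk
#'
#' Writes one VCF per (pipeline, sample), one truth VCF per sample, the
#' manifest TSV, the exome BED and a provenance JSON carrying the seed and
#' all generator parameters.
#'
#' @param study An `snv_study` from [generate_study()].
#' @param outdir Output directory (created if needed).
#' @return The manifest tibble with a `vcf_path` column, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  # manifest stores paths relative to outdir so a written study is portable
  # (and byte-identical across output locations)
  units <- study$manifest %>%
    mutate(vcf_path = file.path("vcf", paste0(.data$pipeline_id, ".",
                                              .data$sample_id, ".vcf")))
  calls_split <- split(
    study$calls,
    paste(study$calls$pipeline_id, study$calls$sample_id, sep = "\r")
  )
  empty_calls <- study$calls[0, ]
  purrr::pwalk(list(units$pipeline_id, units$sample_id, units$vcf_path),
               function(pid, sid, path) {
                 cs <- calls_split[[paste(pid, sid, sep = "\r")]] %||% empty_calls
                 write_vcf(cs, file.path(outdir, path))
               })
  truth_tbl <- tibble::as_tibble(study$truth)
  for (sid in unique(units$sample_id)) {
    keys <- study$sample_truth$key[study$sample_truth$sample_id == sid]
    write_vcf(truth_tbl %>% filter(.data$key %in% keys),
              file.path(outdir, "truth", paste0(sid, ".truth.vcf")))
  }
  readr::write_tsv(units, file.path(outdir, "manifest.tsv"))
  ex <- study$params$exome %||% default_exome()
  readr::write_tsv(
    ex %>% mutate(start = .data$start - 1L) %>% select("chrom", "start", "end"),
    file.path(outdir, "exome.bed"), col_names = FALSE
  )
  prov <- c(list(seed = study$seed),
            study$params[setdiff(names(study$params), c("behaviors", "design"))],
            list(behaviors = study$params$behaviors,
                 design = study$params$design))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(units %>% mutate(vcf_path = file.path(outdir, .data$vcf_path)))
}
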