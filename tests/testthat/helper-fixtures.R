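# Fixtures are built in code; no binary data anywhere.

# A call-table row builder: keys like "c1:10:A>T" are derived from the
# chrom/pos so hand-written fixtures stay readable.
toy_call <- function(pipeline_id, sample_id, sample_type, chrom, pos,
                     ref = "A", alt = "T", depth = 50L, alt_reads = 20L,
                     filter = "PASS") {
  tibble::tibble(
    pipeline_id = pipeline_id, sample_id = sample_id,
    sample_type = sample_type, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, key = variant_key(chrom, pos, ref, alt),
    depth = as.integer(depth), alt_reads = as.integer(alt_reads),
    vaf = ifelse(depth > 0, alt_reads / depth, NA_real_),
    filter = filter
  )
}

# Deterministic hand fixture used across modules:
#   variants a..e on contig c1, positions 1..5 (all A>T)
#   pipelines P1 = "Bwa_Mutect2", P2 = "Novoalign_Strelka2"
#   samples  S1, S2 (monoclone), S3 (parental)
# detection table (pipeline x sample -> variants):
#   P1/S1: a b c     P2/S1: a d
#   P1/S2: a b       P2/S2: b d
#   P1/S3: e         P2/S3: (none -> unit exists but empty)
# support: a {S1,S2}, b {S1,S2}, c {S1}, d {S1,S2}, e {S3}
# validated (>=2 samples): a, b, d
toy_fixture <- function() {
  pos_of <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  det <- list(
    list("Bwa_Mutect2", "S1", "monoclone", c("a", "b", "c")),
    list("Bwa_Mutect2", "S2", "monoclone", c("a", "b")),
    list("Bwa_Mutect2", "S3", "parental", "e"),
    list("Novoalign_Strelka2", "S1", "monoclone", c("a", "d")),
    list("Novoalign_Strelka2", "S2", "monoclone", c("b", "d"))
  )
  calls <- dplyr::bind_rows(lapply(det, function(d) {
    toy_call(d[[1]], d[[2]], d[[3]], "c1", pos_of[d[[4]]])
  }))
  units <- tibble::tibble(
    pipeline_id = rep(c("Bwa_Mutect2", "Novoalign_Strelka2"), each = 3),
    sample_id = rep(c("S1", "S2", "S3"), 2),
    sample_type = rep(c("monoclone", "monoclone", "parental"), 2)
  )
  list(calls = calls, units = units,
       key_of = stats::setNames(variant_key("c1", pos_of, "A", "T"),
                                names(pos_of)))
}

# Random small fixtures for property tests: n_pipe pipelines x n_samp
# samples over a small variant universe, each variant detected by a random
# subset of units.
random_fixture <- function(seed, n_pipe = 3, n_samp = 3, n_var = 6,
                           p_detect = 0.4) {
  set.seed(seed)
  pipes <- paste0(rep(c("Bwa", "Bowtie2", "Novoalign"), 4),
                  "_",
                  rep(c("Mutect2", "Varscan", "SomaticSniper", "Strelka2"),
                      each = 3))[seq_len(n_pipe)]
  samps <- paste0("S", seq_len(n_samp))
  types <- rep(c("monoclone", "parental", "invivo_polyclone"),
               length.out = n_samp)
  grid <- expand.grid(pipeline_id = pipes, sample_id = samps,
                      pos = seq_len(n_var), stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < p_detect, ]
  calls <- dplyr::bind_rows(purrr::pmap(
    grid,
    function(pipeline_id, sample_id, pos) {
      toy_call(pipeline_id, sample_id,
               types[match(sample_id, samps)], "c1", pos)
    }
  ))
  units <- tibble::tibble(
    pipeline_id = rep(pipes, each = n_samp),
    sample_id = rep(samps, n_pipe),
    sample_type = rep(types, n_pipe)
  )
  list(calls = calls, units = units, pipelines = pipes)
}

# --- independent brute-force oracles (plain loops and set ops; no reuse of
# --- package internals beyond variant_key)

# classification by looping over every (variant, pipeline, sample) triple
oracle_classify <- function(calls, validated_keys, units,
                            fn_scope = "per_sample") {
  all_keys <- unique(calls$key)
  out <- list()
  for (i in seq_len(nrow(units))) {
    pid <- units$pipeline_id[i]; sid <- units$sample_id[i]
    ck <- calls$key[calls$pipeline_id == pid & calls$sample_id == sid]
    tp <- 0L; fp <- 0L; fn <- 0L
    for (v in union(all_keys, validated_keys)) {
      called <- v %in% ck
      vald <- v %in% validated_keys
      in_sample <- v %in% calls$key[calls$sample_id == sid]
      if (called && vald) tp <- tp + 1L
      if (called && !vald) fp <- fp + 1L
      if (!called && vald) {
        if (fn_scope == "global" || in_sample) fn <- fn + 1L
      }
    }
    out[[i]] <- tibble::tibble(pipeline_id = pid, sample_id = sid,
                               tp = tp, fp = fp, fn = fn)
  }
  dplyr::bind_rows(out)
}

oracle_validated <- function(calls, min_samples = 2, min_pipelines = 1) {
  keys <- unique(calls$key)
  keep <- vapply(keys, function(v) {
    length(unique(calls$sample_id[calls$key == v])) >= min_samples &&
      length(unique(calls$pipeline_id[calls$key == v])) >= min_pipelines
  }, TRUE)
  keys[keep]
}

oracle_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  c(precision = p, recall = r, f1 = f)
}

# best combination by exhaustive enumeration with plain set algebra
oracle_best_combo <- function(calls, validated_keys, sid, pipelines,
                              fn_scope = "per_sample") {
  n <- length(pipelines)
  best <- NULL
  subsets <- unlist(lapply(seq_len(n), function(k) {
    utils::combn(sort(pipelines), k, simplify = FALSE)
  }), recursive = FALSE)
  sample_keys <- unique(calls$key[calls$sample_id == sid])
  for (s in subsets) {
    ck <- unique(calls$key[calls$sample_id == sid &
                             calls$pipeline_id %in% s])
    tp <- length(intersect(ck, validated_keys))
    fp <- length(setdiff(ck, validated_keys))
    fn_base <- if (fn_scope == "per_sample") {
      intersect(sample_keys, validated_keys)
    } else {
      validated_keys
    }
    fn <- length(setdiff(fn_base, ck))
    m <- oracle_prf(tp, fp, fn)
    cid <- paste(sort(s), collapse = "+")
    row <- list(combo_id = cid, size = length(s), tp = tp, fp = fp, fn = fn,
                f1 = m[["f1"]])
    if (is.na(row$f1)) next
    if (is.null(best) || row$f1 > best$f1 + 1e-12 ||
        (abs(row$f1 - best$f1) <= 1e-12 &&
         (row$size < best$size ||
          (row$size == best$size && row$combo_id < best$combo_id)))) {
      best <- row
    }
  }
  best
}

# minimal VCF writer independent of write_vcf(), for parser fixtures
write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", "NORMAL", "TUMOR"), collapse = "\t"))
  )
  writeLines(c(header, lines), path)
  path
}

small_study <- function(seed = 1, ...) {
  generate_study(design = sample_design(2, 2, 2, 3, 1), n_variants = 800,
                 K = 4, seed = seed, ...)
}
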