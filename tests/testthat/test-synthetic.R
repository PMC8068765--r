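test_that("coverage mixing gives the designed purities", {
  expect_equal(purity_from_mixing(20, 80), 0.2)
  expect_equal(purity_from_mixing(80, 80), 0.5)
  expect_equal(purity_from_mixing(80, 0), 1)
  expect_error(purity_from_mixing(0, 80), "> 0")
  expect_error(purity_from_mixing(10, -1), ">= 0")
})

test_that("generate_truth places distinct in-interval SNVs with clone structure", {
  ex <- default_exome(n_contigs = 2, intervals_per_contig = 3,
                      interval_width = 500)
  tr <- generate_truth(n_variants = 300, exome = ex, K = 3, seed = 4)
  expect_equal(nrow(tr), 300)
  expect_equal(anyDuplicated(tr$key), 0L)
  expect_true(all(tr$ref %in% c("A", "C", "G", "T")))
  expect_true(all(tr$alt %in% c("A", "C", "G", "T")))
  expect_true(all(tr$ref != tr$alt))
  expect_true(all(tr$clone %in% 1:3))
  # every position inside some interval of its contig
  for (i in seq_len(nrow(tr))) {
    iv <- ex[ex$chrom == tr$chrom[i], ]
    expect_true(any(tr$pos[i] >= iv$start & tr$pos[i] <= iv$end))
  }

  expect_equal(unique(generate_truth(50, ex, K = 1, seed = 1)$clone), 1L)
  tr2 <- generate_truth(n_variants = 300, exome = ex, K = 3, seed = 4)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  expect_error(generate_truth(10000, ex), "positions")
})

test_that("simulate_sample produces the heterozygous-diploid VAF scaling", {
  ex <- default_exome()
  tr <- generate_truth(n_variants = 10000, exome = ex, K = 1, seed = 2)
  # clonal variant at purity 1: mean observed VAF 0.5
  s1 <- simulate_sample(tr, clone_fractions = 1, purity = 1,
                        coverage = 80, seed = 7)
  expect_equal(mean(s1$expected_vaf), 0.5)
  # purity 0.2, clonal: mean VAF 0.1, Monte-Carlo check within 3 binomial SEs
  s02 <- simulate_sample(tr, clone_fractions = 1, purity = 0.2,
                         coverage = 80, seed = 7)
  mc <- mean(s02$vaf_obs[s02$depth > 0])
  se <- sqrt(0.1 * 0.9 / 80) / sqrt(sum(s02$depth > 0))
  expect_lt(abs(mc - 0.1), 3 * se)
  # inactive clones contribute zero alt reads
  tr3 <- generate_truth(n_variants = 500, exome = ex, K = 2, seed = 2)
  s3 <- simulate_sample(tr3, clone_fractions = c(1, 0), purity = 1,
                        coverage = 80, seed = 3)
  expect_true(all(s3$alt_reads[s3$clone == 2] == 0))
  expect_true(all(s3$active == (s3$clone == 1)))
  expect_error(simulate_sample(tr3, c(0.9, 0.9), seed = 1), "sum")
})

test_that("apply_pipeline recovers its detection model in limit cases", {
  ex <- default_exome()
  tr <- generate_truth(n_variants = 2000, exome = ex, K = 1, seed = 5)
  sites <- simulate_sample(tr, 1, purity = 1, coverage = 80, seed = 5)
  pool <- tibble::tibble(chrom = "ctg01", pos = 1L, ref = "A", alt = "C",
                         key = "ctg01:1:A>C")

  # near-step sensitivity far below every VAF, no alt-read floor: recall 1
  b_step <- tibble::tibble(pipeline_id = "Bwa_Mutect2", v50 = 0.05,
                           w = 1e-6, fp_rate = 0, fp_shared_prob = 0,
                           min_alt_reads = 0L)
  cs <- apply_pipeline(sites, b_step, pool, "S1", "monoclone", seed = 9)
  detectable <- sites$key[sites$depth >= 10 & sites$vaf_obs >= 0.1]
  expect_true(all(detectable %in% cs$key))

  # zero false-call rate: truth-based precision is exactly 1
  tm <- score_vs_truth(cs, tibble::tibble(sample_id = "S1", key = sites$key))
  expect_equal(tm$precision, 1)

  # Poisson false calls at rate 50: precision near its closed-form expectation
  b_fp <- b_step; b_fp$fp_rate <- 50
  css <- lapply(1:20, function(s) {
    apply_pipeline(sites, b_fp, pool, "S1", "monoclone", seed = s)
  })
  fp_obs <- vapply(css, function(cs) {
    sum(!cs$key %in% sites$key)
  }, numeric(1))
  expect_lt(abs(mean(fp_obs) - 50), 3 * sqrt(50 / 20))
})

test_that("generate_study emits one call set per (pipeline, sample), deterministically", {
  st <- generate_study(design = sample_design(1, 1, 0, 1, 0),
                       behaviors = pipeline_behaviors()[1:2, ],
                       n_variants = 300, K = 2, seed = 8)
  expect_equal(nrow(st$manifest), 6)  # 2 pipelines x 3 samples
  expect_setequal(unique(st$calls$pipeline_id),
                  st$params$behaviors$pipeline_id)

  st2 <- generate_study(design = sample_design(1, 1, 0, 1, 0),
                        behaviors = pipeline_behaviors()[1:2, ],
                        n_variants = 300, K = 2, seed = 8)
  expect_identical(st$calls, st2$calls)
  expect_identical(st$sample_truth, st2$sample_truth)

  # monoclones carry exactly one clone
  mono <- st$manifest$sample_id[st$manifest$sample_type == "monoclone"][1]
  frac <- st$clone_fractions[mono, ]
  expect_equal(sum(frac > 0), 1)
  expect_equal(sum(frac), 1)

  # emitted call sets are filtered-ready: depth >= 10 everywhere
  expect_true(all(st$calls$depth >= 10))
  expect_true(all(st$calls$alt_reads <= st$calls$depth))
})

test_that("written studies are byte-identical under the same seed and parse back", {
  st <- generate_study(design = sample_design(1, 0, 1, 1, 0),
                       n_variants = 200, K = 2, seed = 13)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(st, d1); write_study(st, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 12 * 3)  # VCFs + truth + manifest + bed + json
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  }
  # truth VCFs parse back to the sample truth sets
  sid <- st$manifest$sample_id[1]
  tv <- parse_vcf(file.path(d1, "truth", paste0(sid, ".truth.vcf")),
                  "Bwa_Mutect2", sid, "parental")
  expect_setequal(tv$key,
                  st$sample_truth$key[st$sample_truth$sample_id == sid])
})

test_that("recurrent shared artifacts inflate validation-based precision", {
  mk <- function(rho, seed) {
    st <- generate_study(design = sample_design(2, 2, 2, 3, 1),
                         behaviors = pipeline_behaviors(fp_shared_prob = rho),
                         n_variants = 1200, K = 4, seed = seed)
    calls <- apply_filters(st$calls)
    idx <- build_index(calls)
    val <- validate_variants(idx)
    units <- dplyr::distinct(st$manifest, pipeline_id, sample_id, sample_type)
    vm <- score_metrics(classify_calls(calls, val, idx, units = units))
    tm <- score_vs_truth(calls, st$sample_truth, units = units)
    s <- attr(compare_validation_to_truth(vm, tm), "summary")
    mean(s$mean_delta_precision)
  }
  expect_lt(abs(mk(0, 21)), 0.02)   # clean run: validation tracks truth
  expect_gt(mk(0.9, 21), 0.01)      # recurrent artifacts: validation inflated
})
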