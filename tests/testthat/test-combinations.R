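test_that("enumeration yields every subset exactly once in canonical order", {
  e3 <- enumerate_combinations(c("B", "A", "C"))
  expect_equal(nrow(e3), 7)
  expect_equal(e3$combo_id[e3$size == 1], c("A", "B", "C"))
  expect_true(all(diff(e3$size) >= 0))
  expect_equal(anyDuplicated(e3$combo_id), 0L)

  p12 <- paste0("P", sprintf("%02d", 1:12))
  expect_equal(nrow(enumerate_combinations(p12)), 4095)
  expect_equal(nrow(enumerate_combinations(p12, max_size = 2)), 78)

  expect_equal(combination_id(c("B", "A")), combination_id(c("A", "B")))
  expect_error(enumerate_combinations(character()), "at least one")
  expect_error(enumerate_combinations(p12, max_size = 0), ">= 1")
})

test_that("union_callset unions keys and keeps highest-depth metadata", {
  calls <- dplyr::bind_rows(
    toy_call("P1_x", "S1", "monoclone", "c1", 1, depth = 30),
    toy_call("P1_x", "S1", "monoclone", "c1", 2, depth = 30),
    toy_call("P2_y", "S1", "monoclone", "c1", 2, depth = 80),
    toy_call("P2_y", "S1", "monoclone", "c1", 3, depth = 40)
  )
  u <- union_callset(calls, c("P2_y", "P1_x"), "S1")
  expect_equal(sort(u$pos), 1:3)
  expect_equal(unique(u$pipeline_id), "P1_x+P2_y")
  expect_equal(u$depth[u$pos == 2], 80L)  # highest-depth member wins

  self <- union_callset(calls, "P1_x", "S1")
  expect_setequal(self$key, calls$key[calls$pipeline_id == "P1_x"])

  expect_error(union_callset(calls, c("P1_x", "P9_z"), "S1"), "P9_z")

  # union of all pipelines equals the sample's index support
  fx <- random_fixture(12, n_pipe = 4, n_samp = 2, n_var = 7)
  idx <- build_index(fx$calls)
  det <- attr(idx, "detections")
  u_all <- union_callset(fx$calls, fx$pipelines, "S1")
  expect_setequal(u_all$key, unique(det$key[det$sample_id == "S1"]))
})

test_that("the bitmask combination scorer equals per-union classification", {
  fx <- random_fixture(31, n_pipe = 4, n_samp = 3, n_var = 8, p_detect = 0.45)
  idx <- build_index(fx$calls)
  val <- validate_variants(idx)
  for (scope in c("per_sample", "global")) {
    res <- score_combinations(fx$calls, val, pipelines = fx$pipelines,
                              fn_scope = scope, index = idx,
                              samples = dplyr::distinct(fx$units, sample_id,
                                                        sample_type))
    expect_equal(nrow(res), (2^4 - 1) * 3)
    combos <- enumerate_combinations(fx$pipelines)
    for (i in sample(nrow(combos), 6)) {
      u <- union_callset(fx$calls, combos$members[[i]], "S2")
      ucls <- classify_calls(
        u, val, build_index(dplyr::bind_rows(fx$calls, u)),
        fn_scope = scope,
        units = tibble::tibble(pipeline_id = combos$combo_id[i],
                               sample_id = "S2", sample_type = "monoclone")
      )
      got <- res[res$combo_id == combos$combo_id[i] & res$sample_id == "S2", ]
      expect_equal(got$tp, ucls$tp)
      expect_equal(got$fp, ucls$fp)
      expect_equal(got$fn, ucls$fn)
    }
  }
})

test_that("best_per_sample picks argmax F1 with parsimony tie-breaking", {
  res <- tibble::tibble(
    sample_id = "S1", sample_type = "monoclone",
    combo_id = c("A", "B", "A+B"), size = c(1, 1, 2),
    tp = c(5, 7, 7), fp = c(5, 3, 3), fn = c(5, 3, 3)
  )
  res <- dplyr::bind_cols(res, prf(res$tp, res$fp, res$fn))
  w <- best_per_sample(res)
  expect_equal(w$combo_id, "B")  # equal F1 to A+B, smaller size wins

  # all-NA F1 sample is skipped with a warning
  res2 <- tibble::tibble(sample_id = "S9", sample_type = "monoclone",
                         combo_id = "A", size = 1, tp = 0, fp = 0, fn = 0,
                         precision = NA_real_, recall = NA_real_,
                         f1 = NA_real_)
  expect_warning(w2 <- best_per_sample(dplyr::bind_rows(res, res2)), "S9")
  expect_false("S9" %in% w2$sample_id)
})

test_that("winners match the brute-force subset argmax on random fixtures", {
  for (seed in c(4, 17, 29)) {
    fx <- random_fixture(seed, n_pipe = 5, n_samp = 3, n_var = 9,
                         p_detect = 0.4)
    idx <- build_index(fx$calls)
    val <- validate_variants(idx)
    res <- score_combinations(fx$calls, val, pipelines = fx$pipelines,
                              samples = dplyr::distinct(fx$units, sample_id,
                                                        sample_type))
    w <- best_per_sample(res)
    for (sid in w$sample_id) {
      want <- oracle_best_combo(fx$calls, val$key, sid, fx$pipelines)
      got <- w[w$sample_id == sid, ]
      expect_equal(got$combo_id, want$combo_id)
      expect_equal(got$f1, want$f1, tolerance = 1e-12)
    }
  }
})

test_that("tally_winners counts per-type occurrences with conservation", {
  w <- tibble::tibble(
    sample_id = paste0("S", 1:5),
    sample_type = c("monoclone", "monoclone", "parental", "parental",
                    "monoclone"),
    combo_id = c("A+B", "A+B", "A+B", "C", "A+B"),
    size = 2, scope = "by_size",
    f1 = 0.5, tp = 1, fp = 1, fn = 1, precision = 0.5, recall = 0.5
  )
  tal <- tally_winners(w, tally_sizes = 2)
  expect_equal(tal$total[tal$combo_id == "A+B"], 4)
  expect_equal(tal$total[tal$combo_id == "C"], 1)
  type_cols <- setdiff(names(tal), c("size", "combo_id", "total"))
  expect_equal(rowSums(tal[, type_cols]), tal$total, ignore_attr = TRUE)
  expect_equal(tal$combo_id[1], "A+B")  # sorted by occurrences
})

test_that("f1_by_size reports the per-size best without asserting unimodality", {
  fx <- random_fixture(8, n_pipe = 3, n_samp = 2, n_var = 6, p_detect = 0.5)
  idx <- build_index(fx$calls)
  val <- validate_variants(idx)
  res <- score_combinations(fx$calls, val, pipelines = fx$pipelines,
                            samples = dplyr::distinct(fx$units, sample_id,
                                                      sample_type))
  fs <- f1_by_size(res)
  chk <- dplyr::summarise(
    dplyr::group_by(res[!is.na(res$f1), ], sample_id, size),
    want = max(f1), .groups = "drop"
  )
  merged <- dplyr::inner_join(fs, chk, by = c("sample_id", "size"))
  expect_equal(merged$best_f1, merged$want)

  one <- score_combinations(fx$calls, val, pipelines = fx$pipelines[1],
                            samples = dplyr::distinct(fx$units, sample_id,
                                                      sample_type))
  expect_equal(unique(f1_by_size(one)$size), 1L)
})

test_that("union monotonicity holds for nested combinations on a simulated study", {
  st <- small_study(seed = 2)
  calls <- apply_filters(st$calls)
  idx <- build_index(calls)
  val <- validate_variants(idx)
  pipes <- sort(unique(calls$pipeline_id))
  res <- score_combinations(calls, val, pipelines = pipes,
                            samples = dplyr::distinct(st$manifest, sample_id,
                                                      sample_type))
  # order combos by bitmask and compare every (S, S + one pipeline) pair
  combos <- enumerate_combinations(pipes)
  bit <- stats::setNames(bitwShiftL(1L, seq_along(pipes) - 1L), pipes)
  mask_of <- vapply(combos$members, function(m) Reduce(bitwOr, bit[m], 0L),
                    integer(1))
  names(mask_of) <- combos$combo_id
  for (sid in unique(res$sample_id)) {
    r <- res[res$sample_id == sid, ]
    v <- stats::setNames(seq_len(nrow(r)), r$combo_id)
    masks <- mask_of[r$combo_id]
    for (b in bit) {
      child <- which(bitwAnd(masks, b) == 0L)
      if (length(child) == 0) next
      parent_mask <- bitwOr(masks[child], b)
      pidx <- v[names(mask_of)[match(parent_mask, mask_of)]]
      cidx <- v[r$combo_id[child]]
      expect_true(all(r$tp[pidx] >= r$tp[cidx]))
      expect_true(all(r$fp[pidx] >= r$fp[cidx]))
      ok <- !is.na(r$recall[pidx]) & !is.na(r$recall[cidx])
      expect_true(all(r$recall[pidx][ok] >= r$recall[cidx][ok] - 1e-12))
    }
  }
})
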