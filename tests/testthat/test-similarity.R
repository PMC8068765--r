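test_that("build_incidence resolves detection events per (sample, variant)", {
  calls <- dplyr::bind_rows(
    toy_call("P1_x", "S1", "monoclone", "c1", 1),   # a
    toy_call("P1_x", "S1", "monoclone", "c1", 2),   # b
    toy_call("P2_y", "S1", "monoclone", "c1", 2)    # b
  )
  inc <- build_incidence(calls, "monoclone")
  expect_equal(dim(inc), c(2L, 2L))
  m <- unclass(inc)
  expect_equal(m[paste0("S1|", variant_key("c1", 1, "A", "T")), ],
               c(P1_x = 1L, P2_y = 0L))
  expect_equal(m[paste0("S1|", variant_key("c1", 2, "A", "T")), ],
               c(P1_x = 1L, P2_y = 1L))

  # the same variant in two samples gives two distinct rows
  two <- dplyr::bind_rows(
    toy_call("P1_x", "S1", "monoclone", "c1", 1),
    toy_call("P1_x", "S2", "monoclone", "c1", 1)
  )
  expect_equal(nrow(build_incidence(two, "monoclone")), 2)

  # row count = sum over samples of the union of calls
  fx <- random_fixture(3, n_pipe = 3, n_samp = 3, n_var = 6)
  mono <- fx$calls[fx$calls$sample_type == "monoclone", ]
  inc2 <- build_incidence(fx$calls, "monoclone")
  want <- sum(vapply(split(mono, mono$sample_id),
                     function(d) length(unique(d$key)), integer(1)))
  expect_equal(nrow(inc2), want)
  expect_true(all(rowSums(unclass(inc2)) >= 1))
  expect_error(build_incidence(fx$calls, "plasmid"), "unknown sample_type")
})

test_that("similarity metrics match hand arithmetic", {
  m <- matrix(c(1, 1, 0,
                1, 0, 1), ncol = 2,
              dimnames = list(NULL, c("P1", "P2")))
  class(m) <- c("snv_incidence", class(m))
  expect_equal(unclass(similarity_matrix(m, "cosine"))["P1", "P2"], 0.5)
  expect_equal(unclass(similarity_matrix(m, "jaccard"))["P1", "P2"], 1 / 3)

  ident <- matrix(c(1, 0, 1, 1, 0, 1), ncol = 2,
                  dimnames = list(NULL, c("A", "B")))
  class(ident) <- c("snv_incidence", class(ident))
  for (met in c("cosine", "jaccard", "pearson")) {
    expect_equal(unclass(similarity_matrix(ident, met))["A", "B"], 1,
                 info = met)
  }

  disj <- matrix(c(1, 0, 0, 1), ncol = 2,
                 dimnames = list(NULL, c("A", "B")))
  class(disj) <- c("snv_incidence", class(disj))
  expect_equal(unclass(similarity_matrix(disj, "cosine"))["A", "B"], 0)
  expect_equal(unclass(similarity_matrix(disj, "jaccard"))["A", "B"], 0)

  # an all-zero column: its pairs are undefined, not 0
  z <- matrix(c(1, 1, 0, 0), ncol = 2, dimnames = list(NULL, c("A", "Z")))
  class(z) <- c("snv_incidence", class(z))
  expect_true(is.na(unclass(similarity_matrix(z, "cosine"))["A", "Z"]))
  expect_true(is.na(unclass(similarity_matrix(z, "pearson"))["A", "Z"]))
})

test_that("similarity invariants: symmetry, unit diagonal, jaccard <= cosine, sample-order invariance", {
  for (seed in c(2, 8, 21)) {
    fx <- random_fixture(seed, n_pipe = 4, n_samp = 3, n_var = 8,
                         p_detect = 0.5)
    inc <- build_incidence(fx$calls, "monoclone")
    for (met in c("cosine", "jaccard", "pearson")) {
      v <- unclass(similarity_matrix(inc, met))
      expect_equal(v, t(v))
      expect_equal(unname(diag(v)), rep(1, ncol(v)))
    }
    cosv <- unclass(similarity_matrix(inc, "cosine"))
    jacv <- unclass(similarity_matrix(inc, "jaccard"))
    expect_true(all(jacv <= cosv + 1e-12))
    expect_true(all(cosv >= 0 & cosv <= 1 + 1e-12))

    # permuting incidence rows must not change any similarity value
    perm <- sample(nrow(inc))
    incp <- unclass(inc)[perm, , drop = FALSE]
    class(incp) <- c("snv_incidence", class(incp))
    expect_equal(unclass(similarity_matrix(incp, "cosine")), cosv,
                 ignore_attr = TRUE)
  }
})

test_that("clustering merges the most similar pair first and is tie-stable", {
  m <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 1), ncol = 3,
              dimnames = list(NULL, c("P1", "P2", "P3")))
  class(m) <- c("snv_incidence", class(m))
  cl <- cluster_pipelines(similarity_matrix(m, "cosine"))
  first_merge <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first_merge], c("P1", "P2"))
  expect_match(cl$newick, "P1")

  # all pairs equidistant: leaf order follows input order
  eq <- structure(matrix(0.5, 3, 3, dimnames = list(c("A", "B", "C"),
                                                    c("A", "B", "C"))),
                  class = "snv_similarity", metric = "cosine")
  diag(eq) <- 1
  expect_equal(cluster_pipelines(eq)$order, c("A", "B", "C"))

  nas <- eq; nas[1, 2] <- nas[2, 1] <- NA
  expect_error(cluster_pipelines(nas), "missing cells")
})

test_that("caller-dominant and mapper-dominant studies cluster along their axis", {
  grouping_pure <- function(preset, by, k) {
    st <- generate_study(design = sample_design(2, 3, 2, 4, 1),
                         behaviors = pipeline_behaviors(preset),
                         n_variants = 2000, purity = 0.2, seed = 42)
    calls <- apply_filters(st$calls)
    sm <- similarity_matrix(build_incidence(calls, "monoclone"), "cosine")
    grp <- cut_clusters(cluster_pipelines(sm), k)
    ids <- split_pipeline_id(grp$pipeline_id)
    tab <- table(grp$cluster, ids[[by]])
    all(rowSums(tab > 0) == 1)
  }
  expect_true(grouping_pure("caller_dominant", "caller", 4))
  expect_true(grouping_pure("mapper_dominant", "mapper", 3))
})

test_that("tidy/glance/autoplot provide the expected surfaces", {
  fx <- random_fixture(6, n_pipe = 4, n_samp = 2, n_var = 8, p_detect = 0.6)
  sm <- similarity_matrix(build_incidence(fx$calls, "monoclone"), "jaccard")
  td <- tidy(sm)
  expect_equal(nrow(td), choose(4, 2))
  expect_true(all(td$metric == "jaccard"))
  gl <- glance(sm)
  expect_equal(gl$n_pipelines, 4L)
  expect_s3_class(autoplot(sm), "ggplot")
})
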