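test_that("probe selection keeps shared-signal probes and rejects noise", {
  pair <- tiny_expr_pair(n = 300, n_shared = 100, n_noise = 900, seed = 21)
  sel <- select_corr_probes(pair$a, pair$b, threshold = 0.75)
  expect_true(all(sel$correlation > 0.75))
  expect_true(all(grepl("^sh", sel$probe_id)))
  expect_gt(nrow(sel), 85)  # nearly all 100 shared probes at r ~ 0.9
})

test_that("a copied tissue selects every non-constant probe at r = 1", {
  pair <- tiny_expr_pair(seed = 4)
  copy <- expr_set("b", pair$a$values, pair$a$probes)
  sel <- select_corr_probes(pair$a, copy, threshold = 0.75)
  expect_setequal(sel$probe_id, pair$a$probes$probe_id)
  expect_equal(sel$correlation, rep(1, nrow(sel)))
  # a constant probe has undefined correlation and is excluded
  vals <- pair$a$values; vals[, "no01"] <- 5
  flat <- expr_set("b", vals, pair$a$probes)
  expect_false("no01" %in%
                 select_corr_probes(pair$a, flat, threshold = -0.99)$probe_id)
})

test_that("probe selection needs at least 3 overlapping samples", {
  pair <- tiny_expr_pair(seed = 4)
  two <- expr_set("b", pair$b$values[1:2, ], pair$b$probes)
  expect_error(select_corr_probes(pair$a, two), "3 samples")
})

test_that("pair similarity has unit diagonal for identical data and flags missing", {
  pair <- tiny_expr_pair(seed = 8)
  copy <- expr_set("b", pair$a$values, pair$a$probes)
  sel <- select_corr_probes(pair$a, copy)
  sim <- pair_similarity(pair$a, copy, sel, min_probes = 5)
  expect_equal(unname(diag(sim)), rep(1, nrow(sim)))
  vals <- pair$a$values
  vals["S001", sel$probe_id] <- NA
  holey <- expr_set("a", vals, pair$a$probes)
  sim2 <- pair_similarity(holey, copy, sel, min_probes = 5)
  expect_true(all(is.na(sim2["S001", ])))
  expect_error(pair_similarity(pair$a, copy, sel$probe_id[1:3]),
               "min_probes|threshold")
})

test_that("tissue similarity is the cellwise median over available pairs", {
  m <- function(v) similarity_matrix(
    matrix(v, 1, 1, dimnames = list("s1", "s1")), "correlation")
  med <- tissue_similarity(list(m(0.2), m(0.8), m(0.9)))
  expect_equal(unname(med["s1", "s1"]), 0.8)
  expect_equal(unname(tissue_similarity(list(m(0.4)))["s1", "s1"]), 0.4)
  expect_true(is.na(tissue_similarity(list(m(NA), m(NA)))["s1", "s1"]))
})

test_that("the similarity decision rule follows self/max/second logic", {
  ids <- c("s1", "s2", "s3")
  base <- matrix(c(0.95, 0.2, 0.1,
                   0.15, 0.9, 0.2,
                   0.2, 0.1, 0.97), 3, 3, byrow = TRUE,
                 dimnames = list(ids, ids))
  d <- diagnose_similarity(similarity_matrix(base, "correlation"))
  expect_equal(d$status, rep("correct", 3))

  swapped <- base                      # a true swap: both rows anomalous
  swapped["s1", ] <- c(0.3, 0.95, 0.5)
  swapped["s2", ] <- c(0.9, 0.15, 0.2)
  d2 <- diagnose_similarity(similarity_matrix(swapped, "correlation"))
  expect_equal(d2$status[1:2], c("relabel", "relabel"))
  expect_equal(d2$inferred_label[1:2], c("s2", "s1"))
  # a lone row pointing at an intact row is a duplicate pattern instead
  dup <- base
  dup["s1", ] <- c(0.3, 0.95, 0.5)
  d2b <- diagnose_similarity(similarity_matrix(dup, "correlation"))
  expect_equal(d2b$status[1], "duplicate")

  nose <- base
  nose["s1", ] <- c(0.3, 0.5, 0.45)   # low self, no confident match
  d3 <- diagnose_similarity(similarity_matrix(nose, "correlation"))
  expect_equal(d3$status[1], "unfixable")

  noself <- matrix(c(0.4, 0.3, 0.35, 0.9), 2, 2,
                   dimnames = list(c("sX", "s2"), c("s2", "s3")))
  d4 <- diagnose_similarity(similarity_matrix(noself, "correlation"))
  expect_equal(d4$status[d4$label == "sX"], "unverifiable")
})

test_that("the decision rule is invariant to joint row/column permutation", {
  set.seed(13)
  ids <- sprintf("s%02d", 1:12)
  m <- matrix(runif(144, 0, 0.5), 12, 12, dimnames = list(ids, ids))
  diag(m) <- runif(12, 0.9, 1)
  m[2, ] <- c(runif(11, 0, 0.4), 0.95)[c(12, 1:11)]  # row 2 points at s12
  m[2, 2] <- 0.1
  perm <- sample(12)
  d <- tidy(diagnose_similarity(similarity_matrix(m, "correlation")))
  dp <- tidy(diagnose_similarity(
    similarity_matrix(m[perm, perm], "correlation")))
  expect_equal(dplyr::arrange(dp, label), dplyr::arrange(d, label))
})

test_that("within-tissue duplicates are found and self pairs never reported", {
  pair <- tiny_expr_pair(n = 40, seed = 30)
  vals <- pair$a$values
  vals["S002", ] <- vals["S001", ] + rnorm(ncol(vals), sd = 0.05)
  es <- expr_set("a", vals, pair$a$probes)
  dup <- find_within_tissue_duplicates(es, colnames(vals), 0.9)
  expect_equal(nrow(dup), 1L)
  expect_setequal(c(dup$sample_1, dup$sample_2), c("S001", "S002"))
  clean <- find_within_tissue_duplicates(pair$a, colnames(vals), 0.9)
  expect_equal(nrow(clean), 0L)
})

test_that("corrections invert swaps and rotate cycles; conflicts error", {
  sets <- tiny_expr_trio(n = 30, seed = 44)
  orig_a <- sets$a$values
  vals <- sets$a$values
  vals[c("S003", "S004"), ] <- vals[c("S004", "S003"), ]       # swap
  vals[c("S010", "S011", "S012"), ] <-
    vals[c("S011", "S012", "S010"), ]                          # 3-cycle
  sets$a <- expr_set("a", vals, sets$a$probes)
  al <- align_expression(sets, min_probes = 5)
  da <- al$diagnoses$a
  rel <- da[da$status == "relabel", ]
  expect_setequal(rel$label, c("S003", "S004", "S010", "S011", "S012"))
  expect_equal(rel$inferred_label[match(c("S003", "S004"), rel$label)],
               c("S004", "S003"))
  expect_equal(rel$inferred_label[match(c("S010", "S011", "S012"), rel$label)],
               c("S011", "S012", "S010"))
  expect_equal(al$diagnoses$b$status, rep("correct", 30))
  expect_equal(al$diagnoses$c$status, rep("correct", 30))
  fixed <- apply_expression_corrections(sets, al$diagnoses)
  expect_identical(fixed$expr_sets$a$values[rownames(orig_a), ], orig_a)
  # re-diagnosis after correction is clean
  al2 <- align_expression(fixed$expr_sets, min_probes = 5)
  expect_true(all(al2$diagnoses$a$status == "correct"))

  conflict <- da
  conflict$inferred_label[conflict$label == "S004"] <- "S004"
  conflict$inferred_label[conflict$label == "S003"] <- "S010"
  expect_error(apply_expression_corrections(sets, list(a = conflict)),
               "conflict|duplicate")
})

test_that("expression duplicates are combined under the target label", {
  sets <- tiny_expr_trio(n = 30, seed = 50)
  vals <- sets$a$values
  vals["S007", ] <- vals["S020", ]                    # duplicate array
  sets$a <- expr_set("a", vals, sets$a$probes)
  al <- align_expression(sets, min_probes = 5)
  da <- al$diagnoses$a
  expect_equal(da$status[da$label == "S007"], "duplicate")
  expect_equal(da$argmax_label[da$label == "S007"], "S020")
  fixed <- apply_expression_corrections(sets, al$diagnoses)
  expect_false("S007" %in% rownames(fixed$expr_sets$a$values))
  expect_equal(fixed$expr_sets$a$values["S020", ],
               colMeans(vals[c("S007", "S020"), ]))
})
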