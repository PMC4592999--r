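# helpers to build a compact single-tissue genotype/expression study
# with strong local eQTL, derived from the small error-free cross
small_eqtl_study <- function() {
  fixture("small_eqtl_study", {
    cr <- small_cross()
    set.seed(55)
    n <- length(cr$ledger$sample_ids)
    markers <- c("D1M02", "D1M03", "D1M04", "D1M05", "D1M06", "D1M07",
                 "D2M02", "D2M03", "D2M04", "D2M05")
    n_eq <- length(markers)
    dose <- matrix(match(cr$ledger$calls_true[, markers], GENO_CODES_T),
                   nrow = n) - 1
    vals <- cbind(
      dose + matrix(rnorm(n * n_eq, sd = 0.25), n),     # eQTL probes
      matrix(rnorm(n * 6, sd = 0.3), n))                # 6 noise probes
    ids <- sprintf("eq%02d", seq_len(n_eq))
    colnames(vals) <- c(ids, sprintf("nz%02d", 1:6))
    rownames(vals) <- cr$ledger$sample_ids
    map <- cr$map
    probes <- tibble::tibble(
      probe_id = colnames(vals),
      chr = c(map$chr[match(markers, map$marker)], "X",
              rep("1", 3), rep("2", 2)),
      pos = c(map$pos[match(markers, map$marker)], 5,
              c(11, 22, 33), c(7, 19)))
    es <- expr_set("t1", vals, probes)
    prob <- calc_genoprob(cr$genotypes, cr$map, epsilon = 0)
    list(cross = cr, es = es, prob = prob,
         obs = call_genotype(prob), markers = markers)
  })
}
GENO_CODES_T <- c("BB", "BR", "RR")

test_that("match_proportion follows its definition", {
  expect_equal(match_proportion(c("BB", "BR", "RR", NA),
                                c("BB", "BR", "BB", "RR")), 2 / 3)
  expect_equal(match_proportion(c("BB", "RR"), c("BB", "RR")), 1)
  expect_true(is.na(match_proportion(c(NA, "BB"), c("BR", NA))))
  expect_error(match_proportion("BB", c("BB", "BR")), "length")
})

test_that("local eQTL selection keeps strong autosomal probes only", {
  st <- small_eqtl_study()
  sel <- select_local_eqtl(st$es, st$prob, lod_threshold = 20)
  expect_setequal(sel$probe_id, sprintf("eq%02d", 1:10))
  expect_true(all(sel$lod > 20))
  expect_false(any(grepl("^nz", sel$probe_id)))       # noise never selected
  # an X-linked probe is excluded regardless of signal: relabel eq01 to X
  probes_x <- st$es$probes
  probes_x$chr[probes_x$probe_id == "eq01"] <- "X"
  es_x <- expr_set("t1", st$es$values, probes_x)
  sel_x <- select_local_eqtl(es_x, st$prob, lod_threshold = 20)
  expect_false("eq01" %in% sel_x$probe_id)
})

test_that("k-NN classifiers recover genotypes from separated clusters", {
  st <- small_eqtl_study()
  sel <- select_local_eqtl(st$es, st$prob, lod_threshold = 20)
  cls <- suppressWarnings(fit_knn(sel, st$es, st$obs, k = 15))
  inf <- infer_eqtl_genotypes(cls, st$es)
  # compare inferred genotypes with the true simulated genotypes
  acc <- vapply(seq_along(cls), function(j) {
    mk <- attr(st$prob, "grid")$marker[cls[[j]]$grid_index]
    truth <- st$cross$ledger$calls_true[rownames(inf), mk]
    match_proportion(truth, inf[, j])
  }, numeric(1))
  expect_true(all(acc > 0.95))
  expect_gt(mean(!is.na(inf)), 0.8)
})

test_that("the vote rule is strict: exactly 80% abstains, above it calls", {
  # 100 training points in 1-D: 32 BB then 8 BR nearest, 60 RR far away
  train_x <- matrix(c(seq(0.00, 0.31, by = 0.01),
                      seq(0.40, 0.47, by = 0.01),
                      seq(50, 109, by = 1)), ncol = 1,
                    dimnames = list(sprintf("tr%03d", 1:100), "p1"))
  train_g <- matrix(c(rep("BB", 32), rep("BR", 8), rep("RR", 60)),
                    ncol = 1, dimnames = list(rownames(train_x), NULL))
  eqtl <- tibble::tibble(probe_id = "p1", chr = "1", pos = 0,
                         grid_index = 1L, lod = 200)
  probes <- tibble::tibble(probe_id = "p1", chr = "1", pos = 0)
  es <- expr_set("t", rbind(train_x, query = 0.15), probes)
  cls <- fit_knn(eqtl, es, train_g, k = 40)
  inf <- infer_eqtl_genotypes(cls, es)
  expect_true(is.na(inf["query", 1]))                  # 32/40 is not enough
  train_g2 <- train_g; train_g2[33, 1] <- "BB"         # now 33/40
  cls2 <- fit_knn(eqtl, es, train_g2, k = 40)
  expect_equal(infer_eqtl_genotypes(cls2, es)["query", 1], "BB")
  # missing expression yields NA
  es_na <- expr_set("t", rbind(train_x, query = NA_real_), probes)
  expect_true(is.na(infer_eqtl_genotypes(fit_knn(eqtl, es_na, train_g, k = 40),
                                         es_na)["query", 1]))
})

test_that("the match filter drops planted mislabels and is idempotent on clean data", {
  st <- small_eqtl_study()
  sel <- select_local_eqtl(st$es, st$prob, lod_threshold = 20)
  # plant a mislabel: swap two samples' expression rows
  vals <- st$es$values
  vals[c(3, 50), ] <- vals[c(50, 3), ]
  es_bad <- expr_set("t1", vals, st$es$probes)
  cls <- suppressWarnings(fit_knn(sel, es_bad, st$obs, k = 15))
  inf <- infer_eqtl_genotypes(cls, es_bad)
  rf <- suppressWarnings(
    refit_after_filter(cls, sel, es_bad, st$obs, inf, min_match = 0.7))
  bad_ids <- rownames(vals)[c(3, 50)]
  expect_true(all(!rf$match$kept[rf$match$sample_id %in% bad_ids]))
  expect_true(all(rf$match$kept[!rf$match$sample_id %in% bad_ids]))
  # clean data: nothing filtered, training sets unchanged
  cls_c <- suppressWarnings(fit_knn(sel, st$es, st$obs, k = 15))
  inf_c <- infer_eqtl_genotypes(cls_c, st$es)
  rf_c <- suppressWarnings(
    refit_after_filter(cls_c, sel, st$es, st$obs, inf_c, min_match = 0.7))
  expect_true(all(rf_c$match$kept))
  expect_equal(lapply(rf_c$classifiers, function(u) nrow(u$train_x)),
               lapply(cls_c, function(u) nrow(u$train_x)))
})

test_that("combined similarity pools matches rather than averaging proportions", {
  obs <- matrix(c("BB", "BR", "RR", "BB",
                  "BB", "BR", NA, "RR"), 2, 4, byrow = TRUE,
                dimnames = list(c("d1", "d2"), NULL))
  infA <- matrix(c("BB", "BR", "RR", "RR"), 1, 4,
                 dimnames = list("m1", 1:4))
  infB <- matrix(c("BB", "RR"), 1, 2, dimnames = list("m1", c(1, 2)))
  simA <- dna_mrna_similarity(obs, list(tA = infA))
  expect_equal(unname(simA$combined["d1", "m1"]), 3 / 4)
  expect_equal(simA$combined, simA$per_tissue$tA)
  simAB <- dna_mrna_similarity(obs, list(tA = infA, tB = infB))
  expect_equal(unname(simAB$combined["d1", "m1"]), 4 / 6)   # (3+1)/(4+2)
  # per-cell pooling lies between the per-tissue extremes
  pa <- simAB$per_tissue$tA["d1", "m1"]; pb <- simAB$per_tissue$tB["d1", "m1"]
  expect_true(min(pa, pb) <= simAB$combined["d1", "m1"] &&
                simAB$combined["d1", "m1"] <= max(pa, pb))
})

test_that("a DNA sample with no expression data is unverifiable, never relabeled", {
  sim <- matrix(c(0.97, 0.40, 0.38, 0.96), 2, 2, byrow = TRUE,
                dimnames = list(c("d1", "d2"), c("d1", "d2")))
  sim <- rbind(sim, orphan = c(0.41, 0.44))   # DNA row with no own column
  d <- diagnose_dna(similarity_matrix(sim, "match_proportion"))
  expect_equal(d$status[d$label == "orphan"], "unverifiable")
  expect_equal(d$status[d$label != "orphan"], c("correct", "correct"))
})
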