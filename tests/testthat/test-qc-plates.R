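test_that("duplicate DNA detection reports identical and near-identical pairs", {
  cr <- medium_cross()
  calls <- cr$genotypes$calls
  set.seed(6)
  # plant a duplicate with ~1% call corruption
  dup <- calls[1, ]
  flip <- sample(length(dup), 1)
  dup[flip] <- setdiff(c("BB", "BR", "RR"), dup[flip])[1]
  calls <- rbind(calls, dupA = calls[1, ], dupB = dup)
  gt <- genotype_table(calls, c(cr$genotypes$sex, "female", "female"))
  found <- find_duplicate_dna(gt, identity_threshold = 0.98)
  pairs <- paste(found$sample_1, found$sample_2)
  # every reported pair involves the planted duplicates, none are
  # independent F2 pairs (whose identity concentrates near 0.375)
  expect_true(all(grepl("dup|Mouse0001", pairs)))
  expect_equal(nrow(found), 3L)       # 0001-dupA, 0001-dupB, dupA-dupB
  expect_true(all(found$identity > 0.98))
  expect_true(min(found$identity) >= 1 - 2 / ncol(calls))
})

test_that("duplicate detection is symmetric and order-invariant", {
  cr <- medium_cross()
  calls <- rbind(cr$genotypes$calls, twin = cr$genotypes$calls[5, ])
  gt1 <- genotype_table(calls, c(cr$genotypes$sex, "male"))
  set.seed(14)
  perm <- sample(nrow(calls))
  gt2 <- genotype_table(calls[perm, , drop = FALSE],
                        c(cr$genotypes$sex, "male")[perm])
  f1 <- find_duplicate_dna(gt1)
  f2 <- find_duplicate_dna(gt2)
  norm <- function(f) sort(paste(pmin(f$sample_1, f$sample_2),
                                 pmax(f$sample_1, f$sample_2)))
  expect_equal(norm(f1), norm(f2))
  expect_equal(nrow(f1), 1L)
})

test_that("sex versus X concordance applies the cross's hemizygosity rules", {
  map <- genetic_map(sprintf("x%d", 1:6), rep("X", 6), 0:5)
  mk <- function(v) matrix(v, 1, 6)
  calls <- rbind(
    f_ok = c("RR", "BR", "RR", "BR", "BR", "RR"),
    m_one_het = c("BB", "BB", "BR", "RR", "RR", "RR"),
    f_bad = c("BB", "BB", "BB", "BB", "BB", "RR"),
    m_ok = c("RR", "RR", "RR", "RR", "RR", "RR"),
    u_skip = c("BB", "BB", "BB", "BB", "BB", "BB"))
  colnames(calls) <- map$marker
  gt <- genotype_table(calls, c("female", "male", "female", "male",
                                "unknown"))
  rep_ <- check_sex_vs_x(gt, map, min_discordant = 2)
  expect_equal(rep_$flag[rep_$sample_id == "f_ok"], "ok")
  expect_equal(rep_$flag[rep_$sample_id == "m_one_het"],
               "probable_genotyping_error")
  expect_equal(rep_$flag[rep_$sample_id == "f_bad"], "sex_discordant")
  expect_equal(rep_$n_discordant[rep_$sample_id == "f_bad"], 5)
  expect_equal(rep_$flag[rep_$sample_id == "m_ok"], "ok")
  expect_equal(rep_$flag[rep_$sample_id == "u_skip"], "unknown_sex")
})

test_that("crossover counts match the simulator's ledger exactly when error-free", {
  cr <- small_cross()   # epsilon = 0, no missing calls
  prob <- calc_genoprob(cr$genotypes, cr$map, epsilon = 0)
  qc <- genotype_qc(cr$genotypes, prob, cr$map)
  expect_equal(unname(qc$n_crossovers),
               unname(cr$ledger$crossovers_true[qc$sample_id]))
  expect_true(all(qc$missing_rate == 0))
  expect_false(any(qc$flag_missing))
})

test_that("corrupted samples are flagged by the robust QC cutoffs", {
  cr <- medium_cross()
  calls <- cr$genotypes$calls
  set.seed(77)
  # sample 1: heavy heterozygous corruption (as in DNA contamination)
  # scattered across the genome -> many apparent crossovers
  hit <- seq(1, ncol(calls), by = 3)
  calls[1, hit] <- "BR"
  # sample 2: everything missing
  calls[2, ] <- NA_character_
  gt <- genotype_table(calls, cr$genotypes$sex)
  prob <- calc_genoprob(gt, cr$map, epsilon = 0.002)
  qc <- genotype_qc(gt, prob, cr$map)
  expect_equal(qc$missing_rate[2], 1)
  expect_true(qc$flag_missing[2])
  expect_true(qc$flag_crossovers[1])
  expect_gt(qc$n_crossovers[1], median(qc$n_crossovers) * 3)
})

test_that("plate-error classification computes offsets, categories and runs", {
  lay <- plate_layout(sprintf("s%02d", 1:20),
                      plate = rep(c("P1", "P2"), each = 10),
                      well = index_well(c(1:10, 1:10)))
  mk_diag <- function(df) new_diagnosis(tibble::tibble(
    label = df$label, status = df$status, inferred_label = df$inf,
    self = 0.3, max_score = 0.95, argmax_label = df$inf, second = 0.4),
    score_kind = "match_proportion")
  # a run of three off-by-one errors plus one off-by-two, one long-range,
  # one cross-plate and one unknown sample
  d <- mk_diag(tibble::tibble(
    label = c("s03", "s04", "s05", "s08", "s09", "s11", "s20"),
    status = c(rep("relabel", 6), "relabel"),
    inf = c("s02", "s03", "s04", "s06", "s01", "s02", "ghost")))
  res <- classify_plate_errors(d, lay)
  get <- function(l, col) res[[col]][res$label == l]
  expect_equal(get("s03", "category"), "off-by-one")
  expect_equal(get("s03", "offset"), 1L)
  expect_equal(get("s04", "run_length"), 3L)
  expect_equal(unique(res$run_id[res$label %in% c("s03", "s04", "s05")]),
               res$run_id[res$label == "s03"])
  expect_equal(get("s08", "category"), "off-by-two")
  expect_equal(get("s09", "category"), "long-range")
  expect_equal(get("s11", "category"), "cross-plate")
  expect_equal(get("s20", "category"), "unknown-layout")
})

test_that("an empty diagnosis yields an empty plate report", {
  lay <- plate_layout("s1", "P1", "A01")
  d <- new_diagnosis(tibble::tibble(
    label = "s1", status = "correct", inferred_label = NA_character_,
    self = 0.99, max_score = 0.99, argmax_label = "s1", second = 0.4))
  expect_equal(nrow(classify_plate_errors(d, lay)), 0L)
})
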