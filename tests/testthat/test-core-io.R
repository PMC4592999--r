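make_tiny_cross <- function() {
  map <- genetic_map(c("m1", "m2"), c("1", "1"), c(0, 10))
  calls <- matrix(c("BB", "BR", "RR", NA, "BB", "RR"), nrow = 3,
                  dimnames = list(c("s1", "s2", "s3"), c("m1", "m2")))
  list(genotypes = genotype_table(calls, c("female", "male", "female"), map),
       map = map)
}

test_that("cross files round-trip exactly, including missing calls", {
  cr <- make_tiny_cross()
  gf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  write_cross(cr$genotypes, cr$map, gf, mf)
  back <- read_cross(gf, mf)
  expect_identical(back$genotypes$calls, cr$genotypes$calls)
  expect_identical(unname(back$genotypes$sex), unname(cr$genotypes$sex))
  expect_identical(back$map$marker, cr$map$marker)
  expect_equal(back$map$pos, cr$map$pos)
})

test_that("unknown genotype codes become NA with a reported count", {
  gf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,m1,m2", "s1,female,BB,XX", "s2,male,BR,RR",
               "s3,male,RR,BB"), gf)
  writeLines(c("marker,chr,pos", "m1,1,0", "m2,1,10"), mf)
  expect_message(cr <- read_cross(gf, mf), "1 unknown genotype code")
  expect_identical(sum(is.na(cr$genotypes$calls)), 1L)
  expect_true(is.na(cr$genotypes$calls["s1", "m2"]))
})

test_that("marker/map mismatches and duplicate ids are hard errors", {
  gf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,m1,mX", "s1,female,BB,BB"), gf)
  writeLines(c("marker,chr,pos", "m1,1,0", "m2,1,10"), mf)
  expect_error(read_cross(gf, mf), "mX")
  writeLines(c("id,sex,m1,m2", "s1,female,BB,BB", "s1,male,RR,RR"), gf)
  expect_error(read_cross(gf, mf), "duplicate sample ids")
})

test_that("expression files round-trip bitwise and flag unannotated probes", {
  set.seed(3)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("s1", "s2", "s3"),
                                 c("p1", "p2", "p3", "p4")))
  vals[2, 3] <- NA
  probes <- tibble::tibble(probe_id = colnames(vals),
                           chr = c("1", "2", NA, NA),
                           pos = c(5, 10, NA, NA))
  es <- expr_set("kidney", vals, probes)
  ef <- withr::local_tempfile(fileext = ".tsv")
  af <- withr::local_tempfile(fileext = ".csv")
  write_expression(es, ef, af)
  back <- read_expression(ef, af, "kidney")
  expect_identical(back$values, es$values)
  expect_identical(sum(is.na(back$probes$chr)), 2L)
})

test_that("orphan annotation warns and non-numeric cells error with coordinates", {
  ef <- withr::local_tempfile(fileext = ".tsv")
  af <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id\tp1\tp2", "s1\t0.5\t1.2", "s2\t0.1\t0.7"), ef)
  writeLines(c("probe_id,chr,pos", "p1,1,5", "p2,2,7", "ghost,3,1"), af)
  expect_warning(es <- read_expression(ef, af, "liver"), "ghost|1 annotation")
  expect_equal(dim(es$values), c(2L, 2L))
  writeLines(c("id\tp1\tp2", "s1\t0.5\toops", "s2\t0.1\t0.7"), ef)
  expect_error(suppressWarnings(read_expression(ef, af, "liver")),
               "s1.*p2")
})

test_that("diagnosis reports round-trip through the JSON mirror", {
  d <- new_diagnosis(tibble::tibble(
    label = c("s1", "s2", "s3"),
    status = c("correct", "relabel", "unverifiable"),
    inferred_label = c(NA, "s5", NA),
    self = c(0.99, 0.3, NA), max_score = c(0.99, 0.95, 0.4),
    argmax_label = c("s1", "s5", "s9"), second = c(0.4, 0.5, 0.35)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diagnosis(d, path)
  back <- read_diagnosis(path)
  expect_equal(tidy(back), tidy(d))
  tsv <- readLines(path)
  expect_match(tsv[3], "relabel\ts5")
})

test_that("an empty diagnosis writes a header-only report", {
  d <- new_diagnosis(tibble::tibble(
    label = character(), status = character(),
    inferred_label = character(), self = numeric(),
    max_score = numeric(), argmax_label = character(),
    second = numeric()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diagnosis(d, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_diagnosis(path)), 0L)
})

test_that("plate layouts validate wells and reject double-booked wells", {
  expect_error(plate_layout("s1", "P1", "Z01"), "invalid well")
  expect_error(plate_layout(c("s1", "s2"), c("P1", "P1"), c("A01", "A01")),
               "duplicate")
  lay <- plate_layout(c("s1", "s2"), c("P1", "P1"), c("a01", "H12"))
  expect_equal(lay$well, c("A01", "H12"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(lay, path, row.names = FALSE)
  expect_equal(read_plate_layout(path)$well, lay$well)
})

test_that("well indexing round-trips in both filling orders", {
  wells <- index_well(1:96)
  expect_equal(well_index(wells), 1:96)
  expect_equal(well_index(index_well(1:96, "row"), "row"), 1:96)
  expect_equal(index_well(c(1, 2, 9)), c("A01", "B01", "A02"))  # column-major
})
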