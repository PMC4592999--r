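# Shared domain containers: genotype tables, expression sets, similarity
# matrices, diagnoses, plate layouts.

#' Genotype table constructor
#'
#' Holds categorical genotype calls for an F2 intercross: a samples x
#' markers character matrix with entries in `BB`, `BR`, `RR` or `NA`
#' (missing). On the X chromosome, hemizygous males are stored with the
#' homozygous code since homozygous and hemizygous genotypes cannot be
#' distinguished by a codominant assay.
#'
#' @param calls Character matrix (samples x markers) with rownames =
#'   sample ids and colnames = marker names; entries `"BB"`, `"BR"`,
#'   `"RR"` or `NA`.
#' @param sex Character vector per sample: `"female"`, `"male"` or
#'   `"unknown"`.
#' @param map Optional `genetic_map`; when given, marker columns must
#'   match the map's markers in order.
#' @return A list of class `genotype_table` with elements `calls`, `sex`,
#'   `sample_ids`.
#' @export
genotype_table <- function(calls, sex, map = NULL) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)), !is.null(colnames(calls)))
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  bad <- !(calls %in% c(GENO_CODES, NA))
  if (any(bad))
    stop("invalid genotype codes: ", paste(unique(calls[bad]), collapse = ", "))
  sex <- as.character(sex)
  if (length(sex) != nrow(calls)) stop("sex must have one entry per sample")
  if (!all(sex %in% c("female", "male", "unknown")))
    stop("sex entries must be 'female', 'male' or 'unknown'")
  if (!is.null(map)) {
    if (!identical(colnames(calls), map$marker))
      stop("genotype columns do not match map markers; offenders: ",
           paste(head(c(setdiff(colnames(calls), map$marker),
                        setdiff(map$marker, colnames(calls))), 10), collapse = ", "))
  }
  structure(list(calls = calls, sex = setNames(sex, rownames(calls)),
                 sample_ids = rownames(calls)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " markers; ", sprintf("%.1f%%", 100 * mean(is.na(x$calls))),
      " missing\n", sep = "")
  invisible(x)
}

#' Expression set constructor
#'
#' A per-tissue expression container: a samples x probes numeric matrix
#' of log-ratio expression values (missing allowed) plus per-probe
#' genomic annotation in centimorgan map coordinates (chromosome and
#' position may be unknown).
#'
#' @param tissue Tissue name.
#' @param values Numeric matrix (samples x probes) with rownames = sample
#'   ids, colnames = probe ids.
#' @param probes Tibble with columns `probe_id`, `chr` (character or
#'   `NA`), `pos` (cM or `NA`), one row per probe column of `values`.
#' @return A list of class `expr_set`.
#' @export
expr_set <- function(tissue, values, probes) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in tissue ", tissue)
  if (anyDuplicated(colnames(values)))
    stop("duplicate probe ids in tissue ", tissue)
  probes <- as_tibble(probes)
  stopifnot(all(c("probe_id", "chr", "pos") %in% names(probes)))
  if (!identical(as.character(probes$probe_id), colnames(values)))
    stop("probe annotation does not match value columns (order and names)")
  structure(list(tissue = tissue, values = values, probes = probes),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("<expr_set> tissue '", x$tissue, "': ", nrow(x$values), " samples x ",
      ncol(x$values), " probes (", sum(is.na(x$probes$chr)),
      " with unknown location)\n", sep = "")
  invisible(x)
}

#' Similarity matrix constructor
#'
#' Labeled rows x labeled columns of similarity scores with missing cells
#' allowed; `score_kind` records whether the scores are correlations (in
#' `[-1, 1]`) or match proportions (in `[0, 1]`).
#'
#' @param values Numeric matrix with dimnames.
#' @param score_kind `"correlation"` or `"match_proportion"`.
#' @return The matrix with class `similarity_matrix` and a `score_kind`
#'   attribute.
#' @export
similarity_matrix <- function(values, score_kind = c("correlation",
                                                     "match_proportion")) {
  score_kind <- match.arg(score_kind)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  rng <- suppressWarnings(range(values, na.rm = TRUE))  # all-NA allowed
  lo <- if (score_kind == "correlation") -1 else 0
  if (is.finite(rng[1]) && (rng[1] < lo - 1e-8 || rng[2] > 1 + 1e-8))
    stop("similarity scores outside legal range for ", score_kind)
  structure(values, class = c("similarity_matrix", "matrix", "array"),
            score_kind = score_kind)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", nrow(x), " x ", ncol(x), " (",
      attr(x, "score_kind"), "); ", sum(is.na(x)), " missing cells\n",
      sep = "")
  invisible(x)
}

#' Diagnosis constructor
#'
#' Per-sample verdicts from a similarity matrix. Statuses: `correct`,
#' `relabel` (with `inferred_label`), `duplicate` (this row carries the
#' same underlying sample as the row whose label it matches), `unfixable`
#' (clearly wrong but no confident replacement) and `unverifiable` (no
#' self-similarity available and no strong match).
#'
#' @param df Tibble with columns `label`, `status`, `inferred_label`,
#'   `self`, `max_score`, `argmax_label`, `second`.
#' @param score_kind Score scale of the evidence columns.
#' @return A tibble of class `mixup_diagnosis`.
#' @export
new_diagnosis <- function(df, score_kind = "correlation") {
  df <- as_tibble(df)
  need <- c("label", "status", "inferred_label", "self", "max_score",
            "argmax_label", "second")
  stopifnot(all(need %in% names(df)))
  ok <- df$status %in% c("correct", "relabel", "duplicate", "unfixable",
                         "unverifiable")
  if (!all(ok)) stop("illegal status: ", paste(unique(df$status[!ok]), collapse = ", "))
  bad <- df$status == "relabel" &
    (is.na(df$inferred_label) | df$inferred_label == df$label)
  if (any(bad)) stop("relabel rows must carry a different inferred label")
  structure(df, class = c("mixup_diagnosis", class(tibble())),
            score_kind = score_kind)
}

#' @export
tidy.mixup_diagnosis <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @export
glance.mixup_diagnosis <- function(x, ...) {
  tibble(
    n = nrow(x),
    correct = sum(x$status == "correct"),
    relabel = sum(x$status == "relabel"),
    duplicate = sum(x$status == "duplicate"),
    unfixable = sum(x$status == "unfixable"),
    unverifiable = sum(x$status == "unverifiable")
  )
}

#' Plate layout constructor
#'
#' @param sample_id Character vector of sample ids.
#' @param plate Character vector of plate names.
#' @param well Well strings, row letter `A`-`H` plus column `01`-`12`.
#' @return A tibble of class `plate_layout`.
#' @export
plate_layout <- function(sample_id, plate, well) {
  well <- toupper(as.character(well))
  ok <- grepl("^[A-H](0[1-9]|1[0-2])$", well)
  if (!all(ok)) stop("invalid well strings: ", paste(unique(well[!ok]), collapse = ", "))
  lay <- tibble(sample_id = as.character(sample_id),
                plate = as.character(plate), well = well)
  if (anyDuplicated(lay[, c("plate", "well")]))
    stop("duplicate (plate, well) assignments")
  class(lay) <- unique(c("plate_layout", class(lay)))
  lay
}

#' Filling-order index of wells
#'
#' Converts well strings to a 1-based position in plate filling order.
#' Column-major order (`A01, B01, ..., H01, A02, ...`) is the default,
#' matching single-channel pipetting down the columns; row-major order is
#' available.
#'
#' @param well Character vector of well strings.
#' @param order `"column"` or `"row"` major.
#' @return Integer positions in 1..96.
#' @export
well_index <- function(well, order = c("column", "row")) {
  order <- match.arg(order)
  row <- match(substr(well, 1, 1), LETTERS[1:8])
  col <- as.integer(substr(well, 2, 3))
  if (order == "column") (col - 1L) * 8L + row else (row - 1L) * 12L + col
}

#' @rdname well_index
#' @param index Integer positions in 1..96.
#' @export
index_well <- function(index, order = c("column", "row")) {
  order <- match.arg(order)
  if (order == "column") {
    row <- (index - 1L) %% 8L + 1L
    col <- (index - 1L) %/% 8L + 1L
  } else {
    col <- (index - 1L) %% 12L + 1L
    row <- (index - 1L) %/% 12L + 1L
  }
  sprintf("%s%02d", LETTERS[row], col)
}
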