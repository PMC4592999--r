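# Readers and writers for the on-disk formats: genotype CSV + map CSV,
# expression TSV + probe annotation CSV, plate layout CSV, diagnosis
# report TSV with a JSON mirror.

default_code_map <- c(BB = "BB", BR = "BR", RR = "RR")

#' Read a cross: genotype CSV plus genetic map CSV
#'
#' The genotype file is comma-separated with samples in rows: first
#' column the sample id, second column the sex (`female`/`male`/
#' `unknown`), then one column per marker. The map file has columns
#' `marker`, `chr`, `pos` (centimorgans). Genotype codes are configurable
#' through `code_map` (file code -> `BB`/`BR`/`RR`); empty fields are
#' missing, and any other unknown code is converted to `NA` with a
#' message reporting the count.
#'
#' @param genotype_file,map_file Paths.
#' @param code_map Named character vector mapping the internal codes
#'   `BB`, `BR`, `RR` to the codes used in the file.
#' @param x_chr Chromosome labels treated as X-linked.
#' @return A list with elements `genotypes` (a [genotype_table()]) and
#'   `map` (a [genetic_map()]).
#' @export
read_cross <- function(genotype_file, map_file, code_map = default_code_map,
                       x_chr = "X") {
  map_df <- read.csv(map_file, colClasses = c("character", "character", "numeric"))
  names(map_df)[1:3] <- c("marker", "chr", "pos")
  map <- genetic_map(map_df$marker, map_df$chr, map_df$pos, x_chr = x_chr)

  g <- read.csv(genotype_file, colClasses = "character", check.names = FALSE)
  ids <- g[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", genotype_file, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sex <- tolower(g[[2]])
  raw <- as.matrix(g[, -(1:2), drop = FALSE])
  rownames(raw) <- ids

  extra <- setdiff(colnames(raw), map$marker)
  missing_mk <- setdiff(map$marker, colnames(raw))
  if (length(extra) || length(missing_mk))
    stop("marker/map mismatch; in genotypes but not map: ",
         paste(head(extra, 10), collapse = ", "),
         "; in map but not genotypes: ",
         paste(head(missing_mk, 10), collapse = ", "))
  raw <- raw[, map$marker, drop = FALSE]

  rev_map <- setNames(names(code_map), code_map)
  calls <- matrix(rev_map[raw], nrow = nrow(raw), dimnames = dimnames(raw))
  calls[raw == "" | is.na(raw)] <- NA_character_
  unknown <- !is.na(raw) & raw != "" & is.na(calls)
  if (any(unknown)) {
    message(sum(unknown), " unknown genotype code(s) set to NA")
    calls[unknown] <- NA_character_
  }
  list(genotypes = genotype_table(calls, sex, map), map = map)
}

#' Write a cross to genotype CSV and map CSV
#'
#' Inverse of [read_cross()]: missing calls become empty fields.
#'
#' @param genotypes A `genotype_table`.
#' @param map A `genetic_map`.
#' @param genotype_file,map_file Output paths.
#' @param code_map As in [read_cross()].
#' @export
write_cross <- function(genotypes, map, genotype_file, map_file,
                        code_map = default_code_map) {
  out <- matrix(code_map[genotypes$calls], nrow = nrow(genotypes$calls),
                dimnames = dimnames(genotypes$calls))
  out[is.na(out)] <- ""
  df <- data.frame(id = rownames(out), sex = unname(genotypes$sex), out,
                   check.names = FALSE)
  write.csv(df, genotype_file, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(marker = map$marker, chr = map$chr, pos = map$pos),
            map_file, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a per-tissue expression matrix with probe annotation
#'
#' The expression file is tab-separated with samples in rows (first
#' column the sample id, remaining columns probes); empty fields are
#' missing values. The annotation CSV has columns `probe_id`, `chr`,
#' `pos`; probes lacking an annotation row get unknown location (still
#' usable for expression alignment, excluded from eQTL selection), and
#' annotation rows for absent probes are ignored with a warning.
#'
#' @param file,annotation_file Paths.
#' @param tissue Tissue name.
#' @return An [expr_set()].
#' @export
read_expression <- function(file, annotation_file, tissue) {
  df <- read.delim(file, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, colnames(raw))))
  bad <- is.na(vals) & !(raw == "" | is.na(raw) | raw == "NA")
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at sample '", ids[w[1]], "', probe '",
         colnames(raw)[w[2]], "' in ", file)
  }
  ann <- read.csv(annotation_file,
                  colClasses = c("character", "character", "numeric"))
  names(ann)[1:3] <- c("probe_id", "chr", "pos")
  orphan <- setdiff(ann$probe_id, colnames(vals))
  if (length(orphan))
    warning(length(orphan), " annotation row(s) for probes not in the matrix; ignored")
  probes <- tibble(probe_id = colnames(vals)) |>
    dplyr::left_join(as_tibble(ann), by = "probe_id")
  probes$chr[probes$chr %in% c("", "NA")] <- NA_character_
  expr_set(tissue, vals, probes)
}

#' Write a per-tissue expression matrix and its probe annotation
#'
#' Inverse of [read_expression()]. Values are written in full precision
#' (`%.17g`) so a read round-trip reproduces them bitwise.
#'
#' @param es An `expr_set`.
#' @param file,annotation_file Output paths.
#' @export
write_expression <- function(es, file, annotation_file) {
  out <- matrix(sprintf("%.17g", es$values), nrow = nrow(es$values))
  out[is.na(es$values)] <- ""
  df <- data.frame(id = rownames(es$values), out, check.names = FALSE)
  names(df) <- c("id", colnames(es$values))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(data.frame(probe_id = es$probes$probe_id,
                       chr = ifelse(is.na(es$probes$chr), "", es$probes$chr),
                       pos = es$probes$pos),
            annotation_file, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a plate layout CSV (columns sample_id, plate, well)
#' @param file Path.
#' @return A [plate_layout()].
#' @export
read_plate_layout <- function(file) {
  df <- read.csv(file, colClasses = "character")
  plate_layout(df[[1]], df[[2]], df[[3]])
}

#' Write a diagnosis report: TSV plus a machine-readable JSON mirror
#'
#' One row per sample with columns `label`, `status`, `inferred_label`,
#' `self`, `max`, `argmax`, `second`. The JSON mirror (same path with
#' `.json` appended) round-trips through [read_diagnosis()].
#'
#' @param d A `mixup_diagnosis`.
#' @param path Output TSV path; the mirror is written to `paste0(path, ".json")`.
#' @export
write_diagnosis <- function(d, path) {
  df <- data.frame(label = d$label, status = d$status,
                   inferred_label = d$inferred_label, self = d$self,
                   max = d$max_score, argmax = d$argmax_label,
                   second = d$second)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(score_kind = attr(d, "score_kind"), rows = tidy(d)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(NULL)
}

#' @rdname write_diagnosis
#' @export
read_diagnosis <- function(path) {
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rows <- as_tibble(j$rows)
  if (nrow(rows) == 0) {
    rows <- tibble(label = character(), status = character(),
                   inferred_label = character(), self = numeric(),
                   max_score = numeric(), argmax_label = character(),
                   second = numeric())
  }
  for (col in c("label", "status", "inferred_label", "argmax_label"))
    rows[[col]] <- as.character(rows[[col]])
  for (col in c("self", "max_score", "second"))
    rows[[col]] <- as.numeric(rows[[col]])
  new_diagnosis(rows, score_kind = j$score_kind)
}
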