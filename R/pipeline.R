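# End-to-end orchestration: expression alignment, then genotype
# alignment, then genotype QC and plate-geometry classification, with
# all reports written to an output directory and a machine-readable
# summary.

#' Run configuration for the full pipeline
#'
#' Collects every tunable threshold with its documented default and
#' validates ranges; unknown keys are rejected.
#'
#' @param ... Overrides for any of: `corr_threshold` (0.75),
#'   `min_probes` (20), `expr_self_threshold` (0.75),
#'   `expr_match_threshold` (0.8), `expr_margin` (0.1),
#'   `dup_threshold` (0.9), `lod_threshold` (100), `k` (40),
#'   `vote_threshold` (0.8), `min_match` (0.7), `call_threshold` (0.99),
#'   `epsilon` (0.002), `map_function` ("carter_falconer"),
#'   `max_spacing` (0.5), `dna_self_threshold` (0.8),
#'   `dna_match_threshold` (0.8), `dna_margin` (0.1),
#'   `identity_threshold` (0.98), `min_discordant` (2), `k_mad` (5),
#'   `fill_order` ("column"), `use_sex_covariate` (TRUE).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(corr_threshold = 0.75, min_probes = 20,
              expr_self_threshold = 0.75, expr_match_threshold = 0.8,
              expr_margin = 0.1, dup_threshold = 0.9, lod_threshold = 100,
              k = 40, vote_threshold = 0.8, min_match = 0.7,
              call_threshold = 0.99, epsilon = 0.002,
              map_function = "carter_falconer", max_spacing = 0.5,
              dna_self_threshold = 0.8, dna_match_threshold = 0.8,
              dna_margin = 0.1, identity_threshold = 0.98,
              min_discordant = 2, k_mad = 5, fill_order = "column",
              use_sex_covariate = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(corr_threshold > -1, corr_threshold < 1,
              vote_threshold > 0.5, vote_threshold <= 1,
              call_threshold > 0, call_threshold < 1,
              min_match >= 0, min_match <= 1,
              epsilon >= 0, epsilon < 0.5, max_spacing > 0,
              identity_threshold > 0, identity_threshold <= 1,
              min_discordant >= 1, k >= 1, k_mad > 0,
              map_function %in% c("carter_falconer", "haldane", "kosambi"),
              fill_order %in% c("column", "row"))
  })
  class(cfg) <- "run_config"
  cfg
}

#' Run the full mix-up detection and correction pipeline
#'
#' Stages, in order: (1) expression alignment across tissues, with
#' corrections applied; (2) genotype alignment of DNA to (corrected)
#' mRNA samples, with corrections applied; (3) genotype QC — duplicate
#' DNA detection, sex versus X concordance, per-sample metrics — and
#' plate-geometry classification of the inferred DNA errors. All
#' reports are written under `out_dir` when given; a summary with
#' per-category counts is always returned (and written as
#' `summary.json`).
#'
#' @param genotypes A `genotype_table`.
#' @param map The `genetic_map`.
#' @param expr_sets Named list of `expr_set`s.
#' @param layout Optional `plate_layout` (plate classification skipped
#'   when absent).
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `mixup_pipeline`: `expr_alignment`,
#'   `expr_corrected`, `geno_alignment`, `geno_corrected`,
#'   `duplicates_dna`, `sex_check`, `qc`, `plate_errors`, `summary`.
#' @export
run_mixup_pipeline <- function(genotypes, map, expr_sets, layout = NULL,
                               config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "align-expr"
  res <- tryCatch({
    ea <- align_expression(expr_sets,
                           corr_threshold = config$corr_threshold,
                           min_probes = config$min_probes,
                           self_threshold = config$expr_self_threshold,
                           match_threshold = config$expr_match_threshold,
                           margin = config$expr_margin,
                           dup_threshold = config$dup_threshold)
    ec <- apply_expression_corrections(expr_sets, ea$diagnoses)

    stage <- "align-geno"
    ga <- align_genotypes(genotypes, map, ec$expr_sets,
                          lod_threshold = config$lod_threshold,
                          k = config$k,
                          vote_threshold = config$vote_threshold,
                          min_match = config$min_match,
                          call_threshold = config$call_threshold,
                          epsilon = config$epsilon,
                          map_function = config$map_function,
                          max_spacing = config$max_spacing,
                          self_threshold = config$dna_self_threshold,
                          match_threshold = config$dna_match_threshold,
                          margin = config$dna_margin,
                          use_sex_covariate = config$use_sex_covariate)
    gc_ <- apply_genotype_corrections(genotypes, ga$diagnosis)

    stage <- "qc"
    dup_dna <- find_duplicate_dna(genotypes,
                                  identity_threshold = config$identity_threshold)
    # after DNA relabeling, remaining X-chromosome discordances reflect
    # genuine sex-record errors rather than sample mix-ups
    sex_check <- check_sex_vs_x(gc_$genotypes, map,
                                min_discordant = config$min_discordant)
    qc <- genotype_qc(genotypes, ga$prob, map, k_mad = config$k_mad)
    plate_errors <- if (!is.null(layout))
      classify_plate_errors(ga$diagnosis, layout,
                            fill_order = config$fill_order)
    else NULL

    summary <- list(
      expression = lapply(ea$diagnoses, function(d) as.list(glance(d))),
      dna = as.list(glance(ga$diagnosis)),
      dna_duplicate_pairs = nrow(dup_dna),
      sex_discordant = sum(sex_check$flag == "sex_discordant"),
      qc_flagged = sum(qc$flagged))
    list(expr_alignment = ea, expr_corrected = ec, geno_alignment = ga,
         geno_corrected = gc_, duplicates_dna = dup_dna,
         sex_check = sex_check, qc = qc, plate_errors = plate_errors,
         summary = summary)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tis in names(res$expr_alignment$diagnoses))
      write_diagnosis(res$expr_alignment$diagnoses[[tis]],
                      file.path(out_dir, paste0("diagnosis_expr_", tis, ".tsv")))
    write_diagnosis(res$geno_alignment$diagnosis,
                    file.path(out_dir, "diagnosis_dna.tsv"))
    utils::write.table(res$expr_corrected$changes,
                       file.path(out_dir, "changes_expr.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$geno_corrected$changes,
                       file.path(out_dir, "changes_dna.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$duplicates_dna,
                       file.path(out_dir, "duplicates_dna.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$sex_check, file.path(out_dir, "sex_check.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$qc, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$plate_errors))
      utils::write.table(res$plate_errors,
                         file.path(out_dir, "plate_errors.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "mixup_pipeline"
  res
}

#' @export
print.mixup_pipeline <- function(x, ...) {
  cat("<mixup_pipeline>\n")
  cat("  DNA: ", x$summary$dna$correct, " correct, ",
      x$summary$dna$relabel, " relabeled, ", x$summary$dna$duplicate,
      " duplicate, ", x$summary$dna$unfixable, " unfixable, ",
      x$summary$dna$unverifiable, " unverifiable\n", sep = "")
  for (tis in names(x$summary$expression)) {
    s <- x$summary$expression[[tis]]
    cat("  expression/", tis, ": ", s$correct, " correct, ", s$relabel,
        " relabeled, ", s$duplicate, " duplicate\n", sep = "")
  }
  cat("  DNA duplicate pairs: ", x$summary$dna_duplicate_pairs,
      "; sex-discordant: ", x$summary$sex_discordant,
      "; QC-flagged: ", x$summary$qc_flagged, "\n", sep = "")
  invisible(x)
}
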