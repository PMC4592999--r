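# Alignment of DNA samples to mRNA samples: selection of large-effect
# local eQTL, k-nearest-neighbour classifiers predicting eQTL genotype
# from expression, match-proportion similarity matrices, diagnosis and
# correction of the genotype table.

#' Select probes with a strong local eQTL
#'
#' For every probe with known genomic location on an autosome, computes
#' the single-position Haley-Knott LOD at the grid position nearest the
#' probe (no genome scan) and keeps probes whose LOD strictly exceeds
#' `lod_threshold`. Selected probes are grouped by shared grid position
#' into eQTL units of 1-3 probes (when more than 3 probes share a
#' position, the top 3 by LOD are kept).
#'
#' @param es An `expr_set`.
#' @param prob A `geno_prob` array for the DNA samples.
#' @param lod_threshold LOD that must be exceeded (default 100).
#' @param sex Optional named sex vector (used as an interactive
#'   covariate when supplied).
#' @return Tibble with columns `probe_id`, `chr`, `pos`, `grid_index`
#'   (column of `prob`), `lod`; empty (with a warning) when no probe
#'   qualifies.
#' @export
select_local_eqtl <- function(es, prob, lod_threshold = 100, sex = NULL) {
  grid <- attr(prob, "grid")
  auto_chr <- unique(grid$chr)
  eligible <- which(!is.na(es$probes$chr) & !is.na(es$probes$pos) &
                      es$probes$chr %in% auto_chr)
  dna_ids <- dimnames(prob)[[1]]
  common <- intersect(rownames(es$values), dna_ids)
  covar <- NULL
  if (!is.null(sex))
    covar <- as.numeric(sex[common] == "male")
  res <- purrr::map_dfr(eligible, function(j) {
    gi_full <- nearest_position(grid, es$probes$chr[j], es$probes$pos[j])
    gi <- match(gi_full, grid$index)
    y <- es$values[common, j]
    lod <- tryCatch(
      hk_lod(y, prob[common, gi, ], covariates = covar,
             interactive = !is.null(covar)),
      warning = function(w) Inf)
    tibble(probe_id = es$probes$probe_id[j], chr = es$probes$chr[j],
           pos = es$probes$pos[j], grid_index = gi, lod = lod)
  })
  res <- res[res$lod > lod_threshold, , drop = FALSE]
  if (nrow(res) == 0) {
    warning("no probes with LOD > ", lod_threshold, " in tissue ", es$tissue)
    return(res)
  }
  res |>
    dplyr::group_by(.data$grid_index) |>
    dplyr::slice_max(.data$lod, n = 3, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$grid_index, dplyr::desc(.data$lod))
}

#' Fit k-nearest-neighbour eQTL classifiers for one tissue
#'
#' One classifier per eQTL unit (a grid position with 1-3 selected
#' probes): the training set holds, for every sample with both an
#' expression assay and a non-missing observed eQTL genotype, its
#' expression values at the unit's probes and its observed genotype.
#' Prediction takes the k nearest training points by Euclidean distance
#' in the 1-3 dimensional probe space; if strictly more than
#' `vote_threshold * k` of them share one genotype, that genotype is
#' returned, else `NA`. When fewer than `k` training points exist, all
#' are used with the proportional vote rule (with a warning at fit
#' time).
#'
#' @param eqtl Tibble from [select_local_eqtl()].
#' @param es An `expr_set`.
#' @param obs_geno Character matrix samples x grid positions of observed
#'   (multipoint-called) genotypes, as from [call_genotype()].
#' @param k Neighbour count (default 40).
#' @param vote_threshold Fraction of neighbours that must strictly be
#'   exceeded by the winning vote (default 0.8).
#' @return A list of class `eqtl_classifiers`, one element per unit.
#' @export
fit_knn <- function(eqtl, es, obs_geno, k = 40, vote_threshold = 0.8) {
  stopifnot(vote_threshold > 0.5, vote_threshold <= 1)
  units <- split(eqtl, eqtl$grid_index)
  small <- FALSE
  cls <- lapply(units, function(u) {
    ids <- intersect(rownames(es$values), rownames(obs_geno))
    x <- es$values[ids, u$probe_id, drop = FALSE]
    g <- obs_geno[ids, u$grid_index[1]]
    ok <- stats::complete.cases(x) & !is.na(g)
    if (sum(ok) < k) small <<- TRUE
    list(grid_index = u$grid_index[1], chr = u$chr[1], pos = u$pos[1],
         probe_ids = u$probe_id, train_x = x[ok, , drop = FALSE],
         train_g = g[ok], k = k, vote_threshold = vote_threshold)
  })
  if (small)
    warning("some classifiers have fewer training samples than k; ",
            "using all training points with the proportional vote rule")
  structure(cls, class = "eqtl_classifiers")
}

# predict one classifier for a query expression matrix; queries whose id
# appears in the training set have their own record excluded
predict_unit <- function(unit, query_x, query_ids) {
  n <- nrow(query_x)
  out <- rep(NA_character_, n)
  complete <- stats::complete.cases(query_x)
  tx <- unit$train_x; tg <- unit$train_g
  train_ids <- rownames(tx)
  # squared Euclidean distances, queries x training
  d2 <- outer(rowSums(query_x^2), rowSums(tx^2), `+`) -
    2 * query_x %*% t(tx)
  for (i in which(complete)) {
    di <- d2[i, ]
    use <- if (query_ids[i] %in% train_ids) train_ids != query_ids[i]
           else rep(TRUE, length(di))
    di <- di[use]; gi <- tg[use]
    k_used <- min(unit$k, length(di))
    if (k_used == 0) next
    nb <- gi[order(di)[seq_len(k_used)]]
    tab <- table(nb)
    if (max(tab) > unit$vote_threshold * k_used)
      out[i] <- names(tab)[which.max(tab)]
  }
  out
}

#' Infer eQTL genotypes for every mRNA sample
#'
#' Applies the fitted classifiers to the expression data: for each
#' sample and each eQTL unit, the inferred genotype, or `NA` when the
#' vote is not decisive, the sample's expression is missing at the
#' unit's probes, or the sample lies at a cluster boundary. A sample
#' present in a classifier's training set is predicted with its own
#' record excluded from the neighbour set.
#'
#' @param classifiers An `eqtl_classifiers` list.
#' @param es The `expr_set` to predict for.
#' @return Character matrix samples x eQTL units (named by grid index).
#' @export
infer_eqtl_genotypes <- function(classifiers, es) {
  ids <- rownames(es$values)
  out <- matrix(NA_character_, length(ids), length(classifiers),
                dimnames = list(ids, vapply(classifiers,
                  function(u) as.character(u$grid_index), character(1))))
  for (j in seq_along(classifiers)) {
    u <- classifiers[[j]]
    have <- intersect(u$probe_ids, colnames(es$values))
    if (length(have) < length(u$probe_ids)) next
    out[, j] <- predict_unit(u, es$values[, u$probe_ids, drop = FALSE], ids)
  }
  out
}

#' Proportion of matching genotypes
#'
#' `matches / comparable`, where comparable positions have both entries
#' non-missing; `NA` when no position is comparable.
#'
#' @param observed,inferred Equal-length genotype vectors.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
match_proportion <- function(observed, inferred) {
  stopifnot(length(observed) == length(inferred))
  ok <- !is.na(observed) & !is.na(inferred)
  if (!any(ok)) return(NA_real_)
  mean(observed[ok] == inferred[ok])
}

#' Filter badly matching samples and refit the classifiers
#'
#' Computes, per sample, the proportion of matches between its own
#' observed and inferred eQTL genotypes; samples below `min_match` are
#' removed from the training data and the classifiers refitted (one
#' filter pass, two fits in total).
#'
#' @param classifiers An `eqtl_classifiers` list (first pass).
#' @param eqtl Tibble from [select_local_eqtl()].
#' @param es The tissue's `expr_set`.
#' @param obs_geno Observed genotype matrix (samples x grid positions).
#' @param inferred Inferred genotype matrix from
#'   [infer_eqtl_genotypes()].
#' @param min_match Match proportion below which a sample is dropped
#'   from training (default 0.7).
#' @return List: `classifiers` (refitted), `match` (tibble with
#'   `sample_id`, `proportion`, `kept`).
#' @export
refit_after_filter <- function(classifiers, eqtl, es, obs_geno, inferred,
                               min_match = 0.7) {
  grid_cols <- colnames(inferred)
  ids <- intersect(rownames(inferred), rownames(obs_geno))
  props <- vapply(ids, function(i)
    match_proportion(obs_geno[i, as.integer(grid_cols)], inferred[i, ]),
    numeric(1))
  kept <- is.na(props) | props >= min_match
  if (mean(!kept) > 0.5)
    warning("more than half of the samples fall below the match filter; ",
            "suspect global mislabeling")
  drop_ids <- ids[!kept]
  refit <- fit_knn(eqtl, subset_expr(es, setdiff(rownames(es$values), drop_ids)),
                   obs_geno_drop(obs_geno, drop_ids),
                   k = classifiers[[1]]$k,
                   vote_threshold = classifiers[[1]]$vote_threshold)
  list(classifiers = refit,
       match = tibble(sample_id = ids, proportion = unname(props),
                      kept = unname(kept)))
}

subset_expr <- function(es, ids) {
  expr_set(es$tissue, es$values[intersect(rownames(es$values), ids), ,
                                drop = FALSE], es$probes)
}

obs_geno_drop <- function(obs_geno, drop_ids) {
  obs_geno[setdiff(rownames(obs_geno), drop_ids), , drop = FALSE]
}

#' DNA-mRNA similarity matrices
#'
#' Per tissue, cell (DNA i, mRNA j) is the proportion of matches between
#' the observed eQTL genotypes of DNA sample i and the inferred eQTL
#' genotypes of mRNA sample j over that tissue's eQTL. The combined
#' matrix pools matches and comparisons across tissues (overall
#' proportion, not a mean of per-tissue proportions). A DNA sample with
#' no expression assay anywhere has a missing column.
#'
#' @param obs_geno Observed genotype matrix (DNA samples x grid
#'   positions).
#' @param inferred_list Named list (per tissue) of inferred genotype
#'   matrices from [infer_eqtl_genotypes()].
#' @return List: `per_tissue` (named list of `similarity_matrix`),
#'   `combined` (`similarity_matrix`).
#' @export
dna_mrna_similarity <- function(obs_geno, inferred_list) {
  stopifnot(length(inferred_list) >= 1)
  dna_ids <- rownames(obs_geno)
  mrna_ids <- sort(unique(unlist(lapply(inferred_list, rownames))))
  tot_match <- matrix(0, length(dna_ids), length(mrna_ids),
                      dimnames = list(dna_ids, mrna_ids))
  tot_comp <- tot_match
  per_tissue <- list()
  for (tis in names(inferred_list)) {
    inf <- inferred_list[[tis]]
    gcols <- as.integer(colnames(inf))
    obs <- obs_geno[, gcols, drop = FALSE]
    m <- matrix(0, length(dna_ids), nrow(inf))
    cmp <- matrix(0, length(dna_ids), nrow(inf))
    for (g in GENO_CODES) {
      io <- (!is.na(obs) & obs == g) * 1
      ii <- (!is.na(inf) & inf == g) * 1
      m <- m + io %*% t(ii)
    }
    cmp <- (!is.na(obs)) %*% t(!is.na(inf)) * 1
    sim <- ifelse(cmp > 0, m / cmp, NA_real_)
    dimnames(sim) <- list(dna_ids, rownames(inf))
    per_tissue[[tis]] <- similarity_matrix(sim, "match_proportion")
    jj <- match(rownames(inf), mrna_ids)
    tot_match[, jj] <- tot_match[, jj] + m
    tot_comp[, jj] <- tot_comp[, jj] + cmp
  }
  comb <- ifelse(tot_comp > 0, tot_match / tot_comp, NA_real_)
  dimnames(comb) <- list(dna_ids, mrna_ids)
  list(per_tissue = per_tissue,
       combined = similarity_matrix(comb, "match_proportion"))
}

#' Diagnose DNA sample mix-ups
#'
#' Applies the similarity-matrix decision rule of
#' [diagnose_similarity()] to the combined DNA-mRNA match-proportion
#' matrix, with thresholds on the match-proportion scale. Two DNA rows
#' sharing the same best-matching mRNA label (one of them the label's
#' own row) are reported as duplicates.
#'
#' @param combined A `similarity_matrix` of match proportions.
#' @param self_threshold,match_threshold,margin Decision thresholds
#'   (defaults 0.8, 0.8, 0.1).
#' @return A `mixup_diagnosis`.
#' @export
diagnose_dna <- function(combined, self_threshold = 0.8,
                         match_threshold = 0.8, margin = 0.1) {
  diagnose_similarity(combined, self_threshold = self_threshold,
                      match_threshold = match_threshold, margin = margin)
}

#' Align DNA samples to mRNA samples
#'
#' Full genotype-side pass for a study: multipoint genotype
#' probabilities and observed eQTL genotype calls, per-tissue selection
#' of strong local eQTL, two classifier passes (fit, filter samples with
#' match proportion below `min_match`, refit), per-tissue and combined
#' DNA-mRNA similarity, and the DNA diagnosis.
#'
#' @param genotypes A `genotype_table`.
#' @param map The `genetic_map`.
#' @param expr_sets Named list of (already corrected) `expr_set`s.
#' @param lod_threshold eQTL selection LOD (default 100).
#' @param k,vote_threshold k-NN parameters (defaults 40, 0.8).
#' @param min_match Training filter (default 0.7).
#' @param call_threshold Multipoint call threshold (default 0.99).
#' @param epsilon,map_function,max_spacing HMM / grid settings.
#' @param self_threshold,match_threshold,margin Diagnosis thresholds on
#'   the match-proportion scale (defaults 0.8, 0.8, 0.1).
#' @param use_sex_covariate Use recorded sex as an interactive covariate
#'   in the eQTL-selection LOD (default `TRUE`).
#' @return A list of class `geno_alignment`: `eqtl` (per tissue),
#'   `classifiers`, `match_filter`, `similarity` (per-tissue +
#'   combined), `diagnosis`, `obs_geno`, `prob`.
#' @export
align_genotypes <- function(genotypes, map, expr_sets, lod_threshold = 100,
                            k = 40, vote_threshold = 0.8, min_match = 0.7,
                            call_threshold = 0.99, epsilon = 0.002,
                            map_function = "carter_falconer",
                            max_spacing = 0.5, self_threshold = 0.8,
                            match_threshold = 0.8, margin = 0.1,
                            use_sex_covariate = TRUE) {
  grid <- build_grid(map, max_spacing)
  prob <- calc_genoprob(genotypes, map, grid, epsilon = epsilon,
                        map_function = map_function)
  obs_geno <- call_genotype(prob, threshold = call_threshold)
  sex <- if (use_sex_covariate) genotypes$sex else NULL

  eqtl <- list(); classifiers <- list(); match_filter <- list()
  inferred <- list()
  for (tis in names(expr_sets)) {
    es <- expr_sets[[tis]]
    sel <- select_local_eqtl(es, prob, lod_threshold = lod_threshold,
                             sex = sex)
    eqtl[[tis]] <- sel
    if (nrow(sel) == 0) next
    cls1 <- fit_knn(sel, es, obs_geno, k = k, vote_threshold = vote_threshold)
    inf1 <- infer_eqtl_genotypes(cls1, es)
    rf <- refit_after_filter(cls1, sel, es, obs_geno, inf1,
                             min_match = min_match)
    classifiers[[tis]] <- rf$classifiers
    match_filter[[tis]] <- rf$match
    inferred[[tis]] <- infer_eqtl_genotypes(rf$classifiers, es)
  }
  if (length(inferred) == 0) stop("no tissue yielded any eQTL classifier")
  sim <- dna_mrna_similarity(obs_geno, inferred)
  diagnosis <- diagnose_dna(sim$combined, self_threshold = self_threshold,
                            match_threshold = match_threshold,
                            margin = margin)
  structure(list(eqtl = eqtl, classifiers = classifiers,
                 match_filter = match_filter, similarity = sim,
                 diagnosis = diagnosis, obs_geno = obs_geno, prob = prob),
            class = "geno_alignment")
}

#' Apply DNA-side corrections to the genotype table
#'
#' `relabel` rows are renamed to their inferred labels (the row's
#' recorded sex becomes that of the new label, since sex is sample
#' metadata attached to the label); `duplicate` rows are dropped (their
#' content already exists under the correct label); `unfixable` and
#' `unverifiable` rows are kept and flagged.
#'
#' @param genotypes A `genotype_table`.
#' @param diagnosis A `mixup_diagnosis` over the DNA rows.
#' @return List: `genotypes` (corrected), `flags` (tibble of kept but
#'   unconfirmed rows), `changes` (tibble log).
#' @export
apply_genotype_corrections <- function(genotypes, diagnosis) {
  calls <- genotypes$calls
  sex_lookup <- genotypes$sex
  rel <- diagnosis[diagnosis$status == "relabel", ]
  if (anyDuplicated(rel$inferred_label))
    stop("conflicting DNA relabels: multiple rows claim ",
         paste(unique(rel$inferred_label[duplicated(rel$inferred_label)]),
               collapse = ", "))
  dup <- diagnosis[diagnosis$status == "duplicate", ]
  # a row kept as unfixable/unverifiable whose label is claimed by a
  # relabel holds unidentified DNA; it is dropped so the relabel can land
  unknown <- diagnosis$label[diagnosis$status %in%
                               c("unfixable", "unverifiable")]
  displaced <- intersect(unknown, rel$inferred_label)
  keep <- !rownames(calls) %in% c(dup$label, displaced)
  calls <- calls[keep, , drop = FALSE]
  rn <- rownames(calls)
  for (kk in seq_len(nrow(rel)))
    rn[rownames(calls) == rel$label[kk]] <- rel$inferred_label[kk]
  if (anyDuplicated(rn))
    stop("DNA relabeling produced duplicate labels: ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "))
  rownames(calls) <- rn
  new_sex <- ifelse(rn %in% names(sex_lookup), sex_lookup[rn], "unknown")
  corrected <- genotype_table(calls, new_sex)
  changes <- dplyr::bind_rows(
    if (nrow(rel)) tibble(label = rel$label, action = "relabel",
                          new_label = rel$inferred_label),
    if (nrow(dup)) tibble(label = dup$label, action = "drop_duplicate",
                          new_label = dup$argmax_label),
    if (length(displaced)) tibble(label = displaced,
                                  action = "drop_unidentified",
                                  new_label = NA_character_))
  if (is.null(changes))
    changes <- tibble(label = character(), action = character(),
                      new_label = character())
  flags <- diagnosis[diagnosis$status %in% c("unfixable", "unverifiable"),
                     c("label", "status")]
  list(genotypes = corrected, flags = as_tibble(flags), changes = changes)
}
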