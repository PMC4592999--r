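# Alignment of expression arrays across tissues: probe selection by
# between-tissue correlation, sample-by-sample similarity matrices,
# median summaries, mix-up diagnosis and correction, within-tissue
# duplicate detection.

#' Select probes with high between-tissue correlation
#'
#' For each probe present in both tissues, computes the correlation of
#' its expression across the samples assayed in both tissues (omitting
#' samples with a missing value in either tissue) and keeps probes with
#' correlation strictly above `threshold`. Probes constant in either
#' tissue (correlation undefined) are excluded.
#'
#' @param es,et `expr_set`s for the two tissues.
#' @param threshold Correlation that must be exceeded (default 0.75).
#' @param method Correlation estimator (default Pearson).
#' @return A tibble of class `tissue_pair_probes` with columns
#'   `probe_id`, `correlation`; attributes `tissues` and `threshold`.
#' @export
select_corr_probes <- function(es, et, threshold = 0.75,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common_samples <- intersect(rownames(es$values), rownames(et$values))
  if (length(common_samples) < 3)
    stop("need at least 3 samples assayed in both tissues (have ",
         length(common_samples), ")")
  common_probes <- intersect(colnames(es$values), colnames(et$values))
  xs <- es$values[common_samples, common_probes, drop = FALSE]
  xt <- et$values[common_samples, common_probes, drop = FALSE]
  r <- vapply(seq_along(common_probes), function(j) {
    ok <- !is.na(xs[, j]) & !is.na(xt[, j])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(xs[ok, j], xt[ok, j], method = method))
  }, numeric(1))
  keep <- !is.na(r) & r > threshold
  out <- tibble(probe_id = common_probes[keep], correlation = r[keep])
  structure(out, class = c("tissue_pair_probes", class(tibble())),
            tissues = c(es$tissue, et$tissue), threshold = threshold)
}

#' Between-tissue sample similarity matrix
#'
#' Cell (i, j) is the correlation, across the selected probes, between
#' sample i's expression in the first tissue and sample j's expression in
#' the second tissue. Rows cover samples assayed in the first tissue,
#' columns samples assayed in the second; a sample with fewer than 3
#' non-missing selected-probe values yields missing cells.
#'
#' @param es,et `expr_set`s for the two tissues.
#' @param probes A `tissue_pair_probes` selection (or character vector of
#'   probe ids).
#' @param min_probes Minimum number of selected probes required
#'   (default 20).
#' @param method Correlation estimator.
#' @return A `similarity_matrix` (correlation kind).
#' @export
pair_similarity <- function(es, et, probes, min_probes = 20,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- if (is.character(probes)) probes else probes$probe_id
  ids <- intersect(ids, intersect(colnames(es$values), colnames(et$values)))
  if (length(ids) < min_probes)
    stop("only ", length(ids), " selected probes (< ", min_probes,
         "); lower the correlation threshold or min_probes")
  xs <- t(es$values[, ids, drop = FALSE])
  xt <- t(et$values[, ids, drop = FALSE])
  r <- suppressWarnings(cor(xs, xt, use = "pairwise.complete.obs",
                            method = method))
  counts <- crossprod(!is.na(xs), !is.na(xt))
  r[counts < 3] <- NA_real_
  similarity_matrix(r, "correlation")
}

#' Median similarity across the tissue pairs involving one tissue
#'
#' Summarizes, for a target tissue, the similarity between its sample i
#' and sample j elsewhere by the median of the pairwise similarities over
#' the available tissue pairs that include the target tissue. Cells with
#' no available pair are missing.
#'
#' @param pair_sims List of `similarity_matrix` objects whose rows are
#'   samples of the target tissue.
#' @return A `similarity_matrix` over the union of row/column labels.
#' @export
tissue_similarity <- function(pair_sims) {
  stopifnot(length(pair_sims) >= 1)
  rows <- sort(unique(unlist(lapply(pair_sims, rownames))))
  cols <- sort(unique(unlist(lapply(pair_sims, colnames))))
  stack <- array(NA_real_, c(length(rows), length(cols), length(pair_sims)))
  for (k in seq_along(pair_sims)) {
    m <- pair_sims[[k]]
    stack[match(rownames(m), rows), match(colnames(m), cols), k] <- m
  }
  med <- apply(stack, 1:2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else median(v)
  })
  dimnames(med) <- list(rows, cols)
  similarity_matrix(med, attr(pair_sims[[1]], "score_kind"))
}

#' Diagnose sample mix-ups from a similarity matrix
#'
#' Applies the row-wise decision rule: a row is `correct` when its self
#' similarity (the cell whose column label equals the row label) is the
#' row maximum, or is at least `self_threshold` (a slightly larger
#' off-diagonal value is treated as noise). A row with small self
#' similarity is `relabel`ed to the argmax column when the maximum
#' exceeds `match_threshold` and clears the second-highest value by more
#' than `margin`; otherwise it is `unfixable`. A row with no self cell is
#' `relabel`ed on the same confident-match rule, else `unverifiable`.
#' Finally, a relabel whose target label belongs to a row that is itself
#' `correct` is marked `duplicate` (two rows carrying the same underlying
#' sample).
#'
#' @param sim A `similarity_matrix`.
#' @param self_threshold Self similarity below which a row is suspect.
#' @param match_threshold Row maximum that must be exceeded to relabel.
#' @param margin Required gap between the maximum and the second-highest
#'   value.
#' @return A `mixup_diagnosis` tibble, one row per matrix row.
#' @export
diagnose_similarity <- function(sim, self_threshold = 0.75,
                                match_threshold = 0.8, margin = 0.1) {
  rows <- rownames(sim); cols <- colnames(sim)
  res <- purrr::map_dfr(seq_along(rows), function(i) {
    v <- sim[i, ]
    self <- if (rows[i] %in% cols) unname(v[rows[i]]) else NA_real_
    v_known <- v[!is.na(v)]
    if (length(v_known) == 0)
      return(tibble(label = rows[i], status = "unverifiable",
                    inferred_label = NA_character_, self = self,
                    max_score = NA_real_, argmax_label = NA_character_,
                    second = NA_real_))
    ord <- order(v_known, decreasing = TRUE)
    mx <- v_known[ord[1]]; amx <- names(v_known)[ord[1]]
    second <- if (length(ord) > 1) v_known[ord[2]] else NA_real_
    ev <- tibble(label = rows[i], inferred_label = NA_character_,
                 self = self, max_score = unname(mx), argmax_label = amx,
                 second = unname(second))
    confident <- mx > match_threshold &&
      (is.na(second) || mx - second > margin)
    status <-
      if (is.na(self)) {
        if (confident && amx != rows[i]) "relabel" else "unverifiable"
      } else if (amx == rows[i] || self >= self_threshold) {
        "correct"
      } else if (confident) "relabel" else "unfixable"
    ev$inferred_label <- if (status == "relabel") amx else NA_character_
    dplyr::bind_cols(tibble(status = status), ev)[, c("label", "status",
      "inferred_label", "self", "max_score", "argmax_label", "second")]
  })
  # duplicate detection: a relabel pointing at a label whose own row is
  # correct means two rows carry the same sample
  correct_labels <- res$label[res$status == "correct"]
  dup <- res$status == "relabel" & res$inferred_label %in% correct_labels
  res$status[dup] <- "duplicate"
  new_diagnosis(res, score_kind = attr(sim, "score_kind"))
}

#' Within-tissue duplicate arrays
#'
#' Computes between-sample correlations within one tissue across the
#' chosen probe subset and reports sample pairs (i != j) whose
#' correlation exceeds `dup_threshold`.
#'
#' @param es An `expr_set`.
#' @param probes Character vector of probe ids (the union of the
#'   selected cross-tissue probes for this tissue).
#' @param dup_threshold Correlation that must be exceeded (default 0.9).
#' @return Tibble with columns `sample_1`, `sample_2`, `correlation`.
#' @export
find_within_tissue_duplicates <- function(es, probes, dup_threshold = 0.9) {
  ids <- intersect(probes, colnames(es$values))
  if (length(ids) < 3) stop("need at least 3 probes")
  x <- t(es$values[, ids, drop = FALSE])
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[lower.tri(r, diag = TRUE)] <- NA_real_
  hits <- which(!is.na(r) & r > dup_threshold, arr.ind = TRUE)
  tibble(sample_1 = rownames(r)[hits[, 1]],
         sample_2 = colnames(r)[hits[, 2]],
         correlation = r[hits]) |>
    dplyr::arrange(dplyr::desc(.data$correlation))
}

#' Align expression arrays across tissues
#'
#' Full expression-side pass: selects the correlated probe subset for
#' every tissue pair, forms all pairwise sample-similarity matrices, the
#' per-tissue median summaries, per-tissue mix-up diagnoses, and
#' within-tissue duplicate lists.
#'
#' A sample is called mislabeled in tissue t only when its
#' self-similarity falls below `self_threshold` in every available
#' tissue pair involving t: with few tissues the median over pairs is
#' dominated by a fault in any single other tissue, and requiring all
#' pairs to agree localizes the fault to the tissue actually carrying
#' it. The replacement label is then inferred from the median-similarity
#' row with the confident-match rule of [diagnose_similarity()].
#'
#' @param expr_sets Named list of `expr_set`s (one per tissue).
#' @param corr_threshold Probe selection threshold (default 0.75).
#' @param min_probes Minimum probes per tissue pair (default 20).
#' @param self_threshold,match_threshold,margin Decision thresholds
#'   (defaults 0.75, 0.8, 0.1 on the correlation scale).
#' @param dup_threshold Within-tissue duplicate threshold (default 0.9).
#' @param method Correlation estimator.
#' @return A list of class `expr_alignment`: `pair_probes` (per tissue
#'   pair), `pair_sims`, `tissue_sims`, `diagnoses` (per tissue),
#'   `duplicates` (per tissue).
#' @export
align_expression <- function(expr_sets, corr_threshold = 0.75,
                             min_probes = 20, self_threshold = 0.75,
                             match_threshold = 0.8, margin = 0.1,
                             dup_threshold = 0.9,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  tissues <- names(expr_sets)
  stopifnot(length(tissues) >= 2, !is.null(tissues))
  pairs <- utils::combn(tissues, 2, simplify = FALSE)
  pair_key <- function(s, t) paste(s, t, sep = ":")

  pair_probes <- list(); pair_sims <- list()
  for (pr in pairs) {
    sel <- select_corr_probes(expr_sets[[pr[1]]], expr_sets[[pr[2]]],
                              threshold = corr_threshold, method = method)
    pair_probes[[pair_key(pr[1], pr[2])]] <- sel
    m <- pair_similarity(expr_sets[[pr[1]]], expr_sets[[pr[2]]], sel,
                         min_probes = min_probes, method = method)
    pair_sims[[pair_key(pr[1], pr[2])]] <- m
    pair_sims[[pair_key(pr[2], pr[1])]] <-
      similarity_matrix(t(m), "correlation")
  }

  tissue_sims <- list(); diagnoses <- list(); duplicates <- list()
  for (s in tissues) {
    sims_s <- pair_sims[paste(s, setdiff(tissues, s), sep = ":")]
    sims_s <- sims_s[!vapply(sims_s, is.null, logical(1))]
    med <- tissue_similarity(sims_s)
    tissue_sims[[s]] <- med
    diagnoses[[s]] <- diagnose_tissue(s, rownames(expr_sets[[s]]$values),
                                      sims_s, med, self_threshold,
                                      match_threshold, margin)
    probe_union <- unique(unlist(lapply(
      pair_probes[grepl(paste0("(^", s, ":)|(:", s, "$)"),
                        names(pair_probes))],
      function(p) p$probe_id)))
    duplicates[[s]] <- find_within_tissue_duplicates(expr_sets[[s]],
                                                     probe_union,
                                                     dup_threshold)
  }
  structure(list(pair_probes = pair_probes, pair_sims = pair_sims,
                 tissue_sims = tissue_sims, diagnoses = diagnoses,
                 duplicates = duplicates),
            class = "expr_alignment")
}

# per-tissue diagnosis requiring the self similarity to be low in every
# available tissue pair before declaring a mislabel (see align_expression)
diagnose_tissue <- function(tissue, samples, sims_s, med, self_threshold,
                            match_threshold, margin) {
  res <- purrr::map_dfr(samples, function(i) {
    selfs <- vapply(sims_s, function(m) {
      if (i %in% rownames(m) && i %in% colnames(m)) m[i, i] else NA_real_
    }, numeric(1))
    selfs <- selfs[!is.na(selfs)]
    v <- if (i %in% rownames(med)) med[i, ] else
      setNames(rep(NA_real_, ncol(med)), colnames(med))
    v_known <- v[!is.na(v)]
    self_med <- if (i %in% colnames(med) && i %in% rownames(med))
      unname(med[i, i]) else NA_real_
    if (length(v_known) == 0)
      return(tibble(label = i, status = "unverifiable",
                    inferred_label = NA_character_, self = self_med,
                    max_score = NA_real_, argmax_label = NA_character_,
                    second = NA_real_))
    ord <- order(v_known, decreasing = TRUE)
    mx <- unname(v_known[ord[1]]); amx <- names(v_known)[ord[1]]
    second <- if (length(ord) > 1) unname(v_known[ord[2]]) else NA_real_
    confident <- mx > match_threshold && (is.na(second) || mx - second > margin)
    status <-
      if (length(selfs) == 0) {
        if (confident && amx != i) "relabel" else "unverifiable"
      } else if (all(selfs < self_threshold)) {
        if (confident && amx != i) "relabel" else "unfixable"
      } else "correct"
    tibble(label = i, status = status,
           inferred_label = if (status == "relabel") amx else NA_character_,
           self = self_med, max_score = mx, argmax_label = amx,
           second = second)
  })
  correct_labels <- res$label[res$status == "correct"]
  dup <- res$status == "relabel" & res$inferred_label %in% correct_labels
  res$status[dup] <- "duplicate"
  new_diagnosis(res, score_kind = "correlation")
}

#' Apply expression-side corrections
#'
#' Applies per-tissue diagnoses to the expression sets: `relabel` rows
#' are renamed to their inferred labels (swaps and k-cycles supported),
#' `duplicate` rows are combined with the row already carrying the
#' target label by per-probe averaging, and `unfixable` rows are
#' dropped. Conflicting relabels (two rows claiming the same target
#' label) raise an error naming the conflict.
#'
#' @param expr_sets Named list of `expr_set`s.
#' @param diagnoses Named list of `mixup_diagnosis`, as from
#'   [align_expression()].
#' @param duplicate_policy `"combine"` (average, default) or `"drop"`
#'   (discard the duplicate row).
#' @return A list: `expr_sets` (corrected) and `changes` (tibble log with
#'   `tissue`, `label`, `action`, `new_label`).
#' @export
apply_expression_corrections <- function(expr_sets, diagnoses,
                                         duplicate_policy = c("combine", "drop")) {
  duplicate_policy <- match.arg(duplicate_policy)
  changes <- list()
  for (tis in names(expr_sets)) {
    d <- diagnoses[[tis]]
    if (is.null(d)) next
    es <- expr_sets[[tis]]
    vals <- es$values
    rel <- d[d$status == "relabel", ]
    if (anyDuplicated(rel$inferred_label)) {
      tgt <- unique(rel$inferred_label[duplicated(rel$inferred_label)])
      stop("conflicting relabels in tissue ", tis, ": multiple rows claim ",
           paste(tgt, collapse = ", "))
    }
    rn <- rownames(vals)
    for (k in seq_len(nrow(rel)))
      rn[rownames(vals) == rel$label[k]] <- rel$inferred_label[k]
    if (nrow(rel) > 0 && anyDuplicated(rn))
      stop("relabeling in tissue ", tis,
           " produced duplicate labels (conflict with unchanged rows): ",
           paste(unique(rn[duplicated(rn)]), collapse = ", "))
    rownames(vals) <- rn
    if (nrow(rel) > 0)
      changes[[length(changes) + 1]] <-
        tibble(tissue = tis, label = rel$label, action = "relabel",
               new_label = rel$inferred_label)

    dup <- d[d$status == "duplicate", ]
    for (k in seq_len(nrow(dup))) {
      src <- dup$argmax_label[k]
      if (duplicate_policy == "combine" && src %in% rownames(vals)) {
        vals[src, ] <- colMeans(vals[c(src, dup$label[k]), , drop = FALSE],
                                na.rm = TRUE)
      }
      vals <- vals[rownames(vals) != dup$label[k], , drop = FALSE]
      changes[[length(changes) + 1]] <-
        tibble(tissue = tis, label = dup$label[k],
               action = if (duplicate_policy == "combine") "combine" else "drop",
               new_label = src)
    }

    unfix <- d$label[d$status == "unfixable"]
    if (length(unfix) > 0) {
      vals <- vals[!rownames(vals) %in% unfix, , drop = FALSE]
      changes[[length(changes) + 1]] <-
        tibble(tissue = tis, label = unfix, action = "drop",
               new_label = NA_character_)
    }
    expr_sets[[tis]] <- expr_set(es$tissue, vals, es$probes)
  }
  list(expr_sets = expr_sets,
       changes = if (length(changes)) dplyr::bind_rows(changes)
                 else tibble(tissue = character(), label = character(),
                             action = character(), new_label = character()))
}

#' Heatmap of a similarity matrix
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("row", "col", "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "orange") +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(object, "score_kind")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Self-similarity versus best off-diagonal similarity
#'
#' Scatter plot of each row's self similarity against the largest
#' similarity in its row, colored by diagnosis status — the package's
#' standard diagnostic display for spotting mix-ups.
#'
#' @param object A `mixup_diagnosis`.
#' @param ... Unused.
#' @export
autoplot.mixup_diagnosis <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$self, y = .data$max_score,
                               colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "self similarity", y = "maximum similarity in row") +
    ggplot2::theme_minimal()
}
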