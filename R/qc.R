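# Genotype-level quality control: duplicate DNA samples, sex versus
# X-chromosome concordance, per-sample QC metrics, and classification of
# inferred DNA mislabelings by 96-well plate geometry.

#' Find duplicate DNA samples
#'
#' Reports unordered sample pairs whose proportion of identical calls,
#' across jointly non-missing markers, strictly exceeds
#' `identity_threshold`. Pairs with fewer than `min_typed` jointly typed
#' markers are excluded (with a warning when any such pair occurs).
#'
#' @param genotypes A `genotype_table`.
#' @param identity_threshold Identity proportion that must be exceeded
#'   (default 0.98).
#' @param min_typed Minimum jointly typed markers per pair (default 50).
#' @return Tibble with `sample_1`, `sample_2`, `identity`, `n_typed`.
#' @export
find_duplicate_dna <- function(genotypes, identity_threshold = 0.98,
                               min_typed = 50) {
  calls <- genotypes$calls
  stopifnot(nrow(calls) >= 2)
  m <- matrix(0, nrow(calls), nrow(calls))
  for (g in GENO_CODES) {
    ind <- (!is.na(calls) & calls == g) * 1
    m <- m + tcrossprod(ind)
  }
  cmp <- tcrossprod((!is.na(calls)) * 1)
  idn <- ifelse(cmp > 0, m / cmp, NA_real_)
  idn[lower.tri(idn, diag = TRUE)] <- NA_real_
  thin <- !is.na(idn) & cmp < min_typed & idn > identity_threshold
  if (any(thin))
    warning(sum(thin), " high-identity pair(s) excluded with < ", min_typed,
            " jointly typed markers")
  hits <- which(!is.na(idn) & idn > identity_threshold & cmp >= min_typed,
                arr.ind = TRUE)
  tibble(sample_1 = rownames(calls)[hits[, 1]],
         sample_2 = rownames(calls)[hits[, 2]],
         identity = idn[hits], n_typed = cmp[hits]) |>
    dplyr::arrange(dplyr::desc(.data$identity))
}

#' Sex versus X-chromosome concordance
#'
#' In an F2 from a (strain R female x strain B male)-derived F1
#' intercross, females should be RR or BR on the X and males hemizygous
#' B or R (recorded as the homozygous code). The discordant count is the
#' number of BB calls on the X for recorded females, and of BR calls for
#' recorded males. A sample is flagged sex-discordant when the count
#' reaches `min_discordant`; a single discordant call is reported as a
#' probable genotyping error. Samples of unknown sex are skipped and
#' listed.
#'
#' @param genotypes A `genotype_table` with columns matching `map`.
#' @param map The `genetic_map` (needs at least one X-linked marker).
#' @param min_discordant Count at which a sample is flagged (default 2).
#' @return Tibble with `sample_id`, `sex`, `n_x_typed`, `n_discordant`,
#'   `flag` (`"sex_discordant"`, `"probable_genotyping_error"`,
#'   `"unknown_sex"` or `"ok"`).
#' @export
check_sex_vs_x <- function(genotypes, map, min_discordant = 2) {
  x_markers <- map$marker[map$is_x]
  if (length(x_markers) == 0) stop("map has no X-linked markers")
  xc <- genotypes$calls[, x_markers, drop = FALSE]
  purrr::map_dfr(seq_len(nrow(xc)), function(i) {
    sx <- unname(genotypes$sex[i])
    typed <- !is.na(xc[i, ])
    n_disc <- if (sx == "female") sum(xc[i, typed] == "BB")
              else if (sx == "male") sum(xc[i, typed] == "BR")
              else NA_integer_
    flag <- if (sx == "unknown") "unknown_sex"
            else if (n_disc >= min_discordant) "sex_discordant"
            else if (n_disc >= 1) "probable_genotyping_error"
            else "ok"
    tibble(sample_id = rownames(xc)[i], sex = sx,
           n_x_typed = sum(typed), n_discordant = n_disc, flag = flag)
  })
}

#' Per-sample genotype quality metrics
#'
#' Computes, per sample: the missing-call rate over all markers, the
#' proportion of homozygous calls among non-missing autosomal calls, and
#' the inferred crossover count — the sum over adjacent autosomal grid
#' positions of the absolute allele-dose difference along the maximal
#' posterior genotype path (a BB to RR change counts two crossovers).
#' Each metric is flagged when it exceeds median + `k_mad` * MAD across
#' samples.
#'
#' @param genotypes A `genotype_table`.
#' @param prob A `geno_prob` array for the same samples.
#' @param map The `genetic_map`.
#' @param k_mad Robust flag multiplier (default 5).
#' @return Tibble of class `qc_report` with per-sample metrics and
#'   logical flag columns.
#' @export
genotype_qc <- function(genotypes, prob, map, k_mad = 5) {
  calls <- genotypes$calls
  auto_markers <- map$marker[!map$is_x]
  ac <- calls[, auto_markers, drop = FALSE]
  missing_rate <- rowMeans(is.na(calls))
  n_auto <- rowSums(!is.na(ac))
  prop_hom <- rowSums(ac == "BB" | ac == "RR", na.rm = TRUE) / pmax(n_auto, 1)

  grid <- attr(prob, "grid")
  dose <- apply(prob, 1:2, which.max)  # 1,2,3 -> dose 0,1,2 offset by 1
  xo <- numeric(nrow(calls))
  for (ch in unique(grid$chr)) {
    cols <- which(grid$chr == ch)
    if (length(cols) < 2) next
    dd <- abs(dose[, cols[-1], drop = FALSE] -
                dose[, cols[-length(cols)], drop = FALSE])
    xo <- xo + rowSums(dd)
  }
  robust_flag <- function(v) v > median(v) + k_mad * mad(v)
  out <- tibble(sample_id = rownames(calls),
                missing_rate = unname(missing_rate),
                prop_homozygous = unname(prop_hom),
                n_crossovers = unname(xo),
                flag_missing = robust_flag(missing_rate),
                flag_homozygosity = robust_flag(prop_hom),
                flag_crossovers = robust_flag(xo))
  out$flagged <- out$flag_missing | out$flag_homozygosity | out$flag_crossovers
  class(out) <- unique(c("qc_report", class(out)))
  out
}

#' Classify inferred DNA mislabelings by plate geometry
#'
#' For every relabeled or duplicate DNA row, computes the signed offset
#' in plate filling order between the well where the true sample should
#' have been and the well where it was found. `|offset| = 1` is an
#' off-by-one error, `|offset| = 2` off-by-two, any other same-plate
#' offset long-range, and a move between plates cross-plate. Maximal
#' runs of consecutive (in filling order) equal offsets are numbered in
#' `run_id` with their length in `run_length`.
#'
#' @param diagnosis A `mixup_diagnosis` over DNA rows (labels must
#'   appear in `layout`; rows missing from the layout are categorized
#'   `"unknown-layout"`).
#' @param layout A `plate_layout`.
#' @param fill_order `"column"` (default) or `"row"` major filling.
#' @return Tibble with per-error well coordinates, `offset`, `category`,
#'   `run_id`, `run_length`.
#' @export
classify_plate_errors <- function(diagnosis, layout,
                                  fill_order = c("column", "row")) {
  fill_order <- match.arg(fill_order)
  err <- diagnosis[diagnosis$status %in% c("relabel", "duplicate"), ]
  err$true_sample <- dplyr::coalesce(err$inferred_label, err$argmax_label)
  res <- purrr::map_dfr(seq_len(nrow(err)), function(k) {
    found <- layout[layout$sample_id == err$label[k], ]
    should <- layout[layout$sample_id == err$true_sample[k], ]
    if (nrow(found) == 0 || nrow(should) == 0)
      return(tibble(label = err$label[k], true_sample = err$true_sample[k],
                    plate_found = NA_character_, well_found = NA_character_,
                    plate_should = NA_character_, well_should = NA_character_,
                    offset = NA_integer_, category = "unknown-layout"))
    off <- well_index(found$well, fill_order) -
      well_index(should$well, fill_order)
    category <- if (found$plate != should$plate) "cross-plate"
                else if (abs(off) == 1) "off-by-one"
                else if (abs(off) == 2) "off-by-two"
                else "long-range"
    tibble(label = err$label[k], true_sample = err$true_sample[k],
           plate_found = found$plate, well_found = found$well,
           plate_should = should$plate, well_should = should$well,
           offset = if (category == "cross-plate") NA_integer_
                    else as.integer(off),
           category = category)
  })
  if (nrow(res) == 0)
    return(tibble(label = character(), true_sample = character(),
                  plate_found = character(), well_found = character(),
                  plate_should = character(), well_should = character(),
                  offset = integer(), category = character(),
                  run_id = integer(), run_length = integer()))
  # runs: consecutive filling-order wells on one plate with equal offset
  res$fill_idx <- ifelse(is.na(res$well_found), NA_integer_,
                         well_index(res$well_found, fill_order))
  res <- res[order(res$plate_found, res$fill_idx), ]
  run_id <- integer(nrow(res)); cur <- 0L
  for (k in seq_len(nrow(res))) {
    new_run <- k == 1 || is.na(res$offset[k]) || is.na(res$offset[k - 1]) ||
      res$offset[k] != res$offset[k - 1] ||
      !identical(res$plate_found[k], res$plate_found[k - 1]) ||
      is.na(res$fill_idx[k]) || is.na(res$fill_idx[k - 1]) ||
      res$fill_idx[k] != res$fill_idx[k - 1] + 1L
    if (new_run) cur <- cur + 1L
    run_id[k] <- cur
  }
  res$run_id <- run_id
  res <- res |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(run_length = dplyr::n()) |>
    dplyr::ungroup()
  res$fill_idx <- NULL
  res
}
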