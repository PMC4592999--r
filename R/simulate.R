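# Synthetic multi-tissue F2 eQTL study generator with a ground-truth
# ledger of planted sample mix-ups, so every detection stage can be
# exercised without external data.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_study()]. The default
#' scenario is a scaled-down multi-tissue F2 intercross: 300 mice, five
#' autosomes (100, 90, 80, 70, 60 cM; 20 markers each) plus an X
#' chromosome (50 cM, 10 markers), three tissues of 1000 probes each
#' with 60 large-effect local-eQTL probes (grouped 1-3 per position),
#' 120 latent-factor probes shared across tissues (cross-tissue
#' correlation about 0.9), an Xist-like and a Y-like sex probe, a 2%
#' genotype missing rate and a 0.2% genotyping error rate. Planted
#' errors default to: a DNA plate-shift run of 8 wells at offset +1
#' (whose head well duplicates its neighbour's DNA), one cross-plate DNA
#' swap, one expression swap per tissue, a three-way expression cycle in
#' the first tissue, one expression duplicate per tissue, and one
#' exchange of recorded sex between an eligible male/female pair (two
#' sex-discordant samples).
#'
#' @param n_mice Number of F2 mice.
#' @param chr_lengths Named numeric vector of autosome lengths (cM).
#' @param markers_per_chr Markers per autosome.
#' @param x_length,x_markers X chromosome length (cM) and marker count.
#' @param map_function Map function for meiosis simulation and the HMM.
#' @param epsilon Genotyping error rate.
#' @param missing_rate Genotype missing-call rate.
#' @param tissues Tissue names.
#' @param n_probes Probes per tissue.
#' @param n_eqtl Local-eQTL probes per tissue.
#' @param n_shared Latent-factor probes shared across tissues.
#' @param eqtl_additive,eqtl_dominance,eqtl_sd Additive and dominance
#'   effects and residual SD of the eQTL probes (defaults give a
#'   single-position LOD of roughly 140 at n = 300).
#' @param shared_loading Latent-factor loading; with residual SD
#'   `shared_sd`, the between-tissue probe correlation is
#'   `loading^2 / (loading^2 + shared_sd^2)` (0.9 by default).
#' @param shared_sd,noise_sd Residual SDs for shared and pure-noise
#'   probes.
#' @param sex_effect Mean shift of the Xist-like probe in females and
#'   the Y-like probe in males.
#' @param assayed Optional named list of sample indices assayed per
#'   tissue (default: all mice in all tissues).
#' @param errors List of planted-error descriptors; see
#'   [default_planted_errors()]. Use `list()` for a clean study.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mice = 300,
                       chr_lengths = c("1" = 100, "2" = 90, "3" = 80,
                                       "4" = 70, "5" = 60),
                       markers_per_chr = 20,
                       x_length = 50, x_markers = 10,
                       map_function = "carter_falconer",
                       epsilon = 0.002, missing_rate = 0.02,
                       tissues = c("adipose", "islet", "liver"),
                       n_probes = 1000, n_eqtl = 60, n_shared = 120,
                       eqtl_additive = 1.0, eqtl_dominance = 0.25,
                       eqtl_sd = 0.25, shared_loading = 0.75,
                       shared_sd = 0.25, noise_sd = 0.3,
                       sex_effect = 1.5, assayed = NULL,
                       errors = default_planted_errors(tissues),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  cfg <- list(n_mice = n_mice, chr_lengths = chr_lengths,
              markers_per_chr = markers_per_chr, x_length = x_length,
              x_markers = x_markers, map_function = map_function,
              epsilon = epsilon, missing_rate = missing_rate,
              tissues = tissues, n_probes = n_probes, n_eqtl = n_eqtl,
              n_shared = n_shared, eqtl_additive = eqtl_additive,
              eqtl_dominance = eqtl_dominance, eqtl_sd = eqtl_sd,
              shared_loading = shared_loading, shared_sd = shared_sd,
              noise_sd = noise_sd, sex_effect = sex_effect,
              assayed = assayed, errors = errors, seed = as.integer(seed))
  stopifnot(n_mice > 0, all(chr_lengths > 0), markers_per_chr >= 2,
            x_markers >= 2, epsilon >= 0, epsilon < 0.5,
            missing_rate >= 0, missing_rate < 1, length(tissues) >= 1,
            n_probes >= n_eqtl * length(tissues) + n_shared + 3,
            eqtl_sd > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted-error list for the standard scenario
#'
#' @param tissues Tissue names.
#' @return List of error descriptors understood by [plant_errors()]:
#'   `dna_plate_shift(start, length, offset)`, `dna_swap`, `expr_swap`,
#'   `expr_cycle`, `expr_duplicate`, `sex_swap`.
#' @export
default_planted_errors <- function(tissues = c("adipose", "islet", "liver")) {
  errs <- list(
    list(kind = "dna_plate_shift", start = 20L, length = 8L, offset = 1L),
    list(kind = "dna_swap", samples = c(150L, 230L))
  )
  for (i in seq_along(tissues))
    errs[[length(errs) + 1]] <-
      list(kind = "expr_swap", tissue = tissues[i],
           samples = c(40L + 10L * i, 45L + 10L * i))
  errs[[length(errs) + 1]] <-
    list(kind = "expr_cycle", tissue = tissues[1],
         samples = c(100L, 110L, 120L))
  for (i in seq_along(tissues))
    errs[[length(errs) + 1]] <-
      list(kind = "expr_duplicate", tissue = tissues[i],
           samples = c(250L + 10L * i, 255L + 10L * i))
  errs[[length(errs) + 1]] <- list(kind = "sex_swap")
  errs
}

# sample ids are zero-padded so lexicographic and numeric order agree
sim_sample_ids <- function(n) sprintf("Mouse%04d", seq_len(n))

#' Simulate the cross: genotypes, map, plate layout, truth ledger
#'
#' Autosomal gametes are simulated as first-order Markov chains over the
#' marker positions, with switch probability on each interval equal to
#' the inverse map function of the gap; genotypes are the sum of two
#' independent gametes. The X chromosome follows the cross design of a
#' (strain R female x strain B male)-derived F1 intercross: F2 females
#' carry a non-recombinant R paternal X plus a recombinant maternal X
#' (so are RR or BR), F2 males carry only the recombinant maternal X and
#' are stored with the homozygous code. Genotyping errors are applied
#' symmetrically at rate `epsilon` and calls are set missing at
#' `missing_rate`. Samples fill 96-well plates in column-major order.
#'
#' @param cfg A `sim_config`.
#' @return List: `genotypes` (`genotype_table`), `map` (`genetic_map`),
#'   `layout` (`plate_layout`), `ledger` (truth ledger; see
#'   [restore_truth()]).
#' @export
simulate_cross <- function(cfg) {
  set.seed(cfg$seed)
  ids <- sim_sample_ids(cfg$n_mice)
  sex <- ifelse(runif(cfg$n_mice) < 0.5, "female", "male")

  # map: evenly spaced markers per chromosome
  maps <- lapply(names(cfg$chr_lengths), function(ch) {
    pos <- seq(0, cfg$chr_lengths[[ch]], length.out = cfg$markers_per_chr)
    tibble(marker = sprintf("D%sM%02d", ch, seq_along(pos)), chr = ch,
           pos = pos)
  })
  xpos <- seq(0, cfg$x_length, length.out = cfg$x_markers)
  maps[[length(maps) + 1]] <- tibble(marker = sprintf("DXM%02d", seq_along(xpos)),
                                     chr = "X", pos = xpos)
  map_df <- dplyr::bind_rows(maps)
  map <- genetic_map(map_df$marker, map_df$chr, map_df$pos)

  # one recombinant gamete: allele chain over markers (1 = R allele)
  gamete <- function(n, r_gaps) {
    m <- length(r_gaps) + 1
    al <- matrix(0L, n, m)
    al[, 1] <- rbinom(n, 1, 0.5)
    for (j in seq_along(r_gaps)) {
      sw <- rbinom(n, 1, r_gaps[j])
      al[, j + 1] <- ifelse(sw == 1, 1L - al[, j], al[, j])
    }
    al
  }

  calls_true <- matrix(NA_character_, cfg$n_mice, nrow(map),
                       dimnames = list(ids, map$marker))
  for (ch in names(cfg$chr_lengths)) {
    mk <- which(map$chr == ch)
    r_gaps <- inverse_map_r(diff(map$pos[mk]), cfg$map_function)
    dose <- gamete(cfg$n_mice, r_gaps) + gamete(cfg$n_mice, r_gaps)
    calls_true[, mk] <- GENO_CODES[dose + 1L]
  }
  # X: maternal recombinant gamete; paternal X is non-recombinant R
  mkx <- which(map$chr == "X")
  r_gaps_x <- inverse_map_r(diff(map$pos[mkx]), cfg$map_function)
  mat_x <- gamete(cfg$n_mice, r_gaps_x)
  fem <- sex == "female"
  xdose <- matrix(NA_integer_, cfg$n_mice, length(mkx))
  xdose[fem, ] <- mat_x[fem, , drop = FALSE] + 1L          # R paternal + maternal
  xdose[!fem, ] <- 2L * mat_x[!fem, , drop = FALSE]        # hemizygous as homozygous
  calls_true[, mkx] <- GENO_CODES[xdose + 1L]

  # true crossover count at marker resolution (autosomes, dose metric)
  dose_true <- matrix(match(calls_true, GENO_CODES), nrow = cfg$n_mice) - 1L
  xo <- numeric(cfg$n_mice)
  for (ch in names(cfg$chr_lengths)) {
    mk <- which(map$chr == ch)
    xo <- xo + rowSums(abs(dose_true[, mk[-1], drop = FALSE] -
                             dose_true[, mk[-length(mk)], drop = FALSE]))
  }

  # genotyping errors: symmetric to one of the two other codes
  calls <- calls_true
  err <- matrix(runif(length(calls)) < cfg$epsilon, nrow(calls))
  if (any(err)) {
    idx <- which(err)
    cur <- match(calls[idx], GENO_CODES)
    shift <- sample(1:2, length(idx), replace = TRUE)
    calls[idx] <- GENO_CODES[(cur - 1L + shift) %% 3L + 1L]
  }
  miss <- matrix(runif(length(calls)) < cfg$missing_rate, nrow(calls))
  calls[miss] <- NA_character_

  # plate layout, column-major filling
  fill <- seq_len(cfg$n_mice)
  layout <- plate_layout(ids,
                         plate = sprintf("P%d", (fill - 1L) %/% 96L + 1L),
                         well = index_well((fill - 1L) %% 96L + 1L))

  ledger <- list(
    sample_ids = ids, sex_true = setNames(sex, ids),
    calls_true = calls_true, calls_clean = calls,
    crossovers_true = setNames(xo, ids),
    dna_truth = tibble(label = ids, true_sample = ids),
    expr_truth = list(), sex_recorded_truth = setNames(sex, ids),
    planted = tibble(kind = character(), tissue = character(),
                     label = character(), true_sample = character()),
    overwritten = list()
  )
  list(genotypes = genotype_table(calls, sex, map), map = map,
       layout = layout, ledger = ledger)
}

#' Simulate per-tissue expression data
#'
#' eQTL probes follow `y = a * dose + d * het + N(0, sd^2)` with the
#' mouse's true genotype at the probe's (marker) position, identically
#' across tissues; shared probes load on a per-mouse, per-probe latent
#' factor common to all tissues; an Xist-like X probe is elevated in
#' females and a Y-like probe in males; remaining probes are pure noise.
#' Some noise probes are left without genomic annotation.
#'
#' @param cfg A `sim_config`.
#' @param cross Result of [simulate_cross()].
#' @return List: `expr_sets` (named list of `expr_set`), `ledger`
#'   (updated, with `expr_truth` and `eqtl_truth`).
#' @export
simulate_expression <- function(cfg, cross) {
  set.seed(cfg$seed + 1L)
  map <- cross$map
  ids <- cross$ledger$sample_ids
  n <- length(ids)
  auto <- map[!map$is_x, ]

  # eQTL units per tissue: each tissue draws its own probe set and
  # positions (sampled from the autosomal markers; unit sizes 1-3), so
  # that pooling match proportions across tissues accumulates distinct
  # loci, as when each tissue contributes its own selected eQTL
  eqtl_truth <- dplyr::bind_rows(lapply(cfg$tissues, function(tis) {
    sizes <- integer(0)
    while (sum(sizes) < cfg$n_eqtl) {
      s <- sample(c(1L, 1L, 1L, 2L, 3L), 1)
      sizes <- c(sizes, min(s, cfg$n_eqtl - sum(sizes)))
    }
    pos_idx <- sample(nrow(auto), length(sizes))
    tibble(
      tissue = tis,
      probe_id = sprintf("eqtl_%s_%03d", tis, seq_len(cfg$n_eqtl)),
      chr = rep(auto$chr[pos_idx], sizes),
      pos = rep(auto$pos[pos_idx], sizes),
      marker = rep(auto$marker[pos_idx], sizes),
      additive = cfg$eqtl_additive, dominance = cfg$eqtl_dominance,
      sd = cfg$eqtl_sd)
  }))

  dose <- matrix(match(cross$ledger$calls_true[, eqtl_truth$marker],
                       GENO_CODES), nrow = n) - 1L
  colnames(dose) <- eqtl_truth$probe_id
  het <- (dose == 1L) * 1

  shared_ids <- sprintf("shared_%03d", seq_len(cfg$n_shared))
  latent <- matrix(rnorm(n * cfg$n_shared), n, cfg$n_shared)

  n_eqtl_total <- nrow(eqtl_truth)
  n_noise <- cfg$n_probes - n_eqtl_total - cfg$n_shared - 2L
  stopifnot(n_noise >= 1)
  noise_ids <- sprintf("noise_%03d", seq_len(n_noise))
  auto_chr <- unique(auto$chr)
  min_len <- min(cfg$chr_lengths)
  noise_chr <- sample(c(auto_chr, NA_character_), n_noise, replace = TRUE,
                      prob = c(rep(0.95 / length(auto_chr),
                                   length(auto_chr)), 0.05))
  noise_pos <- ifelse(is.na(noise_chr), NA_real_,
                      round(runif(n_noise, 0, min_len), 1))

  probes <- tibble(
    probe_id = c(eqtl_truth$probe_id, shared_ids, "xist_like", "y_like",
                 noise_ids),
    chr = c(eqtl_truth$chr, sample(auto$chr, cfg$n_shared, replace = TRUE),
            "X", "Y", noise_chr),
    pos = c(eqtl_truth$pos, round(runif(cfg$n_shared, 0, min_len), 1), 10,
            1, noise_pos))

  assayed <- cfg$assayed
  if (is.null(assayed))
    assayed <- setNames(rep(list(seq_len(n)), length(cfg$tissues)),
                        cfg$tissues)
  fem <- cross$ledger$sex_true[ids] == "female"

  expr_sets <- list()
  for (tis in cfg$tissues) {
    rows <- assayed[[tis]]
    vals <- matrix(NA_real_, length(rows), cfg$n_probes,
                   dimnames = list(ids[rows], probes$probe_id))
    own <- eqtl_truth$probe_id[eqtl_truth$tissue == tis]
    other <- setdiff(eqtl_truth$probe_id, own)
    vals[, own] <-
      cfg$eqtl_additive * dose[rows, own, drop = FALSE] +
      cfg$eqtl_dominance * het[rows, own, drop = FALSE] +
      matrix(rnorm(length(rows) * length(own), sd = cfg$eqtl_sd),
             length(rows))
    # probes carrying another tissue's eQTL are plain noise here
    vals[, other] <- matrix(rnorm(length(rows) * length(other),
                                  sd = cfg$noise_sd), length(rows))
    vals[, shared_ids] <-
      cfg$shared_loading * latent[rows, , drop = FALSE] +
      matrix(rnorm(length(rows) * cfg$n_shared, sd = cfg$shared_sd),
             length(rows))
    vals[, "xist_like"] <- cfg$sex_effect * fem[rows] +
      rnorm(length(rows), sd = cfg$shared_sd)
    vals[, "y_like"] <- cfg$sex_effect * (!fem[rows]) +
      rnorm(length(rows), sd = cfg$shared_sd)
    vals[, noise_ids] <- matrix(rnorm(length(rows) * n_noise,
                                      sd = cfg$noise_sd), length(rows))
    expr_sets[[tis]] <- expr_set(tis, vals, probes)
  }
  ledger <- cross$ledger
  ledger$eqtl_truth <- eqtl_truth
  ledger$expr_truth <- lapply(expr_sets, function(es)
    tibble(label = rownames(es$values), true_sample = rownames(es$values)))
  ledger$expr_clean <- lapply(expr_sets, function(es) es$values)
  list(expr_sets = expr_sets, ledger = ledger)
}

#' Plant sample mix-ups into a clean simulated study
#'
#' Applies each configured error and records the exact permutation in
#' the ledger. DNA plate shifts displace the DNA intended for
#' filling-order well `i` into well `i + offset` over the run, so the
#' run's head well carries a second copy of its upstream neighbour's DNA
#' (a duplicate pair) and the tail sample's DNA is lost. Swaps, cycles
#' and duplicates permute or copy rows within one data dimension; sex
#' swaps exchange the recorded sex of an eligible male/female pair
#' (eligible = detectable by X-chromosome concordance: the male shows at
#' least two B-hemizygous X calls, the female at least two heterozygous
#' X calls).
#'
#' @param cfg A `sim_config`.
#' @param cross Result of [simulate_cross()].
#' @param expr Result of [simulate_expression()].
#' @return List: `genotypes`, `expr_sets`, `layout`, `map`, `ledger`
#'   (final, with `planted` and per-dimension truth tables).
#' @export
plant_errors <- function(cfg, cross, expr) {
  set.seed(cfg$seed + 2L)
  genotypes <- cross$genotypes
  expr_sets <- expr$expr_sets
  ledger <- expr$ledger
  ids <- ledger$sample_ids
  calls <- genotypes$calls
  planted <- list()
  touched_dna <- character(0)

  for (e in cfg$errors) {
    if (e$kind == "dna_plate_shift") {
      run <- seq(e$start, e$start + e$length - 1L)
      src <- run - e$offset
      stopifnot(all(src >= 1), all(run <= length(ids)))
      if (length(intersect(ids[c(run, src)], touched_dna)) > 0)
        stop("planted DNA errors touch the same sample twice")
      new_calls <- calls
      new_calls[run, ] <- calls[src, ]  # labels keep their wells
      calls <- new_calls
      ledger$dna_truth$true_sample[run] <- ids[src]
      touched_dna <- c(touched_dna, ids[run])
      planted[[length(planted) + 1]] <-
        tibble(kind = "dna_plate_shift", tissue = NA_character_,
               label = ids[run], true_sample = ids[src])
    } else if (e$kind == "dna_swap") {
      s <- e$samples
      if (length(intersect(ids[s], touched_dna)) > 0)
        stop("planted DNA errors touch the same sample twice")
      calls[s, ] <- calls[rev(s), ]
      ledger$dna_truth$true_sample[s] <- ids[rev(s)]
      touched_dna <- c(touched_dna, ids[s])
      planted[[length(planted) + 1]] <-
        tibble(kind = "dna_swap", tissue = NA_character_, label = ids[s],
               true_sample = ids[rev(s)])
    } else if (e$kind %in% c("expr_swap", "expr_cycle")) {
      tis <- e$tissue; s <- e$samples
      vals <- expr_sets[[tis]]$values
      lab <- ids[s]
      stopifnot(all(lab %in% rownames(vals)))
      src <- c(lab[-1], lab[1])  # row labelled lab[k] receives src[k]'s data
      vals[lab, ] <- vals[src, ]
      expr_sets[[tis]] <- expr_set(tis, vals, expr_sets[[tis]]$probes)
      tt <- ledger$expr_truth[[tis]]
      tt$true_sample[match(lab, tt$label)] <- src
      ledger$expr_truth[[tis]] <- tt
      planted[[length(planted) + 1]] <-
        tibble(kind = e$kind, tissue = tis, label = lab, true_sample = src)
    } else if (e$kind == "expr_duplicate") {
      tis <- e$tissue; s <- e$samples  # slot s[1] <- copy of s[2]'s array
      vals <- expr_sets[[tis]]$values
      lab <- ids[s]
      ledger$overwritten[[paste0("expr:", tis, ":", lab[1])]] <-
        vals[lab[1], ]
      vals[lab[1], ] <- vals[lab[2], ]
      expr_sets[[tis]] <- expr_set(tis, vals, expr_sets[[tis]]$probes)
      tt <- ledger$expr_truth[[tis]]
      tt$true_sample[tt$label == lab[1]] <- lab[2]
      ledger$expr_truth[[tis]] <- tt
      planted[[length(planted) + 1]] <-
        tibble(kind = "expr_duplicate", tissue = tis, label = lab[1],
               true_sample = lab[2])
    } else if (e$kind == "sex_swap") {
      xmk <- which(grepl("^DXM", colnames(calls)))
      n_bb <- rowSums(calls[, xmk, drop = FALSE] == "BB", na.rm = TRUE)
      n_br <- rowSums(calls[, xmk, drop = FALSE] == "BR", na.rm = TRUE)
      sex <- genotypes$sex
      used <- unique(c(touched_dna,
                       unlist(lapply(planted, function(p) p$label))))
      male_ok <- which(sex == "male" & n_bb >= 2 & !(ids %in% used))
      female_ok <- which(sex == "female" & n_br >= 2 & !(ids %in% used))
      if (length(male_ok) == 0 || length(female_ok) == 0)
        stop("no eligible pair for a detectable sex swap")
      pick <- c(male_ok[1], female_ok[1])
      sex[pick] <- sex[rev(pick)]
      genotypes$sex <- sex
      ledger$sex_recorded_truth[ids[pick]] <- sex[rev(pick)]
      planted[[length(planted) + 1]] <-
        tibble(kind = "sex_swap", tissue = NA_character_,
               label = ids[pick], true_sample = ids[rev(pick)])
    } else stop("unknown planted error kind: ", e$kind)
  }

  genotypes <- genotype_table(calls, genotypes$sex)
  ledger$planted <- if (length(planted)) dplyr::bind_rows(planted)
                    else ledger$planted
  list(genotypes = genotypes, expr_sets = expr_sets, layout = cross$layout,
       map = cross$map, ledger = ledger)
}

#' Simulate a complete study
#'
#' Runs [simulate_cross()], [simulate_expression()] and
#' [plant_errors()] from one configuration (all randomness flows from
#' `cfg$seed`).
#'
#' @param cfg A `sim_config`.
#' @return List: `genotypes`, `map`, `layout`, `expr_sets`, `ledger`.
#' @export
simulate_study <- function(cfg) {
  cross <- simulate_cross(cfg)
  expr <- simulate_expression(cfg, cross)
  plant_errors(cfg, cross, expr)
}

#' Restore the clean data from a corrupted study via the truth ledger
#'
#' Inverts every planted permutation and reinstates rows overwritten by
#' duplicates; the result equals the pre-error data exactly.
#'
#' @param study Result of [simulate_study()] (or [plant_errors()]).
#' @return List: `genotypes` calls matrix, `expr` list of value
#'   matrices, `sex` recorded sex vector — all clean.
#' @export
restore_truth <- function(study) {
  ledger <- study$ledger
  ids <- ledger$sample_ids
  calls <- study$genotypes$calls
  clean_calls <- calls
  # DNA: row labelled L holds true_sample(L)'s clean row
  perm <- ledger$dna_truth
  clean_calls[perm$true_sample, ] <- calls[perm$label, ]
  # rows whose DNA was lost (never appearing as a true_sample) come from
  # the ledger's stored clean matrix
  lost <- setdiff(ids, perm$true_sample)
  clean_calls[lost, ] <- ledger$calls_clean[lost, ]

  sex <- study$genotypes$sex
  swaps <- ledger$planted[ledger$planted$kind == "sex_swap", ]
  sex[swaps$label] <- ledger$sex_true[swaps$label]

  expr <- list()
  for (tis in names(study$expr_sets)) {
    vals <- study$expr_sets[[tis]]$values
    clean <- vals
    tt <- ledger$expr_truth[[tis]]
    clean[tt$true_sample, ] <- vals[tt$label, ]
    lost <- setdiff(tt$label, tt$true_sample)
    for (l in lost) {
      key <- paste0("expr:", tis, ":", l)
      if (!is.null(ledger$overwritten[[key]]))
        clean[l, ] <- ledger$overwritten[[key]]
    }
    expr[[tis]] <- clean
  }
  list(genotypes = clean_calls, expr = expr, sex = sex)
}
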