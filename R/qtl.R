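# Haley-Knott regression LOD scores, normal-quantile transform,
# chromosome scans with 2-LOD support intervals and local/trans calls.

#' Normal-quantile transform
#'
#' Replaces the non-missing values of `y` by
#' `qnorm((rank - 0.5) / n)`, where ranks use average ties and `n` is the
#' number of non-missing values; missing values are preserved. The
#' transform is a monotone function of the ranks.
#'
#' @param y Numeric vector, missing allowed.
#' @return Transformed vector of the same length.
#' @export
normal_quantiles <- function(y) {
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y)
  n <- sum(ok)
  if (n == 0) return(out)
  r <- rank(y[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}

# residual sum of squares of y regressed on X, tolerant of rank
# deficiency (lm.fit pivots; collinear columns are dropped, which yields
# the same minimal RSS as a least-norm solution)
rss_fit <- function(y, X) {
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Haley-Knott regression LOD at a single position
#'
#' Regresses the phenotype on the conditional genotype probabilities at
#' one position: the alternative design is
#' `[1, p_BR, p_RR]` (+ covariates; + covariate x probability columns if
#' `interactive`), the null design `[1]` (+ covariates), and
#' `LOD = (n/2) * log10(RSS0 / RSS1)`. Samples with missing phenotype,
#' probability or covariate values are dropped. Rank-deficient designs
#' (e.g. a genotype class absent) are handled by pivoting and do not
#' fail.
#'
#' @param y Phenotype vector.
#' @param p n x 3 matrix of genotype probabilities (columns BB, BR, RR),
#'   rows aligned with `y`.
#' @param covariates Optional numeric matrix (or vector) of covariates.
#' @param interactive If `TRUE`, covariate-by-probability interaction
#'   columns are added to the alternative design (covariates with
#'   QTL-by-covariate interaction, e.g. sex).
#' @return The LOD score (>= 0 up to numerical error); `Inf` with a
#'   warning if the alternative fit is perfect.
#' @export
hk_lod <- function(y, p, covariates = NULL, interactive = FALSE) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  keep <- !is.na(y) & stats::complete.cases(p)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; p <- p[keep, , drop = FALSE]
  n <- length(y)
  X0 <- cbind(rep(1, n),
              if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  if (n < ncol(X0) + 2) stop("too few complete observations for the fit")
  X1 <- cbind(X0, p[, 2:3, drop = FALSE])
  if (interactive && !is.null(covariates)) {
    cv <- covariates[keep, , drop = FALSE]
    for (j in seq_len(ncol(cv))) X1 <- cbind(X1, cv[, j] * p[, 2:3, drop = FALSE])
  }
  rss0 <- rss_fit(y, X0)
  rss1 <- rss_fit(y, X1)
  if (rss0 <= n * .Machine$double.eps * max(1, sum(y^2)))
    return(0)  # null already fits perfectly (e.g. constant phenotype)
  if (rss1 <= 0) {
    warning("perfect fit under the alternative; LOD is infinite")
    return(Inf)
  }
  max(n / 2 * log10(rss0 / rss1), 0)
}

#' Genome scan on one chromosome with 2-LOD support interval
#'
#' Computes the Haley-Knott LOD at every grid position of a chromosome.
#' The peak is the position of maximal LOD (ties broken toward the lower
#' position); the 2-LOD support interval is the contiguous run of
#' positions around the peak with `LOD > peak - 2`, extended one grid
#' position outward on each side where possible.
#'
#' @param y Phenotype vector aligned with the rows of `prob` (use names
#'   to align, otherwise positional).
#' @param prob A `geno_prob` array.
#' @param chromosome Chromosome to scan.
#' @inheritParams hk_lod
#' @return A list of class `scan_result`: `lod` (tibble with `chr`,
#'   `pos`, `lod`) and `peak` (tibble with `chr`, `peak_pos`, `peak_lod`,
#'   `interval_lo`, `interval_hi`).
#' @export
scan_chromosome <- function(y, prob, chromosome, covariates = NULL,
                            interactive = FALSE) {
  grid <- attr(prob, "grid")
  cols <- which(grid$chr == chromosome)
  if (length(cols) == 0) stop("chromosome not in genotype probabilities: ", chromosome)
  lods <- vapply(cols, function(j)
    hk_lod(y, prob[, j, ], covariates = covariates, interactive = interactive),
    numeric(1))
  pk <- which.max(lods)  # first max = lower position on ties
  lo <- pk; hi <- pk
  while (lo > 1 && lods[lo - 1] > lods[pk] - 2) lo <- lo - 1
  while (hi < length(lods) && lods[hi + 1] > lods[pk] - 2) hi <- hi + 1
  lo <- max(1, lo - 1); hi <- min(length(lods), hi + 1)  # one position outward
  structure(list(
    lod = tibble(chr = chromosome, pos = grid$pos[cols], lod = lods),
    peak = tibble(chr = chromosome, peak_pos = grid$pos[cols[pk]],
                  peak_lod = lods[pk], interval_lo = grid$pos[cols[lo]],
                  interval_hi = grid$pos[cols[hi]])
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> chr ", x$peak$chr, ": peak LOD ",
      sprintf("%.2f", x$peak$peak_lod), " at ",
      sprintf("%.1f", x$peak$peak_pos), " cM; 2-LOD interval [",
      sprintf("%.1f", x$peak$interval_lo), ", ",
      sprintf("%.1f", x$peak$interval_hi), "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.scan_result <- function(x, ...) x$lod

#' @export
glance.scan_result <- function(x, ...) x$peak

#' Classify a scanned eQTL as absent, local or trans
#'
#' A QTL is inferred when the peak LOD exceeds `lod_threshold` (default
#' 5, a genome-wide 5% threshold). An inferred eQTL is local when the
#' scan is on the probe's own chromosome and the 2-LOD support interval
#' contains the probe's genomic location; otherwise it is trans.
#'
#' @param scan A `scan_result`.
#' @param probe_chr,probe_pos The probe's genomic location (cM); must be
#'   known (callers filter unannotated probes).
#' @param lod_threshold LOD that must be exceeded to declare a QTL.
#' @return `"none"`, `"local"` or `"trans"`.
#' @export
classify_eqtl <- function(scan, probe_chr, probe_pos, lod_threshold = 5) {
  if (is.na(probe_chr) || is.na(probe_pos))
    stop("probe location unknown; filter unannotated probes before calling")
  pk <- scan$peak
  if (pk$peak_lod <= lod_threshold) return("none")
  if (identical(as.character(pk$chr), as.character(probe_chr)) &&
      probe_pos >= pk$interval_lo && probe_pos <= pk$interval_hi) "local"
  else "trans"
}

#' Write a chromosome scan: TSV of LOD values plus JSON peak summary
#' @param scan A `scan_result`.
#' @param path Output TSV path; the peak summary goes to
#'   `paste0(path, ".json")`.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan$lod, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(scan$peak), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
autoplot.scan_result <- function(object, ...) {
  ggplot2::ggplot(object$lod, ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak$peak_pos, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  title = paste0("chr ", object$peak$chr)) +
    ggplot2::theme_minimal()
}
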