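# Multipoint genotype probabilities for an F2 autosome: hidden Markov
# model with a symmetric genotyping-error emission model, scaled
# forward-backward so long chromosomes do not underflow.

#' F2 intercross transition matrix
#'
#' Transition probabilities between the ordered genotype states
#' (BB, BR, RR) across an interval with recombination fraction `r`,
#' from two independent meioses:
#' BB -> ((1-r)^2, 2r(1-r), r^2); BR -> (r(1-r), (1-r)^2 + r^2, r(1-r));
#' RR symmetric to BB.
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return A 3x3 row-stochastic matrix.
#' @export
f2_transition <- function(r) {
  stopifnot(r >= 0, r <= 0.5)
  matrix(c((1 - r)^2,     2 * r * (1 - r), r^2,
           r * (1 - r),   (1 - r)^2 + r^2, r * (1 - r),
           r^2,           2 * r * (1 - r), (1 - r)^2),
         nrow = 3, byrow = TRUE, dimnames = list(GENO_CODES, GENO_CODES))
}

#' Genotyping-error emission probability
#'
#' P(observed call | true state) under a symmetric codominant error
#' model: the true genotype is observed with probability `1 - epsilon`,
#' and each of the two wrong calls has probability `epsilon / 2`. A
#' missing observation emits 1 for every state.
#'
#' @param observed Observed call (`"BB"`, `"BR"`, `"RR"` or `NA`).
#' @param true_state True genotype state.
#' @param epsilon Genotyping error rate in `[0, 0.5)` (default 0.002,
#'   i.e. 0.2%).
#' @return Emission probability.
#' @export
emission <- function(observed, true_state, epsilon = 0.002) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  if (is.na(observed)) return(1)
  stopifnot(observed %in% GENO_CODES, true_state %in% GENO_CODES)
  if (observed == true_state) 1 - epsilon else epsilon / 2
}

# n x 3 emission matrix for a vector of observed codes (1,2,3 or NA)
emission_matrix <- function(obs_int, epsilon) {
  n <- length(obs_int)
  e <- matrix(1, n, 3)
  typed <- !is.na(obs_int)
  if (any(typed)) {
    e[typed, ] <- epsilon / 2
    e[cbind(which(typed), obs_int[typed])] <- 1 - epsilon
  }
  e
}

#' Multipoint genotype probabilities via forward-backward
#'
#' Computes posterior genotype probabilities at every autosomal grid
#' position (markers and pseudomarkers) for each sample, conditional on
#' all marker calls on the chromosome, under the F2 hidden Markov model:
#' chromosome-start prior (1/4, 1/2, 1/4), transitions from the map
#' function's recombination fraction on each adjacent-gap interval, and
#' the symmetric genotyping-error emission model. The recursions are
#' scaled at every position, so chromosomes with many thousands of grid
#' positions do not underflow. X-linked positions are excluded.
#'
#' @param genotypes A `genotype_table` whose call columns match `map`.
#' @param map A `genetic_map`.
#' @param grid A `position_grid` built from `map` (default:
#'   `build_grid(map)`).
#' @param epsilon Assumed genotyping error rate (default 0.002).
#' @param map_function Map function for gap -> recombination fraction.
#' @return A `geno_prob` object: array samples x grid positions x 3
#'   (states BB, BR, RR) over the autosomal grid rows, with attributes
#'   `grid` (the autosomal subset, original `index` retained), `epsilon`
#'   and `map_function`.
#' @export
calc_genoprob <- function(genotypes, map, grid = build_grid(map),
                          epsilon = 0.002,
                          map_function = c("carter_falconer", "haldane",
                                           "kosambi")) {
  map_function <- match.arg(map_function)
  auto_grid <- grid[!grid$is_x, , drop = FALSE]
  n <- nrow(genotypes$calls)
  obs_int <- matrix(match(genotypes$calls, GENO_CODES), nrow = n,
                    dimnames = dimnames(genotypes$calls))
  prob <- array(NA_real_,
                dim = c(n, nrow(auto_grid), 3),
                dimnames = list(genotypes$sample_ids, NULL, GENO_CODES))
  prior <- c(0.25, 0.5, 0.25)

  for (ch in unique(auto_grid$chr)) {
    rows <- which(auto_grid$chr == ch)
    g <- auto_grid[rows, , drop = FALSE]
    TT <- nrow(g)
    # emissions: markers use observed calls, pseudomarkers emit 1
    E <- vector("list", TT)
    for (t in seq_len(TT)) {
      E[[t]] <- if (g$kind[t] == "marker")
        emission_matrix(obs_int[, g$marker[t]], epsilon)
      else matrix(1, n, 3)
    }
    trans <- lapply(seq_len(TT - 1L), function(t)
      f2_transition(inverse_map_r(g$pos[t + 1] - g$pos[t], map_function)))

    # scaled forward
    f <- vector("list", TT)
    a <- sweep(E[[1]], 2, prior, `*`)
    f[[1]] <- a / rowSums(a)
    if (TT > 1) for (t in 2:TT) {
      a <- (f[[t - 1]] %*% trans[[t - 1]]) * E[[t]]
      f[[t]] <- a / rowSums(a)
    }
    # scaled backward
    b <- matrix(1, n, 3)
    post <- f[[TT]] * b
    prob[, rows[TT], ] <- post / rowSums(post)
    if (TT > 1) for (t in (TT - 1L):1L) {
      b <- (b * E[[t + 1]]) %*% t(trans[[t]])
      b <- b / rowSums(b)
      post <- f[[t]] * b
      prob[, rows[t], ] <- post / rowSums(post)
    }
  }
  structure(prob, class = "geno_prob", grid = auto_grid,
            epsilon = epsilon, map_function = map_function)
}

#' @export
print.geno_prob <- function(x, ...) {
  cat("<geno_prob> ", dim(x)[1], " samples x ", dim(x)[2],
      " autosomal grid positions x 3 states (epsilon = ", attr(x, "epsilon"),
      ", ", attr(x, "map_function"), " map)\n", sep = "")
  invisible(x)
}

#' Call genotypes from multipoint probabilities
#'
#' The call at a position is the state with maximal posterior
#' probability, provided that probability strictly exceeds `threshold`;
#' otherwise the call is `NA` (treated as missing downstream).
#'
#' @param prob A `geno_prob` array.
#' @param threshold Posterior probability that must be exceeded
#'   (default 0.99).
#' @return Character matrix samples x grid positions with entries in
#'   `BB`/`BR`/`RR`/`NA`.
#' @export
call_genotype <- function(prob, threshold = 0.99) {
  d <- dim(prob)
  flat <- matrix(prob, d[1] * d[2], 3)
  mx <- pmax(flat[, 1], flat[, 2], flat[, 3])
  amx <- max.col(flat, ties.method = "first")
  calls <- ifelse(mx > threshold, GENO_CODES[amx], NA_character_)
  matrix(calls, d[1], d[2], dimnames = dimnames(prob)[1:2])
}
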