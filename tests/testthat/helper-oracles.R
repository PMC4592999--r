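# Independent oracles used to validate the HMM and the Haley-Knott
# regression against brute-force computations.

# Exhaustive-path posterior for an F2 chromosome: enumerates all 3^m
# state paths over the given positions (observations may be NA, e.g. at
# pseudomarker positions) and sums path probabilities per state.
enumerate_posterior <- function(obs, pos, epsilon,
                                map_function = "haldane") {
  states <- 1:3
  m <- length(obs)
  prior <- c(0.25, 0.5, 0.25)
  emit <- function(o, s) {
    if (is.na(o)) return(1)
    if (match(o, c("BB", "BR", "RR")) == s) 1 - epsilon else epsilon / 2
  }
  rs <- if (m > 1) inverse_map_r(diff(pos), map_function) else numeric(0)
  trans <- lapply(rs, f2_transition)
  paths <- as.matrix(expand.grid(rep(list(states), m)))
  pp <- apply(paths, 1, function(st) {
    p <- prior[st[1]] * emit(obs[1], st[1])
    if (m > 1) for (j in 2:m)
      p <- p * trans[[j - 1]][st[j - 1], st[j]] * emit(obs[j], st[j])
    p
  })
  post <- t(vapply(seq_len(m), function(j)
    vapply(states, function(s) sum(pp[paths[, j] == s]), numeric(1)),
    numeric(3)))
  post / rowSums(post)  # m x 3 posterior
}

# Least-squares likelihood-ratio LOD via an SVD projection, fully
# independent of lm.fit: RSS = ||y||^2 - ||U' y||^2 over the singular
# subspace of the design.
svd_rss <- function(y, X) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * max(s$d) * .Machine$double.eps
  u <- s$u[, keep, drop = FALSE]
  sum(y^2) - sum(crossprod(u, y)^2)
}

svd_lod <- function(y, X1, X0) {
  length(y) / 2 * log10(svd_rss(y, X0) / svd_rss(y, X1))
}

map_cM_for_test <- function(r, mf) {
  switch(mf, carter_falconer = carter_falconer_cM(r),
         haldane = haldane_cM(r), kosambi = kosambi_cM(r))
}
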