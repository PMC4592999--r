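# Genetic map functions and the marker + pseudomarker evaluation grid.

#' Genetic map constructor
#'
#' A genetic map is a tibble with one row per marker, columns `marker`
#' (unique names), `chr` (character), `pos` (centimorgans, non-decreasing
#' within a chromosome) and `is_x` (logical, constant within a chromosome).
#'
#' @param marker Character vector of unique marker names.
#' @param chr Character vector of chromosome labels.
#' @param pos Numeric vector of map positions in centimorgans.
#' @param x_chr Chromosome labels to treat as X-linked (default `"X"`).
#' @return A tibble of class `genetic_map`.
#' @export
genetic_map <- function(marker, chr, pos, x_chr = "X") {
  map <- tibble(
    marker = as.character(marker),
    chr = as.character(chr),
    pos = as.numeric(pos),
    is_x = as.character(chr) %in% x_chr
  )
  validate_genetic_map(map)
}

#' @rdname genetic_map
#' @param map A candidate genetic map tibble.
#' @export
validate_genetic_map <- function(map) {
  stopifnot(all(c("marker", "chr", "pos") %in% names(map)))
  if (!"is_x" %in% names(map)) map$is_x <- map$chr %in% "X"
  if (anyDuplicated(map$marker))
    stop("duplicate marker names: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  if (any(is.na(map$pos)) || any(map$pos < 0))
    stop("marker positions must be non-negative and non-missing")
  bad <- map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0)
    stop("marker positions not non-decreasing on chromosome(s): ",
         paste(bad$chr, collapse = ", "))
  class(map) <- unique(c("genetic_map", class(map)))
  map
}

#' Map functions: recombination fraction to map distance
#'
#' `carter_falconer_cM()` implements the Carter-Falconer map function,
#' which assumes strong positive crossover interference:
#' d = 100 * (1/4) * ( (1/2) * log((1+2r)/(1-2r)) + atan(2r) ) cM.
#' `haldane_cM()` (no interference) and `kosambi_cM()` are provided for
#' comparison and simulation configurations.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centimorgans.
#' @export
carter_falconer_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * (0.5 * log((1 + 2 * r) / (1 - 2 * r)) + atan(2 * r))
}

#' @rdname carter_falconer_cM
#' @export
haldane_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname carter_falconer_cM
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse map function: map distance to recombination fraction
#'
#' Haldane and Kosambi inverses are closed form; the Carter-Falconer
#' inverse has no closed form and is obtained by bracketed root finding
#' on `[0, 0.5)` to absolute tolerance 1e-12.
#'
#' @param d Map distance(s) in centimorgans, `d >= 0`.
#' @param map_function One of `"carter_falconer"`, `"haldane"`, `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
inverse_map_r <- function(d, map_function = c("carter_falconer", "haldane",
                                              "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d < 0)) stop("d must be non-negative")
  switch(map_function,
    haldane = (1 - exp(-2 * d / 100)) / 2,
    kosambi = 0.5 * tanh(2 * d / 100),
    carter_falconer = vapply(d, function(di) {
      if (di == 0) return(0)
      upper <- 0.5 - 1e-14
      if (carter_falconer_cM(upper) <= di) return(upper)
      stats::uniroot(function(r) carter_falconer_cM(r) - di,
                     lower = 0, upper = upper, tol = 1e-12)$root
    }, numeric(1))
  )
}

#' Forward map function dispatch
#' @noRd
map_cM <- function(r, map_function) {
  switch(map_function,
    carter_falconer = carter_falconer_cM(r),
    haldane = haldane_cM(r),
    kosambi = kosambi_cM(r),
    stop("unknown map function: ", map_function)
  )
}

#' Build the marker + pseudomarker evaluation grid
#'
#' Between each adjacent marker pair with gap `g` cM, inserts
#' `ceiling(g / max_spacing) - 1` evenly spaced pseudomarkers, so that no
#' gap between adjacent grid positions exceeds `max_spacing`. Markers are
#' preserved exactly; coincident markers are kept as distinct grid
#' positions in map order.
#'
#' @param map A `genetic_map`.
#' @param max_spacing Maximum spacing between adjacent grid positions in
#'   centimorgans (default 0.5).
#' @return A tibble of class `position_grid` with columns `chr`, `pos`,
#'   `kind` (`"marker"` or `"pseudomarker"`), `marker` (name or `NA`),
#'   `is_x`, and `index` (row number).
#' @export
build_grid <- function(map, max_spacing = 0.5) {
  stopifnot(max_spacing > 0)
  map <- validate_genetic_map(map)
  pieces <- lapply(split(seq_len(nrow(map)), factor(map$chr, unique(map$chr))),
                   function(idx) {
    pos <- map$pos[idx]
    out_pos <- numeric(0); out_kind <- character(0); out_marker <- character(0)
    for (i in seq_along(idx)) {
      out_pos <- c(out_pos, pos[i])
      out_kind <- c(out_kind, "marker")
      out_marker <- c(out_marker, map$marker[idx[i]])
      if (i < length(idx)) {
        g <- pos[i + 1] - pos[i]
        if (g > max_spacing) {
          n_pm <- ceiling(g / max_spacing) - 1
          pm <- pos[i] + g * seq_len(n_pm) / (n_pm + 1)
          out_pos <- c(out_pos, pm)
          out_kind <- c(out_kind, rep("pseudomarker", n_pm))
          out_marker <- c(out_marker, rep(NA_character_, n_pm))
        }
      }
    }
    tibble(chr = map$chr[idx[1]], pos = out_pos, kind = out_kind,
           marker = out_marker, is_x = map$is_x[idx[1]])
  })
  grid <- dplyr::bind_rows(pieces)
  grid$index <- seq_len(nrow(grid))
  class(grid) <- unique(c("position_grid", class(grid)))
  grid
}

#' Nearest grid position to a genomic location
#'
#' Returns the grid `index` of the position on `chromosome` minimizing the
#' absolute centimorgan distance to `pos`; ties are broken toward the
#' lower (proximal) index.
#'
#' @param grid A `position_grid`.
#' @param chromosome Chromosome label.
#' @param pos Position in centimorgans.
#' @return Integer grid index (row of `grid`).
#' @export
nearest_position <- function(grid, chromosome, pos) {
  on_chr <- which(grid$chr == chromosome)
  if (length(on_chr) == 0) stop("chromosome not in grid: ", chromosome)
  d <- abs(grid$pos[on_chr] - pos)
  on_chr[which.min(d)]  # which.min takes the first (lower) index on ties
}
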