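# Shared heavy fixtures, built once per test run. The default planted
# and null scenarios (seed fixed at 42) feed the end-to-end tests; the
# small cross feeds fast module tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

planted_study <- function() fixture("planted_study",
  simulate_study(sim_config(seed = 42)))

planted_out_dir <- function()
  file.path(tempdir(), "crossalign_planted_out")

planted_pipeline <- function() fixture("planted_pipeline", {
  s <- planted_study()
  run_mixup_pipeline(s$genotypes, s$map, s$expr_sets, layout = s$layout,
                     out_dir = planted_out_dir())
})

null_study <- function() fixture("null_study",
  simulate_study(sim_config(seed = 42, errors = list())))

null_pipeline <- function() fixture("null_pipeline", {
  s <- null_study()
  run_mixup_pipeline(s$genotypes, s$map, s$expr_sets, layout = s$layout)
})

# small error-free cross for module tests
small_cross <- function() fixture("small_cross",
  simulate_cross(sim_config(
    n_mice = 80, chr_lengths = c("1" = 60, "2" = 50), markers_per_chr = 8,
    x_markers = 5, epsilon = 0, missing_rate = 0,
    tissues = "t1", n_probes = 30, n_eqtl = 6, n_shared = 10,
    errors = list(), seed = 7)))

# denser error-free cross (default 5-autosome map) for duplicate tests,
# where a sparse map would allow chance-identical unrelated pairs
medium_cross <- function() fixture("medium_cross",
  simulate_cross(sim_config(
    n_mice = 60, epsilon = 0, missing_rate = 0, tissues = "t1",
    n_probes = 30, n_eqtl = 6, n_shared = 10, errors = list(),
    seed = 19)))

# tiny two-tissue expression study with known structure
tiny_expr_pair <- function(n = 60, n_shared = 15, n_noise = 30,
                           loading = 0.75, resid = 0.25, seed = 11) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  lat <- matrix(rnorm(n * n_shared), n, n_shared)
  mk <- function() {
    shared <- loading * lat + matrix(rnorm(n * n_shared, sd = resid), n)
    noise <- matrix(rnorm(n * n_noise, sd = 0.3), n)
    vals <- cbind(shared, noise)
    dimnames(vals) <- list(ids, c(sprintf("sh%02d", seq_len(n_shared)),
                                  sprintf("no%02d", seq_len(n_noise))))
    vals
  }
  probes <- tibble::tibble(probe_id = c(sprintf("sh%02d", seq_len(n_shared)),
                                        sprintf("no%02d", seq_len(n_noise))),
                           chr = NA_character_, pos = NA_real_)
  list(a = expr_set("a", mk(), probes), b = expr_set("b", mk(), probes))
}

# three tissues sharing per-mouse latent factors (between-tissue probe
# correlation ~0.9), for fault-localization tests
tiny_expr_trio <- function(n = 30, n_shared = 60, n_noise = 30,
                           loading = 1, resid = 0.25, seed = 11) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  lat <- matrix(rnorm(n * n_shared), n, n_shared)
  probes <- tibble::tibble(probe_id = c(sprintf("sh%02d", seq_len(n_shared)),
                                        sprintf("no%02d", seq_len(n_noise))),
                           chr = NA_character_, pos = NA_real_)
  mk <- function(tis) {
    shared <- loading * lat + matrix(rnorm(n * n_shared, sd = resid), n)
    noise <- matrix(rnorm(n * n_noise, sd = 0.3), n)
    vals <- cbind(shared, noise)
    dimnames(vals) <- list(ids, probes$probe_id)
    expr_set(tis, vals, probes)
  }
  list(a = mk("a"), b = mk("b"), c = mk("c"))
}
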