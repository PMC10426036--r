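# Shared fixtures built in code.

tiny_registry <- function() {
  component_registry(c("AB", "CD", "EF"), c("circle", "slash", "bar"))
}

# population with explicit components (list of integer vectors), one zip each
make_population <- function(comps, zips, year = 1990, first_year = year,
                            n_symbols = max(unlist(comps)),
                            spatial = NULL) {
  comp <- matrix(0L, length(comps), 4L)
  for (i in seq_along(comps))
    comp[i, seq_along(comps[[i]])] <- as.integer(comps[[i]])
  if (is.null(spatial))
    spatial <- spatial_registry(unique(zips),
                                paste0("c", unique(zips)),
                                rep_len(c("NW", "NE", "SW", "SE"),
                                        length(unique(zips))))
  brand_population(comp, zips, first_year, NA_integer_, year,
                   sprintf("S%03d", seq_len(n_symbols)), spatial)
}

# independent dynamic-programming Levenshtein oracle on token vectors
lev_dp <- function(a, b) {
  na <- length(a); nb <- length(b)
  D <- matrix(0L, na + 1L, nb + 1L)
  D[, 1L] <- 0:na; D[1L, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb))
    D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                             D[i, j] + (a[i] != b[j]))
  D[na + 1L, nb + 1L]
}

# small ground-truth configuration for fast end-to-end tests
small_config <- function(...) {
  base <- list(n_symbols = 40, n_zips = 8, n_initial_brands = 400,
               years = 1990:2001, N_new = 60, N_old = 50, seed = 77)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

# synthetic regression rows with a combo-level random intercept and an
# optional planted ACTUAL effect
simulate_rows <- function(seed, beta_actual = 0, n_combo = 60,
                          n_datasets = 16) {
  set.seed(seed)
  g <- data.frame(combo_id = rep(paste0("c", seq_len(n_combo)), n_datasets),
                  space = rep(rep(c("NW", "NE", "SW", "SE"),
                                  length.out = n_datasets),
                              each = n_combo),
                  time = rep(rep(c("O", "Y"), length.out = n_datasets),
                             each = n_combo))
  g$ACTUAL <- as.integer(stats::runif(nrow(g)) < 0.4)
  g$MIXED <- rep(rep(0:1, each = n_datasets / 2), each = n_combo)
  g$COMPLEXITY <- as.integer(g$combo_id %in% paste0("c", 1:(n_combo / 2)))
  u <- stats::rnorm(n_combo, 0, 1.5)
  g$logS <- u[match(g$combo_id, paste0("c", seq_len(n_combo)))] +
    beta_actual * g$ACTUAL + stats::rnorm(nrow(g), 0, 0.5)
  g
}

# brand list (list of character vectors) -> arguments for shuffle_predictions
brands_to_matrix <- function(brands, symbols) {
  comp <- matrix(0L, length(brands), 4L)
  for (i in seq_along(brands))
    comp[i, seq_along(brands[[i]])] <- match(brands[[i]], symbols)
  list(comp = comp, n_comp = lengths(brands), symbols = symbols)
}
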