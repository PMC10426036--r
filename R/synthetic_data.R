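#' Synthetic study configuration
#'
#' Ground-truth conditions for generating registries with known copying
#' strength and complexity. Defaults emulate the scale of the Kansas
#' registry study: a fixed 103-symbol component alphabet (no innovation),
#' a ~2,000-brand initial population, a 27-year span, and yearly turnover of
#' 180 new / 150 removed brands, giving slow net growth. Zip zones have a
#' skewed frequency distribution (Dirichlet-style weights with concentration
#' `zip_concentration`); the initial component distribution is skewed the
#' same way via `symbol_concentration`.
#'
#' @param n_symbols size of the component alphabet.
#' @param n_zips number of zip zones.
#' @param zip_concentration Dirichlet concentration of zip weights (smaller =
#'   more skewed).
#' @param symbol_concentration Dirichlet concentration of initial component
#'   weights.
#' @param n_initial_brands initial population size.
#' @param lambda_true,C_true ground-truth complexity and copying parameters.
#' @param years inclusive simulated year range.
#' @param N_new,N_old brands created / removed per year.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_symbols = 103, n_zips = 10,
                             zip_concentration = 1,
                             symbol_concentration = 1,
                             n_initial_brands = 2000, lambda_true = 3,
                             C_true = 1, years = 1990:2016, N_new = 180,
                             N_old = 150, seed = 1L) {
  stopifnot(length(years) >= 1, n_initial_brands >= N_old,
            lambda_true > 0, n_symbols >= 2, n_zips >= 2)
  structure(list(n_symbols = n_symbols, n_zips = n_zips,
                 zip_concentration = zip_concentration,
                 symbol_concentration = symbol_concentration,
                 n_initial_brands = as.integer(n_initial_brands),
                 lambda_true = lambda_true, C_true = C_true,
                 years = as.integer(years), N_new = as.integer(N_new),
                 N_old = as.integer(N_old), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Synthetic spatial registry
#'
#' Zip zones `z01..` are mapped round-robin onto `ceiling(n_zips / 2)`
#' counties, and counties round-robin onto the four quadrants. Quadrants are
#' synthetic labels; no geometry is implied.
#'
#' @param n_zips number of zip zones (>= 8 guarantees all four quadrants).
#' @return a [spatial_registry].
#' @export
synthetic_spatial <- function(n_zips = 10) {
  zips <- sprintf("z%02d", seq_len(n_zips))
  n_counties <- max(4L, ceiling(n_zips / 2))
  county <- sprintf("c%02d", rep_len(seq_len(n_counties), n_zips))
  quad_of_county <- rep_len(c("NW", "NE", "SW", "SE"), n_counties)
  spatial_registry(zips, county,
                   quad_of_county[as.integer(sub("c", "", county))])
}

# Skewed zip weights shared by the generators; reproducible given the config.
synthetic_zip_probs <- function(config) {
  set.seed(derive_seed(config$seed, 101))
  w <- stats::rgamma(config$n_zips, shape = config$zip_concentration)
  w <- pmax(w, 1e-9)
  stats::setNames(w / sum(w), sprintf("z%02d", seq_len(config$n_zips)))
}

#' Generate the initial synthetic population
#'
#' Brand complexities are drawn from the truncated Poisson at `lambda_true`;
#' components i.i.d. from a seeded skewed (Dirichlet-weight) distribution
#' over the symbol alphabet; zips from the skewed zip distribution. Fully
#' reproducible given `config$seed`.
#'
#' @param config a [synthetic_config].
#' @return a [brand_population] for the first configured year.
#' @export
generate_initial_population <- function(config) {
  spatial <- synthetic_spatial(config$n_zips)
  zip_probs <- synthetic_zip_probs(config)
  set.seed(derive_seed(config$seed, 102))
  n <- config$n_initial_brands
  symbols <- sprintf("S%03d", seq_len(config$n_symbols))
  w <- stats::rgamma(config$n_symbols, shape = config$symbol_concentration)
  w <- pmax(w, 1e-9)
  comp <- matrix(0L, n, 4L)
  if (n > 0) {
    ks <- sample.int(4L, n, replace = TRUE,
                     prob = complexity_pmf(config$lambda_true))
    syms <- sample.int(config$n_symbols, sum(ks), replace = TRUE,
                       prob = w / sum(w))
    comp[cbind(rep.int(seq_len(n), ks), sequence(ks))] <- syms
  }
  zips <- if (n > 0) sample(names(zip_probs), n, replace = TRUE,
                            prob = zip_probs) else character(0)
  pop <- brand_population(comp, zips, rep(config$years[1L], n), NA_integer_,
                          config$years[1L], symbols, spatial)
  attr(pop, "zip_probs") <- zip_probs
  pop
}

#' Generate a ground-truth observed series
#'
#' Builds the initial population and delegates the yearly dynamics to the
#' generative model at (`lambda_true`, `C_true`). The returned series carries
#' its ground truth in the `"truth"` attribute for recovery scoring.
#'
#' @param config a [synthetic_config].
#' @param initial optional pre-built initial [brand_population] (defaults to
#'   [generate_initial_population()]).
#' @return named list of yearly [brand_population] snapshots.
#' @export
generate_observed_series <- function(config, initial = NULL) {
  if (is.null(initial)) initial <- generate_initial_population(config)
  zip_probs <- attr(initial, "zip_probs")
  if (is.null(zip_probs)) zip_probs <- synthetic_zip_probs(config)
  params <- abm_params(C = config$C_true, lambda = config$lambda_true,
                       N_new = config$N_new, N_old = config$N_old,
                       zip_probs = zip_probs, years = config$years,
                       seed = derive_seed(config$seed, 103))
  snaps <- run_abm(initial, params)
  attr(snaps, "truth") <- list(lambda = config$lambda_true,
                               C = config$C_true)
  snaps
}

#' Toy conformity simulation
#'
#' A fully connected population of `n_agents` agents transmits `n_variants`
#' variants, starting from equal frequencies. At each timestep every agent
#' re-adopts a variant with probability proportional to its previous-timestep
#' frequency raised to `C` (simultaneous updating by default; sequential
#' updating, where each agent responds to the current population, is
#' available). A time-mixed subsample of `n_agents` agent-states is drawn
#' uniformly without replacement from all timesteps pooled.
#'
#' @param n_agents population size (must be divisible by `n_variants`).
#' @param n_variants number of variants (>= 2).
#' @param C conformity exponent.
#' @param timesteps number of timesteps (the first holds the equal start).
#' @param seed integer seed.
#' @param scheduling `"simultaneous"` or `"sequential"` updating.
#' @return list with `freqs` (timesteps x variants frequency matrix, rows sum
#'   to 1), `mixed` (variant frequencies in the pooled subsample), and
#'   `states` (the agent-state matrix).
#' @export
toy_conformity_sim <- function(n_agents = 30, n_variants = 2, C = 2,
                               timesteps = 3, seed = 1L,
                               scheduling = c("simultaneous", "sequential")) {
  scheduling <- match.arg(scheduling)
  stopifnot(n_variants >= 2, n_agents %% n_variants == 0, timesteps >= 1)
  set.seed(seed)
  states <- matrix(NA_integer_, timesteps, n_agents)
  states[1L, ] <- rep_len(seq_len(n_variants), n_agents)
  for (t in seq_len(timesteps)[-1L]) {
    if (scheduling == "simultaneous") {
      f <- tabulate(states[t - 1L, ], n_variants)
      p <- ifelse(f > 0, f^C, 0)
      states[t, ] <- sample.int(n_variants, n_agents, replace = TRUE,
                                prob = p / sum(p))
    } else {
      cur <- states[t - 1L, ]
      for (a in seq_len(n_agents)) {
        f <- tabulate(cur, n_variants)
        p <- ifelse(f > 0, f^C, 0)
        cur[a] <- sample.int(n_variants, 1L, prob = p / sum(p))
      }
      states[t, ] <- cur
    }
  }
  freqs <- t(apply(states, 1L, tabulate, nbins = n_variants)) / n_agents
  pooled <- as.vector(states)
  mixed <- tabulate(sample(pooled, n_agents), n_variants) / n_agents
  colnames(freqs) <- names(mixed) <- LETTERS[seq_len(n_variants)]
  list(freqs = freqs, mixed = mixed, states = states)
}

rank_freq <- function(pop) {
  f <- build_frequency_table(pop)
  sort(f / sum(f), decreasing = TRUE)
}

#' Time-mixing demonstration on component frequency distributions
#'
#' For each copying strength in `C_values`, runs the generative model and
#' returns (averaged over `n_iterations` seeded runs) the rank-frequency
#' distribution of components in the final year, the distribution from an
#' equal-size brand subsample pooled over all years (time-mixed), and the
#' final-year distribution under random copying (`C = 1`) as reference.
#'
#' @param config a [synthetic_config].
#' @param C_values copying strengths to contrast (default 0 and 10).
#' @param n_iterations seeded replicate runs to average over.
#' @return list with one element per C value (each holding `final` and
#'   `mixed` rank-frequency vectors) plus `reference` (the C = 1 final-year
#'   distribution).
#' @export
component_mixing_demo <- function(config, C_values = c(0, 10),
                                  n_iterations = 5) {
  run_one <- function(C, iter) {
    cfg <- config
    cfg$C_true <- C
    cfg$seed <- derive_seed(config$seed, 1000 * iter + round(100 * C) + 7)
    snaps <- generate_observed_series(cfg)
    final <- snaps[[length(snaps)]]
    n_final <- n_brands(final)
    pool_comp <- do.call(rbind, lapply(snaps, function(p) p$components))
    pool_n <- unlist(lapply(snaps, function(p) p$n_comp), use.names = FALSE)
    set.seed(derive_seed(cfg$seed, 9))
    idx <- sample.int(nrow(pool_comp), n_final)
    mixed_counts <- tabulate(pool_comp[idx, , drop = FALSE],
                             nbins = length(final$symbols))
    list(final = rank_freq(final),
         mixed = sort(mixed_counts / sum(mixed_counts), decreasing = TRUE))
  }
  avg <- function(vs) Reduce(`+`, vs) / length(vs)
  out <- lapply(C_values, function(C) {
    runs <- lapply(seq_len(n_iterations), function(i) run_one(C, i))
    list(final = avg(lapply(runs, `[[`, "final")),
         mixed = avg(lapply(runs, `[[`, "mixed")))
  })
  names(out) <- paste0("C", C_values)
  refs <- lapply(seq_len(n_iterations),
                 function(i) run_one(1, i)$final)
  out$reference <- avg(refs)
  out
}

#' Synthetic brands with planted wholesale copying
#'
#' Generates a pooled brand table spanning two periods (O/Y) and the four
#' quadrants. Within each (period x quadrant x complexity) cell, brands are
#' created sequentially: with probability `copy_prob` a brand copies the full
#' component set of an earlier brand from the same cell (wholesale copying);
#' otherwise it assembles its components independently from a shared
#' Zipf-skewed component distribution, as heavily skewed component
#' frequencies are typical of such registries. Wholesale copying creates
#' local co-occurrence clusters that a prevalence model assuming independent
#' components under-predicts in structured data but captures better once
#' time or space mixing dilutes the clusters; because copying stays within a
#' cell, same-period brands are also more similar in edit distance.
#'
#' Component popularity is not spatially or temporally uniform: the shared
#' Zipf log-weights receive an additive quadrant effect (sd
#' `space_heterogeneity`) and an additive period effect (sd
#' `time_heterogeneity`), the way component fashions vary regionally and
#' drift between periods.
#'
#' @param n_per_cell brands per (period x quadrant x complexity) cell.
#' @param n_symbols component alphabet size.
#' @param copy_prob probability that a brand copies an earlier local brand
#'   wholesale.
#' @param space_heterogeneity,time_heterogeneity sd of the per-quadrant and
#'   per-period log-normal perturbations of component weights.
#' @param seed integer seed.
#' @return list of class `brand_table` with fields `components`, `n_comp`,
#'   `period`, `quadrant`, `zip`, `symbols`, `spatial`.
#' @export
generate_wholesale_copy_table <- function(n_per_cell = 200, n_symbols = 30,
                                          copy_prob = 0.8,
                                          space_heterogeneity = 0.4,
                                          time_heterogeneity = 0.4,
                                          seed = 1L) {
  set.seed(seed)
  symbols <- sprintf("S%03d", seq_len(n_symbols))
  quadrants <- c("NW", "NE", "SW", "SE")
  spatial <- spatial_registry(paste0("z", quadrants), paste0("c", quadrants),
                              quadrants)
  w0 <- (1 / seq_len(n_symbols))
  zq <- matrix(stats::rnorm(n_symbols * 4, 0, space_heterogeneity),
               n_symbols, 4, dimnames = list(NULL, quadrants))
  zp <- matrix(stats::rnorm(n_symbols * 2, 0, time_heterogeneity),
               n_symbols, 2, dimnames = list(NULL, c("O", "Y")))
  comp <- list(); per <- list(); quad <- list()
  for (p in c("O", "Y")) for (q in quadrants) {
    w <- w0 * exp(zq[, q] + zp[, p])
    w <- w / sum(w)
    for (k in 2:3) {
      m <- matrix(0L, n_per_cell, 4L)
      for (i in seq_len(n_per_cell)) {
        if (i > 1L && stats::runif(1) < copy_prob) {
          # wholesale copying: the full component set of an earlier local
          # brand is taken over as-is
          m[i, ] <- m[sample.int(i - 1L, 1L), ]
        } else {
          m[i, seq_len(k)] <- sample.int(n_symbols, k, replace = TRUE,
                                         prob = w)
        }
      }
      comp[[length(comp) + 1L]] <- m
      per[[length(per) + 1L]] <- rep(p, n_per_cell)
      quad[[length(quad) + 1L]] <- rep(q, n_per_cell)
    }
  }
  components <- do.call(rbind, comp)
  quadrant <- unlist(quad)
  structure(list(components = components,
                 n_comp = as.integer(rowSums(components > 0L)),
                 period = unlist(per), quadrant = quadrant,
                 zip = paste0("z", quadrant), symbols = symbols,
                 spatial = spatial),
            class = "brand_table")
}
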