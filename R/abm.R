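#' ABM parameters
#'
#' Parameters of the generative model of yearly brand creation. `C` is the
#' copying/distinctiveness exponent on component frequency: `C = 1` is random
#' (unbiased) copying, `C > 1` conformist copying, `C = 0` frequency-blind
#' sampling, and negative values favour the rarest components (pressure for
#' distinctiveness). `lambda` sets the truncated-Poisson pressure on brand
#' complexity (number of components, 1-4).
#'
#' @param C real exponent on component frequency.
#' @param lambda positive real; complexity parameter.
#' @param N_new,N_old non-negative integers: brands created / removed per year.
#' @param zip_probs named probability vector over zip zones (sums to 1).
#' @param years inclusive range of simulated calendar years.
#' @param seed integer RNG seed.
#' @return list of class `abm_params`.
#' @export
abm_params <- function(C, lambda, N_new, N_old, zip_probs, years, seed = 1L) {
  stopifnot(lambda > 0, N_new >= 0, N_old >= 0, length(years) >= 1)
  zip_probs <- zip_probs / sum(zip_probs)
  if (is.null(names(zip_probs))) stop("zip_probs must be named by zip")
  structure(list(C = C, lambda = lambda, N_new = as.integer(N_new),
                 N_old = as.integer(N_old), zip_probs = zip_probs,
                 years = as.integer(years), seed = as.integer(seed)),
            class = "abm_params")
}

#' Component frequency table
#'
#' Counts component tokens (with multiplicity: a symbol used twice within one
#' brand counts twice) across all active brands. This table drives the
#' weighted random sampling by which new brands draw their components.
#'
#' @param pop a [brand_population].
#' @return named integer vector over the full symbol alphabet.
#' @export
build_frequency_table <- function(pop) {
  if (n_brands(pop) == 0L) stop("cannot tabulate an empty population")
  counts <- tabulate(pop$components, nbins = length(pop$symbols))
  names(counts) <- pop$symbols
  counts
}

#' Frequency-dependent component sampling probabilities
#'
#' The probability of using component `x` is its token count raised to the
#' exponent `C`, normalised over all components currently in use:
#' `P(x) = n_x^C / sum_y n_y^C`. Components with zero count are never sampled
#' (variation is bounded: no innovation of new component types), which also
#' keeps negative exponents well defined.
#'
#' @param freqs named count vector (see [build_frequency_table()]).
#' @param C real exponent.
#' @return probability vector aligned with `freqs` (zeros where count is 0).
#' @export
component_sampling_probs <- function(freqs, C) {
  if (all(freqs == 0)) stop("all component counts are zero")
  p <- numeric(length(freqs))
  pos <- freqs > 0
  w <- freqs[pos]^C
  p[pos] <- w / sum(w)
  names(p) <- names(freqs)
  p
}

#' Truncated-Poisson complexity distribution
#'
#' Number of components per new brand: a Poisson(`lambda`) truncated to
#' `{1, 2, 3, 4}` and renormalised, i.e. `q(k)` proportional to
#' `lambda^k / k!`. `lambda = 3` gives equal mass to two- and three-component
#' brands; small `lambda` favours one-component brands, large `lambda`
#' four-component brands.
#'
#' @param lambda positive real.
#' @return probability vector over k = 1..4.
#' @export
complexity_pmf <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number")
  k <- 1:4
  w <- lambda^k / factorial(k)
  stats::setNames(w / sum(w), k)
}

#' Create one new brand
#'
#' Draws a complexity from [complexity_pmf()], then that many components
#' i.i.d. (with replacement, so within-brand repeats are legal) from
#' [component_sampling_probs()], and a zip in proportion to `zip_probs`.
#'
#' @param freqs named count vector.
#' @param params an [abm_params].
#' @return list with `components` (integer symbol indices) and `zip`.
#' @export
create_brand <- function(freqs, params) {
  k <- sample.int(4L, 1L, prob = complexity_pmf(params$lambda))
  p <- component_sampling_probs(freqs, params$C)
  list(components = sample.int(length(freqs), k, replace = TRUE, prob = p),
       zip = sample(names(params$zip_probs), 1L, prob = params$zip_probs))
}

# One simulated year on the light internal state (comp matrix, zip index,
# first_year). The frequency table is built once, before any of the year's
# N_new creations; removal then draws N_old brands uniformly from the union
# (same-year brands are removable).
step_year_state <- function(comp, zip_i, fy, year, params, n_symbols,
                            n_zips) {
  n <- nrow(comp)
  if (n + params$N_new - params$N_old <= 0L)
    stop("population would become empty")
  if (params$N_new > 0L) {
    counts <- tabulate(comp, nbins = n_symbols)
    p <- numeric(n_symbols)
    pos <- counts > 0L
    w <- counts[pos]^params$C
    p[pos] <- w / sum(w)
    ks <- sample.int(4L, params$N_new, replace = TRUE,
                     prob = complexity_pmf(params$lambda))
    syms <- sample.int(n_symbols, sum(ks), replace = TRUE, prob = p)
    newcomp <- matrix(0L, params$N_new, 4L)
    newcomp[cbind(rep.int(seq_len(params$N_new), ks), sequence(ks))] <- syms
    newzip <- sample.int(n_zips, params$N_new, replace = TRUE,
                         prob = params$zip_probs)
    comp <- rbind(comp, newcomp)
    zip_i <- c(zip_i, newzip)
    fy <- c(fy, rep.int(year, params$N_new))
  }
  if (params$N_old > 0L) {
    drop <- sample.int(nrow(comp), params$N_old)
    comp <- comp[-drop, , drop = FALSE]
    zip_i <- zip_i[-drop]
    fy <- fy[-drop]
  }
  list(comp = comp, zip_i = zip_i, fy = fy)
}

#' Advance a population by one year
#'
#' At the beginning of the year `N_new` brands are created by weighted
#' sampling from the frequency table compiled before any additions; then
#' `N_old` brands are removed uniformly at random (brands created the same
#' year are removable).
#'
#' @param pop a [brand_population].
#' @param params an [abm_params].
#' @return the [brand_population] for the following year.
#' @export
step_year <- function(pop, params) {
  zips <- names(params$zip_probs)
  zi <- match(pop$zip, zips)
  if (anyNA(zi)) stop("population zips missing from params$zip_probs")
  st <- step_year_state(pop$components, zi, pop$first_year, pop$year + 1L,
                        params, length(pop$symbols), length(zips))
  brand_population(st$comp, zips[st$zip_i], st$fy, NA_integer_,
                   pop$year + 1L, pop$symbols, pop$spatial)
}

#' Run the generative model over a span of years
#'
#' The simulation is initialised with `initial` (the earliest year in
#' `params$years`) and advanced year by year to the end of the range.
#' Deterministic given `params$seed`.
#'
#' @param initial a [brand_population] for the first year.
#' @param params an [abm_params].
#' @param snapshot_years years at which to materialise snapshots (default:
#'   every simulated year).
#' @return named list of [brand_population] snapshots, one per snapshot year.
#' @export
run_abm <- function(initial, params, snapshot_years = params$years) {
  years <- params$years
  stopifnot(initial$year == years[1L], all(snapshot_years %in% years))
  set.seed(params$seed)
  zips <- names(params$zip_probs)
  zi <- match(initial$zip, zips)
  if (anyNA(zi)) stop("initial population zips missing from params$zip_probs")
  comp <- initial$components; fy <- initial$first_year
  n_symbols <- length(initial$symbols)
  out <- vector("list", length(snapshot_years))
  names(out) <- as.character(snapshot_years)
  if (years[1L] %in% snapshot_years)
    out[[as.character(years[1L])]] <- initial
  for (y in years[-1L]) {
    st <- step_year_state(comp, zi, fy, y, params, n_symbols, length(zips))
    comp <- st$comp; zi <- st$zip_i; fy <- st$fy
    if (y %in% snapshot_years)
      out[[as.character(y)]] <- brand_population(
        comp, zips[zi], fy, NA_integer_, y, initial$symbols, initial$spatial)
  }
  out
}

population_keys <- function(pop) {
  paste(pop$components[, 1L], pop$components[, 2L], pop$components[, 3L],
        pop$components[, 4L], pop$zip, sep = "_")
}

#' Estimate yearly turnover and zip distribution from observed snapshots
#'
#' `N_new` is the average number of brand codes per year that appear in a
#' snapshot but not the previous one, `N_old` the average number that
#' disappear; counts are divided by the calendar gap between books, which may
#' exceed one year for unevenly spaced registries. Zip probabilities are the
#' pooled zip relative frequencies over all snapshots.
#'
#' @param observed list of [brand_population] snapshots in year order.
#' @return list with integer `N_new`, `N_old`, and named `zip_probs`.
#' @export
estimate_turnover <- function(observed) {
  if (length(observed) < 2L)
    stop("turnover estimation needs at least two snapshots")
  years <- vapply(observed, function(p) p$year, integer(1))
  if (is.unsorted(years, strictly = TRUE))
    stop("snapshots must be in strictly increasing year order")
  app <- dis <- numeric(length(observed) - 1L)
  for (i in seq_along(app)) {
    gap <- years[i + 1L] - years[i]
    t0 <- table(population_keys(observed[[i]]))
    t1 <- table(population_keys(observed[[i + 1L]]))
    all_keys <- union(names(t0), names(t1))
    c0 <- as.integer(t0[all_keys]); c0[is.na(c0)] <- 0L
    c1 <- as.integer(t1[all_keys]); c1[is.na(c1)] <- 0L
    app[i] <- sum(pmax(c1 - c0, 0L)) / gap
    dis[i] <- sum(pmax(c0 - c1, 0L)) / gap
  }
  zips <- unlist(lapply(observed, function(p) p$zip), use.names = FALSE)
  zp <- table(zips) / length(zips)
  list(N_new = as.integer(round(mean(app))),
       N_old = as.integer(round(mean(dis))),
       zip_probs = stats::setNames(as.numeric(zp), names(zp)))
}
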