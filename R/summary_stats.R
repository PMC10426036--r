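#' Proportions of the most common and most rare component
#'
#' The share of all component tokens belonging to the most common (resp. most
#' rare among those present) component type.
#'
#' @param freqs named count vector (see [build_frequency_table()]).
#' @return proportion in `(0, 1]`.
#' @export
prop_most_common <- function(freqs) {
  pos <- freqs[freqs > 0]
  if (!length(pos)) stop("empty frequency table")
  max(pos) / sum(pos)
}

#' @rdname prop_most_common
#' @export
prop_most_rare <- function(freqs) {
  pos <- freqs[freqs > 0]
  if (!length(pos)) stop("empty frequency table")
  min(pos) / sum(pos)
}

check_probs <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("input must be a probability vector (non-negative, summing to 1)")
}

#' Hill-number diversities
#'
#' Effective numbers of equally-common types: `hill_shannon` is the Hill
#' number of order 1, `exp(-sum p_i log p_i)`; `hill_simpson` is the Hill
#' number of order 2, `1 / sum p_i^2`. Both equal richness on a uniform
#' distribution, and Hill numbers are non-increasing in the order, so
#' `hill_shannon(p) >= hill_simpson(p)`.
#'
#' @param p probability vector (non-negative, sums to 1).
#' @return effective number of types (>= 1).
#' @export
hill_shannon <- function(p) {
  check_probs(p)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' @rdname hill_shannon
#' @export
hill_simpson <- function(p) {
  check_probs(p)
  1 / sum(p^2)
}

mean_upper_tri <- function(m) mean(m[upper.tri(m)])

#' Pairwise beta-diversity similarity, averaged over spatial units
#'
#' `jaccard_beta` computes the classical Jaccard similarity
#' `|A intersect B| / |A union B|` on component incidence for every unordered
#' pair of spatial units and returns the mean. `morisita_horn_beta` does the
#' same with the abundance-based Morisita-Horn similarity
#' `2 sum(x_i y_i) / ((sum x_i^2 / X^2 + sum y_i^2 / Y^2) X Y)`. Units with
#' zero tokens are dropped before averaging.
#'
#' @param m matrix of component counts, one row per spatial unit, one column
#'   per component type (for `jaccard_beta` any positive entry marks
#'   incidence).
#' @return mean pairwise similarity in `[0, 1]`.
#' @export
jaccard_beta <- function(m) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two non-empty spatial units")
  z <- m > 0
  storage.mode(z) <- "numeric"
  inter <- tcrossprod(z)
  rs <- rowSums(z)
  mean_upper_tri(inter / (outer(rs, rs, "+") - inter))
}

#' @rdname jaccard_beta
#' @export
morisita_horn_beta <- function(m) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two non-empty spatial units")
  tot <- rowSums(m)
  cross <- tcrossprod(m)
  d <- rowSums(m^2) / tot^2
  mean_upper_tri(2 * cross / (outer(d, d, "+") * outer(tot, tot)))
}

#' Component abundance by spatial unit
#'
#' Token counts of each component type per zip zone or county.
#'
#' @param pop a [brand_population] (with a spatial registry when
#'   `level = "county"`).
#' @param level `"zip"` or `"county"`.
#' @return count matrix, one row per non-empty unit, one column per symbol.
#' @export
abundance_by_unit <- function(pop, level = c("zip", "county")) {
  level <- match.arg(level)
  unit <- if (level == "zip") pop$zip
          else resolve_zip(pop$zip, pop$spatial)$county
  lev <- unique(unit)
  ui <- match(unit, lev)
  comp <- pop$components
  n <- nrow(comp)
  idx <- which(comp > 0L)
  sym <- comp[idx]
  row <- (idx - 1L) %% n + 1L
  ns <- length(pop$symbols)
  cnt <- tabulate((ui[row] - 1L) * ns + sym, nbins = length(lev) * ns)
  m <- matrix(cnt, length(lev), ns, byrow = TRUE,
              dimnames = list(lev, pop$symbols))
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Mean Levenshtein distance between brands
#'
#' Token-level edit distance (insertions, deletions, substitutions of whole
#' components) over canonical symbol sequences in recorded slot order,
#' ignoring rotations; computed for all unordered pairs in a random
#' subsample of the population (10% by default, minimum 2 brands).
#'
#' @param pop a [brand_population] with at least 2 brands.
#' @param fraction subsample fraction (default 0.1).
#' @param seed optional integer; when given, the subsample is drawn from a
#'   seeded local RNG stream.
#' @return mean pairwise edit distance.
#' @export
mean_levenshtein <- function(pop, fraction = 0.1, seed = NULL) {
  n <- n_brands(pop)
  if (n < 2) stop("population must contain at least 2 brands")
  m <- max(2L, ceiling(fraction * n))
  idx <- if (is.null(seed)) sample.int(n, m) else {
    old <- .Random.seed_save()
    set.seed(seed)
    s <- sample.int(n, m)
    .Random.seed_restore(old)
    s
  }
  s <- encode_component_strings(pop$components[idx, , drop = FALSE],
                                pop$n_comp[idx])
  d <- utils::adist(s)
  mean_upper_tri(d)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Token-level Levenshtein distances between two sets of brands
#'
#' @param comp integer component matrix (rows = brands).
#' @param n_comp integer vector of component counts per row.
#' @return symmetric integer distance matrix.
#' @export
levenshtein_matrix <- function(comp, n_comp) {
  utils::adist(encode_component_strings(comp, n_comp))
}

summary_stat_names <- c("prop_most_common", "prop_most_rare", "hill_shannon",
                        "hill_simpson", "jaccard_zip", "morisita_horn_zip",
                        "jaccard_county", "morisita_horn_county",
                        "mean_levenshtein")

#' Nine-statistic summary of one population snapshot
#'
#' In fixed order: proportion of the most common component; proportion of the
#' most rare component; Hill-Shannon diversity; Hill-Simpson diversity;
#' mean pairwise Jaccard similarity across zips; mean pairwise Morisita-Horn
#' similarity across zips; the same two indices across counties; and the mean
#' Levenshtein distance between brands from a random 10% subsample.
#'
#' @param pop a [brand_population] with a spatial registry.
#' @param lev_fraction subsample fraction for the edit-distance statistic.
#' @param lev_seed seed for the edit-distance subsample.
#' @return named numeric vector of length 9.
#' @export
summarize_snapshot <- function(pop, lev_fraction = 0.1, lev_seed = NULL) {
  freqs <- build_frequency_table(pop)
  p <- freqs / sum(freqs)
  mz <- abundance_by_unit(pop, "zip")
  mc <- abundance_by_unit(pop, "county")
  stats::setNames(
    c(prop_most_common(freqs), prop_most_rare(freqs),
      hill_shannon(p), hill_simpson(p),
      jaccard_beta(mz), morisita_horn_beta(mz),
      jaccard_beta(mc), morisita_horn_beta(mc),
      mean_levenshtein(pop, lev_fraction, lev_seed)),
    summary_stat_names)
}

#' Summary vector over snapshot years
#'
#' Concatenates the nine per-year statistics over the requested snapshot
#' years (9 x number of years values; four years give the 36-statistic
#' vector consumed by the ABC stage). The edit-distance subsample is drawn
#' with a year-offset seed so the whole vector is reproducible given `seed`.
#'
#' @param snapshots named list of [brand_population] (names = years).
#' @param snapshot_years years to include, in order.
#' @param seed integer seed for the edit-distance subsamples.
#' @param lev_fraction subsample fraction for the edit-distance statistic.
#' @return named numeric vector of length `9 * length(snapshot_years)`.
#' @export
summarize_series <- function(snapshots, snapshot_years, seed = 1L,
                             lev_fraction = 0.1) {
  missing <- setdiff(as.character(snapshot_years), names(snapshots))
  if (length(missing))
    stop("missing snapshot year(s): ", paste(missing, collapse = ", "))
  out <- lapply(snapshot_years, function(y) {
    v <- summarize_snapshot(snapshots[[as.character(y)]], lev_fraction,
                            lev_seed = derive_seed(seed, y))
    stats::setNames(v, paste0(summary_stat_names, "_", y))
  })
  do.call(c, out)
}
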