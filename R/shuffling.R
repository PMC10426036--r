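#' Predicted prevalence of one component combination
#'
#' The shuffling model predicts how prevalent a combination of components
#' would be if components travelled independently: the product, over the
#' combination's components, of the frequency of each component among brands
#' containing none of the combination's *other* components, multiplied by
#' `N_other` (the brand count excluding exact occurrences of the focal
#' combination). The prediction is 0 when a component is repeated within the
#' combination, when any component occurs in exactly one brand of the
#' dataset, or when any frequency denominator is empty.
#'
#' This scalar implementation is the reference definition; use
#' [shuffle_predictions()] to score all combinations of a dataset at once.
#'
#' @param combo vector of 2 or 3 component labels.
#' @param brands list of component vectors (one per brand; repeats allowed).
#' @return list with `S`, `factors`, `n_other`, `actual`.
#' @export
predicted_prevalence <- function(combo, brands) {
  if (!length(brands)) stop("empty dataset")
  if (!length(combo) %in% 2:3) stop("combo must have 2 or 3 components")
  combo <- as.character(combo)
  n <- length(brands)
  sets <- lapply(brands, function(b) unique(as.character(b)))
  sorted_combo <- sort(combo)
  exact <- sum(vapply(brands, function(b)
    identical(sort(as.character(b)), sorted_combo), logical(1)))
  n_other <- n - exact
  actual <- exact > 0
  zero <- function() list(S = 0, factors = rep(0, length(combo)),
                          n_other = n_other, actual = actual)
  if (anyDuplicated(combo)) return(zero())
  occ <- vapply(combo, function(s)
    sum(vapply(sets, function(b) s %in% b, logical(1))), numeric(1))
  if (any(occ <= 1)) return(zero())
  factors <- vapply(seq_along(combo), function(i) {
    others <- combo[-i]
    eligible <- vapply(sets, function(b) !any(others %in% b), logical(1))
    if (!any(eligible)) return(NA_real_)
    sum(vapply(sets[eligible], function(b) combo[i] %in% b, logical(1))) /
      sum(eligible)
  }, numeric(1))
  if (anyNA(factors)) return(zero())
  list(S = prod(factors) * n_other, factors = factors, n_other = n_other,
       actual = actual)
}

#' Enumerate all unordered k-subsets of a component inventory
#'
#' @param symbols vector of distinct component labels.
#' @param k subset size, 2 or 3.
#' @return matrix with `k` rows, one column per combination (possibly 0
#'   columns).
#' @export
enumerate_combinations <- function(symbols, k) {
  if (!k %in% 2:3) stop("k must be 2 or 3")
  symbols <- unique(symbols)
  if (length(symbols) < k)
    return(matrix(symbols[0], nrow = k, ncol = 0))
  utils::combn(symbols, k)
}

# Sorted-multiset key for exact-match counting, on present-symbol indices.
brand_keys <- function(comp_idx, k, m) {
  srt <- t(apply(comp_idx, 1L, sort))
  if (k == 2L) (srt[, 1L] - 1) * m + srt[, 2L]
  else ((srt[, 1L] - 1) * m + (srt[, 2L] - 1)) * m + srt[, 3L]
}

#' Shuffling-model predictions for every combination in a dataset
#'
#' Vectorised equivalent of applying [predicted_prevalence()] to every
#' unordered `k`-subset of the components present in the dataset.
#'
#' @param comp integer component matrix (`n x 4`, 0 = empty) with entries
#'   indexing `symbols`.
#' @param n_comp integer component counts per row.
#' @param symbols character alphabet indexed by `comp`.
#' @param k combination size (2 or 3).
#' @return data frame with columns `combo` (labels joined by `"|"`), `S`,
#'   `actual`, `k`.
#' @export
shuffle_predictions <- function(comp, n_comp, symbols, k) {
  n <- nrow(comp)
  if (n == 0L) stop("empty dataset")
  if (!k %in% 2:3) stop("k must be 2 or 3")
  present <- sort(unique(as.vector(comp[comp > 0L])))
  m <- length(present)
  empty <- data.frame(combo = character(0), S = numeric(0),
                      actual = logical(0), k = integer(0))
  if (m < k) return(empty)
  idx <- which(comp > 0L)
  M <- matrix(0, n, m)
  M[cbind((idx - 1L) %% n + 1L, match(comp[idx], present))] <- 1
  n_i <- colSums(M)
  TT <- crossprod(M)
  cb <- utils::combn(m, k)

  # exact-match counts: brands whose full component multiset equals a combo
  ex_rows <- which(n_comp == k)
  if (length(ex_rows)) {
    ci <- matrix(match(comp[ex_rows, seq_len(k), drop = FALSE], present),
                 ncol = k)
    bk <- brand_keys(ci, k, m)
    uk <- unique(bk)
    ucnt <- tabulate(match(bk, uk), nbins = length(uk))
  } else {
    uk <- numeric(0); ucnt <- integer(0)
  }
  lookup <- function(keys) {
    pos <- match(keys, uk)
    out <- ifelse(is.na(pos), 0L, ucnt[pos])
    out
  }

  if (k == 2L) {
    a <- cb[1L, ]; b <- cb[2L, ]
    n_ab <- TT[cbind(a, b)]
    den_a <- n - n_i[b]; den_b <- n - n_i[a]
    Fa <- ifelse(den_a > 0, (n_i[a] - n_ab) / den_a, NA_real_)
    Fb <- ifelse(den_b > 0, (n_i[b] - n_ab) / den_b, NA_real_)
    exact <- lookup((a - 1) * m + b)
    S <- Fa * Fb * (n - exact)
    zero <- n_i[a] <= 1 | n_i[b] <= 1 | is.na(Fa) | is.na(Fb)
  } else {
    a <- cb[1L, ]; b <- cb[2L, ]; cc <- cb[3L, ]
    # brands containing all three symbols of a triple (distinct sets of
    # size >= 3 contribute each of their sub-triples)
    trip_keys <- numeric(0)
    dsets <- apply(comp, 1L, function(r) unique(r[r > 0L]), simplify = FALSE)
    big <- which(lengths(dsets) >= 3L)
    if (length(big)) {
      tk <- lapply(big, function(i) {
        s <- sort(match(dsets[[i]], present))
        tri <- utils::combn(s, 3L)
        ((tri[1L, ] - 1) * m + (tri[2L, ] - 1)) * m + tri[3L, ]
      })
      trip_keys <- unlist(tk, use.names = FALSE)
    }
    utk <- unique(trip_keys)
    utc <- tabulate(match(trip_keys, utk), nbins = length(utk))
    key3 <- ((a - 1) * m + (b - 1)) * m + cc
    pos <- match(key3, utk)
    n_all3 <- ifelse(is.na(pos), 0, utc[pos])
    n_ab <- TT[cbind(a, b)]; n_ac <- TT[cbind(a, cc)]; n_bc <- TT[cbind(b, cc)]
    den_a <- n - n_i[b] - n_i[cc] + n_bc
    den_b <- n - n_i[a] - n_i[cc] + n_ac
    den_c <- n - n_i[a] - n_i[b] + n_ab
    Fa <- ifelse(den_a > 0, (n_i[a] - n_ab - n_ac + n_all3) / den_a, NA_real_)
    Fb <- ifelse(den_b > 0, (n_i[b] - n_ab - n_bc + n_all3) / den_b, NA_real_)
    Fc <- ifelse(den_c > 0, (n_i[cc] - n_ac - n_bc + n_all3) / den_c,
                 NA_real_)
    exact <- lookup(key3)
    S <- Fa * Fb * Fc * (n - exact)
    zero <- n_i[a] <= 1 | n_i[b] <= 1 | n_i[cc] <= 1 |
      is.na(Fa) | is.na(Fb) | is.na(Fc)
  }
  S[zero] <- 0
  labels <- matrix(symbols[present[cb]], nrow = k)
  data.frame(combo = apply(labels, 2L, paste, collapse = "|"),
             S = as.numeric(S), actual = exact > 0L, k = k,
             stringsAsFactors = FALSE)
}

#' Pool snapshots into a brand table with period labels
#'
#' Collects the distinct brands appearing across a series of snapshots
#' (identity: components + zip + first year) and labels each as old (`"O"`,
#' appears in the earliest book, i.e. `first_year <= old_year`) or young
#' (`"Y"`, appears only in later books). Quadrants come from the spatial
#' registry.
#'
#' @param snapshots named list of [brand_population].
#' @param old_year year of the earliest book (default: first snapshot year).
#' @return list of class `brand_table`.
#' @export
pool_brands <- function(snapshots, old_year = NULL) {
  stopifnot(length(snapshots) >= 1)
  if (is.null(old_year)) old_year <- snapshots[[1L]]$year
  comp <- do.call(rbind, lapply(snapshots, function(p) p$components))
  zip <- unlist(lapply(snapshots, function(p) p$zip), use.names = FALSE)
  fy <- unlist(lapply(snapshots, function(p) p$first_year),
               use.names = FALSE)
  key <- paste(comp[, 1L], comp[, 2L], comp[, 3L], comp[, 4L], zip, fy,
               sep = "_")
  keep <- !duplicated(key)
  comp <- comp[keep, , drop = FALSE]
  zip <- zip[keep]; fy <- fy[keep]
  spatial <- snapshots[[1L]]$spatial
  structure(list(components = comp,
                 n_comp = as.integer(rowSums(comp > 0L)),
                 period = ifelse(fy <= old_year, "O", "Y"),
                 quadrant = resolve_zip(zip, spatial)$quadrant,
                 zip = zip, first_year = fy,
                 symbols = snapshots[[1L]]$symbols, spatial = spatial),
            class = "brand_table")
}

subset_keys_all <- function() {
  as.vector(outer(outer(c("O", "Y"), c("NW", "NE", "SW", "SE"),
                        paste, sep = "-"),
                  2:3, paste, sep = "-"))
}

#' Split a brand table into the 16 structured subsets
#'
#' Each subset is one combination of period (O/Y), quadrant (NW/NE/SW/SE)
#' and complexity (2/3 components), keyed e.g. `"O-NE-2"`. One- and
#' four-component brands are excluded: the former lack combinatorics, the
#' latter are rare.
#'
#' @param table a `brand_table` (see [pool_brands()]).
#' @return list of class `structured_subsets` with `table` and `subsets`
#'   (named list of 16 integer index vectors, possibly empty).
#' @export
build_structured_subsets <- function(table) {
  keys <- subset_keys_all()
  subsets <- lapply(keys, function(kk) {
    p <- strsplit(kk, "-", fixed = TRUE)[[1L]]
    which(table$period == p[1L] & table$quadrant == p[2L] &
            table$n_comp == as.integer(p[3L]))
  })
  names(subsets) <- keys
  structure(list(table = table, subsets = subsets),
            class = "structured_subsets")
}

mixed_pool <- function(key, table, mode) {
  p <- strsplit(key, "-", fixed = TRUE)[[1L]]
  if (mode == "time")
    which(table$quadrant == p[2L] & table$n_comp == as.integer(p[3L]))
  else
    which(table$period == p[1L] & table$n_comp == as.integer(p[3L]))
}

#' Construct time- and space-mixed counterparts of a structured subset
#'
#' A time-mixed dataset draws the same number of brands as the structured
#' subset from the same quadrant and complexity, ignoring period; a
#' space-mixed dataset draws from the same period and complexity, ignoring
#' quadrant. Sampling is without replacement and seeded.
#'
#' @param key subset key, e.g. `"O-NE-2"`.
#' @param subsets a [build_structured_subsets()] result.
#' @param seed integer seed.
#' @return integer index vector into the pooled table.
#' @export
build_time_mixed <- function(key, subsets, seed = 1L) {
  build_mixed(key, subsets, "time", seed)
}

#' @rdname build_time_mixed
#' @export
build_space_mixed <- function(key, subsets, seed = 1L) {
  build_mixed(key, subsets, "space", seed)
}

build_mixed <- function(key, subsets, mode, seed) {
  n <- length(subsets$subsets[[key]])
  if (n == 0L) stop("structured subset ", key, " is empty")
  pool <- mixed_pool(key, subsets$table, mode)
  if (length(pool) < n)
    stop("mixing pool for ", key, " smaller than the structured subset")
  set.seed(seed)
  sort(sample(pool, n))
}

#' Shuffling-model predictions for one subset of a brand table
#'
#' @param table a `brand_table`.
#' @param idx integer row indices defining the dataset.
#' @param k combination size (2 or 3).
#' @return data frame as in [shuffle_predictions()].
#' @export
table_predictions <- function(table, idx, k) {
  shuffle_predictions(table$components[idx, , drop = FALSE],
                      table$n_comp[idx], table$symbols, k)
}

#' Classify predictions against presence
#'
#' Boundary follows the prevalence scale: a prediction is positive when
#' `S >= 1` (at least one brand expected). True positive: present and
#' `S >= 1`; false positive: absent and `S >= 1`; true negative: absent and
#' `S < 1`; false negative: present and `S < 1`.
#'
#' @param predictions data frame with columns `S` and `actual`.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
classify_predictions <- function(predictions) {
  pos <- predictions$S >= 1
  act <- predictions$actual
  c(TP = sum(act & pos), FP = sum(!act & pos),
    TN = sum(!act & !pos), FN = sum(act & !pos))
}
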