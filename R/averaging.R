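#' Assemble the regression table from structured and mixed predictions
#'
#' One row per enumerated combination per dataset. Combinations with a
#' predicted prevalence of 0 are dropped; the remaining values are
#' log-transformed (`logS = ln S`). Codes: `MIXED` 0 = structured, 1 = mixed;
#' `ACTUAL` 0 = absent, 1 = present; `COMPLEXITY` 0 = two components,
#' 1 = three.
#'
#' @param structured_preds,mixed_preds data frames with columns `combo`, `S`,
#'   `actual`, `k`, `space`, `time` (see [run_averaging_experiment()]), from
#'   matching subset keys.
#' @return data frame of model rows.
#' @export
assemble_model_table <- function(structured_preds, mixed_preds) {
  need <- c("combo", "S", "actual", "k", "space", "time")
  stopifnot(all(need %in% names(structured_preds)),
            all(need %in% names(mixed_preds)))
  sk <- function(d) sort(unique(paste(d$time, d$space, d$k)))
  if (!identical(sk(structured_preds), sk(mixed_preds)))
    stop("structured and mixed predictions cover different subset keys")
  one <- function(d, mixed) {
    d <- d[d$S > 0, , drop = FALSE]
    data.frame(logS = log(d$S), ACTUAL = as.integer(d$actual),
               MIXED = mixed, COMPLEXITY = as.integer(d$k) - 2L,
               combo_id = d$combo, space = d$space, time = d$time,
               stringsAsFactors = FALSE)
  }
  rbind(one(structured_preds, 0L), one(mixed_preds, 1L))
}

lmm_formula <- function(tier) {
  switch(as.character(tier),
         "0" = logS ~ 1 + (1 | combo_id),
         "1" = logS ~ COMPLEXITY + (1 | combo_id),
         "2" = logS ~ COMPLEXITY + ACTUAL + MIXED + (1 | combo_id),
         "3" = logS ~ COMPLEXITY + ACTUAL * MIXED + (1 | combo_id),
         stop("tier must be 0, 1, 2 or 3"))
}

lmm_converged <- function(model) {
  msgs <- model@optinfo$conv$lme4$messages
  is.null(msgs) || !length(msgs)
}

fixef_table <- function(model) {
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  data.frame(term = names(est), estimate = as.numeric(est),
             lower = as.numeric(est - 1.96 * se),
             upper = as.numeric(est + 1.96 * se),
             stringsAsFactors = FALSE)
}

#' Fit the prevalence mixed model at a given tier
#'
#' Likelihood-based (ML, not REML, so AICs are comparable) linear mixed
#' models of log predicted prevalence with a random intercept per
#' combination. Tiers: 0 intercept only; 1 adds `COMPLEXITY`; 2 adds
#' `ACTUAL` and `MIXED`; 3 adds the `ACTUAL x MIXED` interaction. Wald 95%
#' confidence intervals are reported per fixed effect; non-convergence is
#' flagged, never silent.
#'
#' @param rows model table from [assemble_model_table()].
#' @param tier 0-3 (default 3, the full specification).
#' @return list of class `lmm_fit` with `fixed`, `aic`, `converged`, `tier`,
#'   `model`.
#' @export
fit_lmm <- function(rows, tier = 3) {
  if (length(unique(rows$combo_id)) < 2)
    stop("need at least two combination groups")
  model <- lme4::lmer(lmm_formula(tier), data = rows, REML = FALSE)
  structure(list(fixed = fixef_table(model), aic = stats::AIC(model),
                 converged = lmm_converged(model), tier = tier,
                 model = model),
            class = "lmm_fit")
}

#' AIC ladder across model tiers
#'
#' Fits tiers 0-3 and reports the AIC improvement between consecutive tiers
#' (positive delta = the richer tier fits better) and the selected
#' (lowest-AIC) tier.
#'
#' @param rows model table from [assemble_model_table()].
#' @return list with `aic` (per tier), `deltas` (3 values), `best_tier`.
#' @export
aic_ladder <- function(rows) {
  fits <- lapply(0:3, function(t) fit_lmm(rows, t))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  names(aic) <- paste0("tier", 0:3)
  deltas <- aic[-4L] - aic[-1L]
  names(deltas) <- paste0("tier", 0:2, "_to_", 1:3)
  list(aic = aic, deltas = deltas, best_tier = which.min(aic) - 1L,
       fits = fits)
}

#' Intraclass correlations from a random-intercepts-only model
#'
#' Fits `logS ~ 1` with a random intercept per requested grouping and
#' returns, for each, the share of total variance (all groupings plus
#' residual) it explains.
#'
#' @param rows model table from [assemble_model_table()].
#' @param groupings subset of `c("combo_id", "space", "time")`.
#' @return named numeric vector of ICCs in `[0, 1]`.
#' @export
icc <- function(rows, groupings = c("combo_id", "space", "time")) {
  stopifnot(all(groupings %in% c("combo_id", "space", "time")))
  for (g in groupings)
    if (length(unique(rows[[g]])) < 2)
      stop("grouping '", g, "' has fewer than 2 levels")
  fml <- stats::as.formula(paste(
    "logS ~ 1 +", paste(sprintf("(1 | %s)", groupings), collapse = " + ")))
  model <- lme4::lmer(fml, data = rows, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(model))
  tot <- sum(vc$vcov)
  out <- vapply(groupings, function(g) vc$vcov[vc$grp == g] / tot,
                numeric(1))
  stats::setNames(out, groupings)
}

pair_indices <- function(n, max_pairs, seed) {
  total <- n * (n - 1) / 2
  if (total <= max_pairs) {
    ij <- utils::combn(n, 2L)
    return(list(i = ij[1L, ], j = ij[2L, ]))
  }
  set.seed(seed)
  id <- sort(sample(total, max_pairs))
  # decode linear index of the upper triangle (row-major by first element)
  cum <- cumsum((n - 1):1)
  i <- findInterval(id - 1, cum) + 1L
  j <- i + (id - c(0, cum)[i])
  list(i = as.integer(i), j = as.integer(j))
}

#' Temporal-distance analysis
#'
#' Pools old and young brands within each quadrant-complexity cell (e.g.
#' O-NE-2 + Y-NE-2), computes token-level Levenshtein distances between all
#' brand pairs in the cell (optionally capped with seeded subsampling), and
#' fits `LD ~ same_period` with crossed random intercepts for the two
#' compared brands. `same_period` is 1 for old-old and young-young pairs, 0
#' for old-young pairs; a negative coefficient means same-period brands are
#' more similar.
#'
#' @param subsets a [build_structured_subsets()] result.
#' @param seed integer seed for pair subsampling.
#' @param max_pairs cap on pairs per cell (default 200000).
#' @return list of class `tempdist_fit` with `fixed`, `converged`, `rows`,
#'   `degenerate`.
#' @export
temporal_distance_analysis <- function(subsets, seed = 1L,
                                       max_pairs = 200000) {
  table <- subsets$table
  cells <- expand.grid(quadrant = c("NW", "NE", "SW", "SE"), k = 2:3,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    idx <- which(table$quadrant == cells$quadrant[ci] &
                   table$n_comp == cells$k[ci])
    if (length(idx) < 2) {
      warning("cell ", cells$quadrant[ci], "-", cells$k[ci],
              " has fewer than 2 brands; skipped")
      next
    }
    d <- levenshtein_matrix(table$components[idx, , drop = FALSE],
                            table$n_comp[idx])
    pr <- pair_indices(length(idx), max_pairs, derive_seed(seed, ci))
    rows[[ci]] <- data.frame(
      ld = d[cbind(pr$i, pr$j)],
      same_period = as.integer(table$period[idx[pr$i]] ==
                                 table$period[idx[pr$j]]),
      brand_i = as.character(idx[pr$i]), brand_j = as.character(idx[pr$j]),
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0)
    stop("no cell had enough brands for the temporal-distance analysis")
  if (stats::var(rows$ld) == 0) {
    warning("all pairwise distances identical; model degenerate")
    return(structure(list(fixed = NULL, converged = FALSE, rows = rows,
                          degenerate = TRUE), class = "tempdist_fit"))
  }
  model <- lme4::lmer(ld ~ same_period + (1 | brand_i) + (1 | brand_j),
                      data = rows, REML = FALSE)
  structure(list(fixed = fixef_table(model), converged = lmm_converged(model),
                 rows = rows, degenerate = FALSE, model = model),
            class = "tempdist_fit")
}
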