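test_that("predicted prevalence matches the hand-computed example", {
  brands <- list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B"))
  p <- predicted_prevalence(c("A", "B"), brands)
  expect_equal(p$S, 2)
  expect_equal(p$factors, c(1, 1))
  expect_equal(p$n_other, 2)
  expect_true(p$actual)
})

test_that("both zero rules fire", {
  brands <- list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B"))
  expect_equal(predicted_prevalence(c("A", "A"), brands)$S, 0)
  # D occurs in exactly one brand
  brands2 <- c(brands, list(c("A", "D")))
  expect_equal(predicted_prevalence(c("A", "D"), brands2)$S, 0)
  expect_error(predicted_prevalence(c("A", "B"), list()), "empty")
  expect_error(predicted_prevalence("A", brands), "2 or 3")
})

test_that("combination enumeration counts k-subsets", {
  expect_equal(ncol(enumerate_combinations(LETTERS[1:4], 2)), 6L)
  expect_equal(ncol(enumerate_combinations(LETTERS[1:20], 3)), 1140L)
  expect_equal(ncol(enumerate_combinations("A", 2)), 0L)
  expect_error(enumerate_combinations(LETTERS[1:4], 4), "2 or 3")
})

test_that("vectorised predictions agree with the scalar reference", {
  for (s in 1:4) for (k in 2:3) {
    set.seed(s)
    symbols <- LETTERS[1:8]
    brands <- replicate(30, sample(symbols, k, replace = TRUE,
                                   prob = 8:1), simplify = FALSE)
    bm <- brands_to_matrix(brands, symbols)
    batch <- shuffle_predictions(bm$comp, bm$n_comp, symbols, k)
    for (i in seq_len(nrow(batch))) {
      combo <- strsplit(batch$combo[i], "|", fixed = TRUE)[[1]]
      ref <- predicted_prevalence(combo, brands)
      expect_equal(batch$S[i], ref$S, tolerance = 1e-12)
      expect_equal(batch$actual[i], ref$actual)
    }
  }
})

test_that("prevalence is invariant to brand order and symbol relabeling", {
  set.seed(7)
  symbols <- LETTERS[1:6]
  brands <- replicate(25, sample(symbols, 2), simplify = FALSE)
  bm <- brands_to_matrix(brands, symbols)
  base <- shuffle_predictions(bm$comp, bm$n_comp, symbols, 2)

  perm <- sample(25)
  reord <- shuffle_predictions(bm$comp[perm, ], bm$n_comp[perm], symbols, 2)
  expect_equal(reord[order(reord$combo), ], base[order(base$combo), ],
               ignore_attr = TRUE)

  relab <- c(F1 = "A", F2 = "B", F3 = "C", F4 = "D", F5 = "E", F6 = "F")
  brands2 <- lapply(brands, function(b) names(relab)[match(b, relab)])
  bm2 <- brands_to_matrix(brands2, names(relab))
  alt <- shuffle_predictions(bm2$comp, bm2$n_comp, names(relab), 2)
  expect_equal(sort(alt$S), sort(base$S))
})

test_that("present combinations score higher than absent under the null", {
  diffs <- vapply(1:10, function(s) {
    set.seed(s)
    symbols <- LETTERS[1:10]
    brands <- replicate(80, sample(symbols, 2, replace = TRUE,
                                   prob = 10:1), simplify = FALSE)
    bm <- brands_to_matrix(brands, symbols)
    d <- shuffle_predictions(bm$comp, bm$n_comp, symbols, 2)
    d <- d[d$S > 0, ]
    mean(d$S[d$actual]) - mean(d$S[!d$actual])
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("structured subsets partition by period, quadrant and complexity", {
  tb <- generate_wholesale_copy_table(n_per_cell = 50, seed = 2)
  subs <- build_structured_subsets(tb)
  expect_length(subs$subsets, 16L)
  expect_true(all(lengths(subs$subsets) == 50L))
  idx <- subs$subsets[["O-NE-2"]]
  expect_true(all(tb$period[idx] == "O"))
  expect_true(all(tb$quadrant[idx] == "NE"))
  expect_true(all(tb$n_comp[idx] == 2L))

  # 1- and 4-component brands are excluded
  tb$components[1, ] <- c(5L, 0L, 0L, 0L)
  tb$components[2, ] <- c(5L, 6L, 7L, 8L)
  tb$n_comp <- as.integer(rowSums(tb$components > 0L))
  subs2 <- build_structured_subsets(tb)
  expect_equal(sum(lengths(subs2$subsets)), nrow(tb$components) - 2L)
})

test_that("mixed datasets match their structured twins in size and strata", {
  tb <- generate_wholesale_copy_table(n_per_cell = 50, seed = 4)
  subs <- build_structured_subsets(tb)
  for (key in c("O-NE-2", "Y-SW-3")) {
    n <- length(subs$subsets[[key]])
    p <- strsplit(key, "-")[[1]]
    tm <- build_time_mixed(key, subs, seed = 5)
    expect_length(tm, n)
    expect_true(all(tb$quadrant[tm] == p[2]))
    expect_true(all(tb$n_comp[tm] == as.integer(p[3])))
    expect_true(any(tb$period[tm] != p[1]))  # period genuinely mixed
    sm <- build_space_mixed(key, subs, seed = 5)
    expect_length(sm, n)
    expect_true(all(tb$period[sm] == p[1]))
    expect_true(all(tb$n_comp[sm] == as.integer(p[3])))
  }
  expect_identical(build_time_mixed("O-NE-2", subs, seed = 5),
                   build_time_mixed("O-NE-2", subs, seed = 5))

  # a pool with a single period makes the time-mixed set a resample of the
  # structured one
  tb1 <- tb
  keep <- tb1$period == "O"
  tb1 <- structure(list(components = tb1$components[keep, ],
                        n_comp = tb1$n_comp[keep], period = tb1$period[keep],
                        quadrant = tb1$quadrant[keep], zip = tb1$zip[keep],
                        symbols = tb1$symbols, spatial = tb1$spatial),
                   class = "brand_table")
  subs1 <- build_structured_subsets(tb1)
  tm1 <- build_time_mixed("O-NE-2", subs1, seed = 6)
  expect_setequal(tm1, subs1$subsets[["O-NE-2"]])
})

test_that("confusion classification uses the S >= 1 boundary", {
  preds <- data.frame(S = c(2, 1, 0.5, 0.2), actual = c(TRUE, FALSE, FALSE,
                                                        TRUE))
  cls <- classify_predictions(preds)
  expect_equal(cls, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_equal(sum(cls), nrow(preds))
})

test_that("pooled snapshots carry period labels from the first book", {
  cfg <- small_config()
  snaps <- generate_observed_series(cfg)
  tbl <- pool_brands(snaps)
  expect_true(all(tbl$period[tbl$first_year <= 1990] == "O"))
  expect_true(all(tbl$period[tbl$first_year > 1990] == "Y"))
  expect_true(all(tbl$quadrant %in% c("NW", "NE", "SW", "SE")))
  # pooling is deduplicated: no more rows than brands ever created
  expect_lte(nrow(tbl$components),
             cfg$n_initial_brands + cfg$N_new * (length(cfg$years) - 1L))
})
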