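test_that("frequency tables count component tokens with multiplicity", {
  pop <- make_population(list(c(1, 2), c(1, 1, 3)), c("z1", "z1"))
  ft <- build_frequency_table(pop)
  expect_equal(unname(ft[1:3]), c(3L, 1L, 1L))
  expect_equal(sum(ft), sum(pop$n_comp))

  single <- make_population(list(1), "z1")
  expect_equal(unname(build_frequency_table(single)[1]), 1L)
})

test_that("frequency-dependent sampling follows the exponent law", {
  f <- c(A = 3L, B = 1L)
  expect_equal(unname(component_sampling_probs(f, 0)), c(0.5, 0.5))
  expect_equal(unname(component_sampling_probs(f, 1)), c(0.75, 0.25))
  expect_equal(unname(component_sampling_probs(f, 2)), c(0.9, 0.1))
  expect_equal(unname(component_sampling_probs(f, -1)), c(0.25, 0.75))

  # zero-count symbols are excluded from the support, even for C <= 0
  f2 <- c(A = 3L, B = 0L, C = 1L)
  p2 <- component_sampling_probs(f2, -2)
  expect_equal(unname(p2[2]), 0)
  expect_equal(sum(p2), 1)
  expect_error(component_sampling_probs(c(A = 0L), 1), "zero")

  # P(a)/P(b) strictly increasing in C when count a > count b
  ratios <- sapply(c(-1, 0, 1, 2), function(C) {
    p <- component_sampling_probs(f, C)
    p[["A"]] / p[["B"]]
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("truncated-Poisson complexity distribution matches closed form", {
  q3 <- complexity_pmf(3)
  expect_equal(q3[["2"]], q3[["3"]])
  expect_equal(unname(q3), c(0.19512, 0.29268, 0.29268, 0.21951),
               tolerance = 1e-4)
  expect_equal(sum(q3), 1)
  expect_equal(which.max(complexity_pmf(15)), c("4" = 4L))
  expect_gt(complexity_pmf(1e-6)[["1"]], 0.999)
  expect_error(complexity_pmf(0), "positive")
  expect_error(complexity_pmf(-2), "positive")
})

test_that("complexity pmf matches a rejection-sampling oracle", {
  set.seed(11)
  draws <- stats::rpois(2e5, 2.4)
  draws <- draws[draws >= 1 & draws <= 4]
  emp <- tabulate(draws, 4) / length(draws)
  expect_equal(emp, unname(complexity_pmf(2.4)), tolerance = 0.02)
})

test_that("new brands draw from the existing component pool", {
  params <- abm_params(C = 1, lambda = 3, N_new = 1, N_old = 0,
                       zip_probs = c(z1 = 1), years = 1990:1991)
  set.seed(3)
  b <- create_brand(c(A = 5L), params)
  expect_true(all(b$components == 1L))

  f <- c(A = 4L, B = 0L, C = 2L)
  set.seed(5)
  for (i in 1:20) expect_false(2L %in% create_brand(f, params)$components)

  set.seed(8); b1 <- create_brand(f, params)
  set.seed(8); b2 <- create_brand(f, params)
  expect_identical(b1, b2)
})

test_that("empirical create_brand frequencies match the sampling law", {
  f <- c(A = 5L, B = 3L, C = 2L)
  params <- abm_params(C = 1.3, lambda = 3, N_new = 1, N_old = 0,
                       zip_probs = c(z1 = 1), years = 1990:1991)
  set.seed(21)
  toks <- unlist(replicate(20000, create_brand(f, params)$components,
                           simplify = FALSE))
  obs <- tabulate(toks, 3)
  p <- component_sampling_probs(f, 1.3)
  gof <- stats::chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.001)
})

test_that("yearly stepping keeps the turnover bookkeeping", {
  cfg <- small_config()
  init <- generate_initial_population(cfg)
  zp <- attr(init, "zip_probs")
  params <- abm_params(C = 1, lambda = 3, N_new = 5, N_old = 3,
                       zip_probs = zp, years = cfg$years)
  set.seed(2)
  nxt <- step_year(init, params)
  expect_equal(n_brands(nxt), n_brands(init) + 2L)
  expect_equal(nxt$year, init$year + 1L)

  id_params <- abm_params(C = 1, lambda = 3, N_new = 0, N_old = 0,
                          zip_probs = zp, years = cfg$years)
  same <- step_year(init, id_params)
  expect_equal(same$components, init$components)

  tiny <- make_population(list(1, 2), c("z1", "z1"))
  kill <- abm_params(C = 1, lambda = 3, N_new = 0, N_old = 2,
                     zip_probs = c(z1 = 1), years = 1990:1991)
  expect_error(step_year(tiny, kill), "empty")
})

test_that("multi-year runs are deterministic with exact size arithmetic", {
  cfg <- synthetic_config(seed = 5)
  init <- generate_initial_population(cfg)
  params <- abm_params(C = 1, lambda = 3, N_new = 180, N_old = 150,
                       zip_probs = attr(init, "zip_probs"),
                       years = 1990:2016, seed = 42)
  snaps <- run_abm(init, params, snapshot_years = c(1990, 2016))
  expect_equal(n_brands(snaps[["1990"]]), 2000L)
  expect_equal(n_brands(snaps[["2016"]]), 2000L + 26L * 30L)

  snaps2 <- run_abm(init, params, snapshot_years = c(1990, 2016))
  expect_identical(snaps[["2016"]]$components, snaps2[["2016"]]$components)

  one <- abm_params(C = 1, lambda = 3, N_new = 10, N_old = 5,
                    zip_probs = attr(init, "zip_probs"), years = 1990)
  expect_identical(run_abm(init, one), list("1990" = init))
})

test_that("turnover estimation averages appearance rates over year gaps", {
  # 1990 -> 1991: 10 appear, 4 disappear; 1991 -> 1992: 14 appear, 6 disappear
  mk <- function(ids, year) make_population(as.list(ids), rep("z1",
                                                              length(ids)),
                                            year = year, first_year = 1990,
                                            n_symbols = 200)
  s1 <- mk(1:20, 1990)
  s2 <- mk(c(5:20, 21:30), 1991)      # drops 1:4, adds 21:30
  s3 <- mk(c(5:24, 31:44), 1992)      # drops 25:30 (6), adds 31:44 (14)
  est <- estimate_turnover(list(s1, s2, s3))
  expect_equal(est$N_new, 12L)
  expect_equal(est$N_old, 5L)

  est0 <- estimate_turnover(list(s1, mk(1:20, 1991)))
  expect_equal(est0$N_new, 0L)
  expect_equal(est0$N_old, 0L)

  # uneven gap: 36 appearances over an 18-year gap is 2 per year
  s4 <- mk(c(1:20, 101:136), 2008)
  gap <- estimate_turnover(list(s1, s4))
  expect_equal(gap$N_new, 2L)
  expect_error(estimate_turnover(list(s1)), "two snapshots")
})

test_that("strong conformity concentrates the component distribution", {
  cfg <- small_config(C_true = 10, years = 1990:2005)
  deltas <- sapply(1:5, function(s) {
    c2 <- cfg; c2$seed <- s
    snaps <- generate_observed_series(c2)
    f0 <- build_frequency_table(snaps[[1]])
    f1 <- build_frequency_table(snaps[[length(snaps)]])
    max(f1) / sum(f1) - max(f0) / sum(f0)
  })
  expect_gt(mean(deltas), 0)
})
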