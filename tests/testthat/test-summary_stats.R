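test_that("dominance proportions come from the token counts", {
  f <- c(A = 3L, B = 1L)
  expect_equal(prop_most_common(f), 0.75)
  expect_equal(prop_most_rare(f), 0.25)
  expect_equal(prop_most_common(c(A = 7L)), 1)
  expect_equal(prop_most_rare(c(A = 7L)), 1)
  u <- stats::setNames(rep(2L, 5), LETTERS[1:5])
  expect_equal(prop_most_common(u), 0.2)
  expect_equal(prop_most_rare(u), 0.2)
  expect_error(prop_most_common(c(A = 0L)), "empty")
})

test_that("Hill numbers match closed forms and are ordered", {
  expect_equal(hill_shannon(rep(0.25, 4)), 4)
  expect_equal(hill_simpson(rep(0.25, 4)), 4)
  expect_equal(hill_shannon(1), 1)
  expect_equal(hill_simpson(1), 1)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(hill_shannon(p), 2^1.5)
  expect_equal(hill_simpson(p), 1 / 0.375)
  expect_error(hill_shannon(c(0.5, 0.2)), "probability")

  set.seed(14)
  for (i in 1:30) {
    q <- stats::rgamma(sample(2:12, 1), 1)
    q <- q / sum(q)
    expect_gte(hill_shannon(q), hill_simpson(q) - 1e-10)
  }
})

test_that("beta-diversity similarities match hand-computed examples", {
  same <- rbind(c(2, 1, 0), c(2, 1, 0))
  expect_equal(jaccard_beta(same), 1)
  expect_equal(morisita_horn_beta(same), 1)

  disjoint <- rbind(c(2, 1, 0, 0), c(0, 0, 3, 1))
  expect_equal(jaccard_beta(disjoint), 0)
  expect_equal(morisita_horn_beta(disjoint), 0)

  # incidence {a,b,c} vs {b,c,d}: 2 shared / 4 in union
  inc <- rbind(c(1, 1, 1, 0), c(0, 1, 1, 1))
  expect_equal(jaccard_beta(inc), 0.5)

  # counts x = (2,0,2), y = (1,1,0)
  expect_equal(morisita_horn_beta(rbind(c(2, 0, 2), c(1, 1, 0))), 0.5)

  expect_error(jaccard_beta(rbind(c(1, 1, 0))), "two non-empty")
  # zero-token units are dropped, not counted
  expect_equal(jaccard_beta(rbind(c(1, 1, 1, 0), c(0, 1, 1, 1), c(0, 0, 0, 0))),
               0.5)
})

test_that("beta similarities are symmetric and relabeling-invariant", {
  set.seed(3)
  m <- matrix(rpois(4 * 7, 2), 4, 7)
  m[1, ] <- m[1, ] + 1  # no empty unit
  perm_units <- m[sample(4), ]
  perm_syms <- m[, sample(7)]
  expect_equal(jaccard_beta(perm_units), jaccard_beta(m))
  expect_equal(jaccard_beta(perm_syms), jaccard_beta(m))
  expect_equal(morisita_horn_beta(perm_units), morisita_horn_beta(m))
  expect_equal(morisita_horn_beta(perm_syms), morisita_horn_beta(m))
  # merging two incidence-identical units leaves their similarity to any
  # other unit unchanged (incidence ignores abundance)
  a <- c(1, 1, 0, 1, 0, 0, 0)
  b <- m[2, ]
  expect_equal(jaccard_beta(rbind(a + a, b)), jaccard_beta(rbind(a, b)))
})

test_that("token Levenshtein matches a dynamic-programming oracle", {
  pop0 <- make_population(list(c(1, 2), c(1, 2), c(1, 2)), rep("z1", 3))
  expect_equal(mean_levenshtein(pop0, fraction = 1), 0)
  pop1 <- make_population(list(c(1, 2), c(1, 3)), c("z1", "z1"))
  expect_equal(mean_levenshtein(pop1, fraction = 1), 1)
  pop2 <- make_population(list(1, c(2, 3)), c("z1", "z1"))
  expect_equal(mean_levenshtein(pop2, fraction = 1), 2)

  # exhaustive check on all token sequences of length 1-3 over 3 symbols
  seqs <- c(lapply(1:3, function(x) x),
            unlist(lapply(1:3, function(a) lapply(1:3, function(b) c(a, b))),
                   recursive = FALSE),
            unlist(lapply(1:3, function(a) unlist(lapply(1:3, function(b)
              lapply(1:3, function(cc) c(a, b, cc))), recursive = FALSE)),
              recursive = FALSE))
  comp <- matrix(0L, length(seqs), 4L)
  for (i in seq_along(seqs)) comp[i, seq_along(seqs[[i]])] <- seqs[[i]]
  D <- levenshtein_matrix(comp, lengths(seqs))
  for (i in seq_along(seqs)) for (j in seq_along(seqs))
    expect_equal(D[i, j], lev_dp(seqs[[i]], seqs[[j]]))

  # metric axioms on the pair level
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))
  set.seed(6)
  for (r in 1:500) {
    ijk <- sample(length(seqs), 3, replace = TRUE)
    expect_lte(D[ijk[1], ijk[3]], D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]])
  }
})

test_that("summary vectors have fixed layout and order invariance", {
  cfg <- small_config()
  snaps <- generate_observed_series(cfg)
  sy <- default_snapshot_years(cfg$years)
  v <- summarize_series(snaps, sy, seed = 5)
  expect_length(v, 36L)
  expect_equal(names(v)[1:2], c("prop_most_common_1998",
                                "prop_most_rare_1998"))
  v1 <- summarize_series(snaps, sy[1], seed = 5)
  expect_length(v1, 9L)
  expect_error(summarize_series(snaps, 1885), "missing snapshot")

  # Hill-Shannon >= Hill-Simpson within each year
  expect_true(all(v[grep("hill_shannon", names(v))] >=
                    v[grep("hill_simpson", names(v))]))

  # permuting storage order changes nothing except (possibly) the seeded
  # Levenshtein subsample
  pop <- snaps[[as.character(sy[1])]]
  set.seed(31)
  perm <- brandevo:::subset_population(pop, sample(n_brands(pop)))
  s_orig <- summarize_snapshot(pop, lev_seed = 1)
  s_perm <- summarize_snapshot(perm, lev_seed = 1)
  expect_equal(s_perm[1:8], s_orig[1:8])

  # the same seed reproduces the full vector exactly
  expect_identical(v, summarize_series(snaps, sy, seed = 5))
})
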