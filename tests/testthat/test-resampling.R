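test_that("resampled matrices are reproducible and prefix-stable in B", {
  d <- tiny_dataset()
  plan <- resampling_plan(n_matrices = 20, seed = 99)
  m1 <- resample_matrices(d, plan)
  m2 <- resample_matrices(d, plan)
  expect_identical(m1, m2)
  # enlarging B leaves earlier matrices untouched
  m3 <- resample_matrices(d, resampling_plan(n_matrices = 35, seed = 99))
  expect_identical(m3[1:20], m1[1:20])
  # every resample spans the full design
  expect_true(all(vapply(m1, function(m) all(dim(m$eggs) == c(3, 2)), logical(1))))
})

test_that("degenerate replication collapses the resampling distribution", {
  # one oviposition replicate and exactly k cups per cell: no randomness left
  d <- tiny_dataset()
  ovi1 <- d$oviposition[d$oviposition$replicate == 1, ]
  d1 <- community_dataset(d$catalog, d$roster, ovi1, d$survival,
                          cups_range = c(5L, 5L))
  est <- alpha_distributions(d1, resampling_plan(n_matrices = 30, seed = 3))
  expect_true(all(est$summary$var_alpha == 0))
  agg <- aggregate_survival(d1$survival)
  mats <- resample_matrices(d1, resampling_plan(n_matrices = 5, seed = 3))
  for (m in mats)
    expect_equal(m$survival[cbind(as.character(agg$fruit_id), agg$species)],
                 agg$survival)
  # a species restricted to one host has alpha exactly 1 with zero variance
  pref <- est$summary[est$summary$measure == "eggs", ]
  expect_equal(pref$mean_alpha[pref$species == "spec_a"], 1)
})

test_that("sampling five cups without replacement has the hypergeometric mean", {
  surv <- data.frame(species = "spec_a", fruit_id = 1L, cup = 1:10,
                     pupated = c(1L, 1L, rep(0L, 8)))
  ovi <- data.frame(species = "spec_a", fruit_id = 1L, assay = "no_choice",
                    replicate = 1L, n_females = 5L, eggs = 4L)
  catalog <- tiny_catalog()[1, ]
  roster <- tiny_roster()[1, ]
  d <- community_dataset(catalog, roster, ovi, surv, cups_range = c(10L, 10L))
  mats <- resample_matrices(d, resampling_plan(n_matrices = 2000, seed = 17))
  draws <- vapply(mats, function(m) m$survival["1", "spec_a"], numeric(1))
  # X ~ Hypergeom(N=10, K=2, n=5); E[X/5] = 0.2, Var[X/5] = Var(X)/25
  se <- sqrt((5 * 0.2 * 0.8 * (5 / 9)) / 25 / 2000)
  expect_lt(abs(mean(draws) - 0.2), 3 * se)
})

test_that("cells below the survival draw size fall back to all cups", {
  d <- tiny_dataset()
  surv <- d$survival[!(d$survival$species == "spec_a" & d$survival$fruit_id == 2 &
                         d$survival$cup > 3), ]
  d2 <- community_dataset(d$catalog, d$roster, d$oviposition, surv,
                          cups_range = c(3L, 5L))
  mats <- resample_matrices(d2, resampling_plan(n_matrices = 10, seed = 1))
  expect_match(attr(mats, "fallback_cells"), "2 x spec_a", all = FALSE)
  agg <- aggregate_survival(surv)
  v <- agg$survival[agg$species == "spec_a" & agg$fruit_id == 2]
  for (m in mats) expect_equal(m$survival["2", "spec_a"], v)
})

test_that("zero-replicate oviposition cells are an error listing the cells", {
  d <- tiny_dataset()
  ovi <- d$oviposition[!(d$oviposition$species == "gen_b" &
                           d$oviposition$fruit_id == 2), ]
  d2 <- community_dataset(d$catalog, d$roster, ovi, d$survival)
  expect_error(resample_matrices(d2, resampling_plan(n_matrices = 2, seed = 1)),
               "2 x gen_b")
})

test_that("all-zero egg draws are redrawn so alpha stays defined", {
  # spec_a lays eggs only in replicate 1; a draw of replicate 2 everywhere
  # would be an all-zero profile, so the column must be redrawn
  grid <- expand.grid(species = c("spec_a", "gen_b"), fruit_id = 1:3,
                      replicate = 1:2, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  eggs <- ifelse(grid$species == "spec_a",
                 ifelse(grid$replicate == 1, 5L, 0L), 8L)
  ovi <- data.frame(grid[c("species", "fruit_id")], assay = "no_choice",
                    replicate = grid$replicate, n_females = 5L, eggs = eggs,
                    stringsAsFactors = FALSE)
  d <- community_dataset(tiny_catalog(), tiny_roster(), ovi,
                         tiny_dataset()$survival)
  est <- alpha_distributions(d, resampling_plan(n_matrices = 100, seed = 23))
  pref <- est$summary[est$summary$measure == "eggs", ]
  expect_equal(pref$n_dropped, c(0L, 0L))
  expect_true(all(pref$n_resamples == 100L))
})

test_that("largest-gap classification recovers the guild structure", {
  sim <- default_sim()
  est <- alpha_distributions(sim$dataset, resampling_plan(n_matrices = 60, seed = 5))
  cl <- classify_by_alpha(est, sim$dataset$roster)
  expect_equal(cl$assigned_guild, cl$a_priori_guild)
  expect_true(all(cl$agrees))
  expect_gte(cl$separation_score[1], 0.95)
  expect_false(attr(cl, "degenerate"))
})

test_that("classification flags a degenerate all-equal split", {
  d <- tiny_dataset(eggs = rep(4L, 12))   # both species uniform: equal alphas
  est <- alpha_distributions(d, resampling_plan(n_matrices = 10, seed = 2))
  cl <- classify_by_alpha(est, d$roster)
  expect_true(attr(cl, "degenerate"))
  expect_true(is.finite(cl$separation_score[1]))
})

test_that("largest-gap split separates low from high means", {
  # synthetic estimates object with known means
  means <- c(1.2, 1.5, 9, 10, 11, 12)
  sp <- paste0("s", 1:6)
  est <- structure(list(
    summary = data.frame(species = sp, measure = "eggs", mean_alpha = means,
                         var_alpha = 0, n_resamples = 2, n_dropped = 0,
                         stringsAsFactors = FALSE),
    samples = data.frame(matrix_index = rep(1:2, each = 6),
                         species = rep(sp, 2), measure = "eggs",
                         alpha = rep(means, 2), stringsAsFactors = FALSE),
    plan = resampling_plan(n_matrices = 2, seed = 1)),
    class = "alpha_distributions")
  roster <- data.frame(species = sp,
                       guild = rep(c("specialist", "generalist"), c(2, 4)))
  cl <- classify_by_alpha(est, roster)
  expect_setequal(cl$species[cl$assigned_guild == "specialist"], c("s1", "s2"))
  expect_equal(cl$separation_score[1], 1)
})
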