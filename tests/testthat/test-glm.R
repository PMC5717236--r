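test_that("design matrices use treatment coding and drop aliased columns", {
  d5 <- data.frame(y = 1:5)
  dm <- build_design_matrix(character(0), d5)
  expect_equal(dim(dm$X), c(5L, 1L))
  expect_true(all(dm$X == 1))

  df <- data.frame(f = factor(rep(letters[1:3], 4)), x = rnorm(12))
  dm <- build_design_matrix("f", df)
  expect_equal(ncol(dm$X), 3L)          # intercept + 2 dummies
  expect_true("(Intercept)" %in% colnames(dm$X))

  # 29-level factor crossed with a continuous covariate: 58 columns
  sim <- default_sim()
  est_alpha <- species_alpha(suppressWarnings(
    build_interaction_matrix(sim$dataset, "eggs", "sum")))
  rt <- replicate_egg_table(sim$dataset, est_alpha)
  dm <- build_design_matrix(c("fruit", "alpha", "fruit:alpha"), rt)
  expect_equal(ncol(dm$X), 58L)
  expect_length(dm$dropped, 0L)

  # a duplicated covariate is aliased and dropped
  df$x2 <- df$x
  dm <- build_design_matrix(c("x", "x2"), df)
  expect_equal(ncol(dm$X), 2L)
  expect_length(dm$dropped, 1L)

  expect_error(build_design_matrix("g", data.frame(g = factor(rep("a", 4)))),
               "single level")
})

test_that("IRLS reproduces closed-form quasi-Poisson fits", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_quasipoisson(X, c(1, 2, 3))
  expect_equal(unname(fit$coefficients), log(2), tolerance = 1e-9)
  expect_equal(fit$fitted, rep(2, 3), tolerance = 1e-9)

  fit0 <- fit_quasipoisson(X, c(2, 2, 2))
  expect_equal(fit0$deviance, 0, tolerance = 1e-12)
  expect_equal(fit0$dispersion, 0, tolerance = 1e-12)

  # saturated model: one parameter per observation, deviance 0
  Xs <- diag(4)
  colnames(Xs) <- paste0("o", 1:4)
  fits <- fit_quasipoisson(Xs, c(3, 1, 7, 2))
  expect_equal(fits$deviance, 0, tolerance = 1e-10)
  expect_equal(fits$df_residual, 0L)

  expect_error(fit_quasipoisson(X, c(1, -2, 3)), "non-negative")
})

test_that("the IRLS engine agrees with the reference GLM implementation", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(25:70, 1)
    df <- data.frame(x = rnorm(n), f = factor(sample(letters[1:3], n, TRUE)))
    mu <- exp(0.5 + 0.4 * df$x + c(a = 0, b = 0.5, c = -0.4)[df$f])
    df$y <- rnbinom(n, size = 1.5, mu = mu)
    if (sum(df$y) == 0) next
    dm <- build_design_matrix(c("x", "f"), df)
    fit <- fit_quasipoisson(dm$X, df$y)
    ref <- glm(y ~ x + f, df, family = quasipoisson(),
               control = glm.control(epsilon = 1e-12))
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
    expect_equal(fit$dispersion, summary(ref)$dispersion, tolerance = 1e-6)
  }
})

test_that("sequential deviance telescopes the degrees of freedom", {
  sim <- default_sim()
  est_alpha <- species_alpha(suppressWarnings(
    build_interaction_matrix(sim$dataset, "eggs", "sum")))
  cell <- cell_egg_table(sim$dataset, est_alpha)
  tab <- sequential_deviance(c("survival", "guild", "survival:guild"), cell)
  expect_true(all(tab$delta_dev >= -1e-8))
  expect_equal(sum(tab$delta_df) + attr(tab, "df_residual_full"),
               attr(tab, "n_obs") - 1L)
  expect_equal(tab$df_residual[nrow(tab)], attr(tab, "df_residual_full"))
  # deviance drops are order-dependent but totals agree between orderings
  tab2 <- sequential_deviance(c("guild", "survival", "survival:guild"), cell)
  expect_equal(sum(tab$delta_dev), sum(tab2$delta_dev), tolerance = 1e-6)
  # chi-square flavour gives the same deviance decomposition
  tabc <- sequential_deviance(c("survival", "guild", "survival:guild"), cell,
                              pvalue = "chisq")
  expect_equal(tabc$delta_dev, tab$delta_dev)
  expect_false(identical(tabc$p, tab$p))
})

test_that("quasi-F tests of a null term are calibrated near the nominal level", {
  set.seed(33)
  rej <- replicate(300, {
    n <- 80
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    mu <- exp(3 + 0.5 * df$x1)
    df$y <- rnbinom(n, size = mu / 2, mu = mu)   # phi = 3
    sequential_deviance(c("x1", "x2"), df, "y")$p[2] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.10)
})

test_that("zero filtering removes exactly the flagged cells", {
  tab <- data.frame(eggs = c(0, 5, 3, 0, 9, 2, 7, 1, 4, 6),
                    survival = c(0.2, 0, 0.5, 0, 0.1, 0.3, 0, 0.4, 0.6, 0.2))
  expect_equal(nrow(zero_filter(tab, "survival_zeros")), 7L)
  expect_equal(nrow(zero_filter(tab, "oviposition_zeros")), 8L)
  both <- zero_filter(tab, "both")
  drop_union <- sum(tab$eggs == 0 | tab$survival == 0)
  expect_equal(nrow(both), nrow(tab) - drop_union)
  expect_equal(attr(both, "removed"), drop_union)
  clean <- tab[tab$eggs > 0 & tab$survival > 0, ]
  expect_equal(as.data.frame(zero_filter(clean, "both")), clean,
               ignore_attr = TRUE)
  expect_error(zero_filter(tab[tab$eggs == 0, ], "oviposition_zeros"),
               "every cell")
})

test_that("the model suite wires each analysis to its observation unit", {
  sim <- default_sim()
  est <- alpha_distributions(sim$dataset, resampling_plan(n_matrices = 40, seed = 13))
  suite <- model_suite(sim$dataset, est)
  expect_named(suite, c("preference_by_fruit_alpha", "guild_coupling",
                        "generalists_survival", "specialists_survival",
                        "generalists_by_species", "specialists_by_species",
                        "specialists_survival_no_zero_survival",
                        "specialists_survival_no_zero_eggs",
                        "specialists_survival_no_zero_both"))
  # replicate-level model: 6 reps x 29 fruits x 6 species observations
  expect_equal(attr(suite$preference_by_fruit_alpha, "n_obs"), 1044L)
  expect_equal(suite$preference_by_fruit_alpha$delta_df[1], 28L)
  # cell-level models: df bookkeeping for every table
  for (tab in suite)
    expect_equal(sum(tab$delta_df) + attr(tab, "df_residual_full"),
                 attr(tab, "n_obs") - 1L)
  flat <- deviance_suite_table(suite)
  expect_true(all(c("model_id", "term", "F", "p", "dispersion") %in% names(flat)))
})
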