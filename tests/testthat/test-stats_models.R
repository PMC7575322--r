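# Synthetic pair tables for the model layer: response built from known fixed
# effects, a per-animal intercept, and i.i.d. noise.
make_model_table <- function(n_pairs = 80, n_animals = 4, beta = 0.8,
                             animal_sd = 0.02, resid_sd = 0.02, seed = 1) {
  set.seed(seed)
  animal <- rep(sprintf("a%d", seq_len(n_animals)), length.out = n_pairs)
  u <- stats::rnorm(n_animals, 0, animal_sd)
  x <- stats::runif(n_pairs, 0, 0.1)
  data.frame(animal_id = animal, x = x,
             y = beta * x + u[match(animal, unique(animal))] +
               stats::rnorm(n_pairs, 0, resid_sd))
}

test_that("a constant response gives zero slopes", {
  tab <- make_model_table(seed = 2)
  tab$y <- 0
  fit <- suppressWarnings(suppressMessages(fit_lmm(tab, "y", "x")))
  expect_lt(max(abs(fit$coefficients$estimate)), 1e-10)
})

test_that("fit_lmm recovers a planted slope within its confidence interval", {
  tab <- make_model_table(beta = 0.8, seed = 3)
  fit <- fit_lmm(tab, "y", "x")
  est <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(est$estimate - 0.8), 2.5 * est$se)
  expect_equal(fit$n_obs, 80L)
  expect_equal(fit$n_groups, 4L)
  expect_equal(fit$method, "ML")
})

test_that("single-group data degrades to a plain linear model with a warning", {
  tab <- make_model_table(seed = 4)
  tab$animal_id <- "a1"
  expect_warning(fit <- fit_lmm(tab, "y", "x"), "fewer than 2 groups")
  expect_s3_class(fit$model, "lm")
  expect_null(fit$group)
})

test_that("missing rows are dropped listwise with a logged count", {
  tab <- make_model_table(seed = 5)
  tab$x[c(1, 7)] <- NA
  expect_message(fit <- fit_lmm(tab, "y", "x"), "dropped 2 row")
  expect_equal(fit$n_obs, 78L)
})

test_that("random-effect LRT is zero for identical models and non-negative when nested", {
  tab <- make_model_table(seed = 6)
  m0 <- fit_lmm(tab, "y", "x", group = NULL)
  same <- lrt_random_effect(m0, m0)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)

  for (s in 1:5) {
    tb <- make_model_table(animal_sd = c(0, 0.05)[s %% 2 + 1], seed = 10 + s)
    mw <- fit_lmm(tb, "y", "x")
    mo <- fit_lmm(tb, "y", "x", group = NULL)
    expect_gte(lrt_random_effect(mw, mo)$stat, 0)
  }
})

test_that("random-effect LRT has power when the animal variance is real", {
  hits <- vapply(1:10, function(s) {
    tb <- make_model_table(n_pairs = 80, animal_sd = 0.02, resid_sd = 0.02,
                           seed = 100 + s)
    lrt_random_effect(fit_lmm(tb, "y", "x"),
                      fit_lmm(tb, "y", "x", group = NULL))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("LRT refuses mismatched observation sets", {
  tab <- make_model_table(seed = 7)
  m1 <- fit_lmm(tab, "y", "x")
  m2 <- fit_lmm(tab[1:60, ], "y", "x", group = NULL)
  expect_error(lrt_random_effect(m1, m2), "different observation sets")
})

test_that("model comparison flags redundant predictors and finds the real one", {
  set.seed(8)
  tab <- make_model_table(seed = 8)
  tab$x_dup <- tab$x + stats::rnorm(80, 0, 1e-9)
  expect_warning(mc <- model_comparison(tab, "y", c("x", "x_dup")),
                 "collinear")
  expect_true(all(mc$p > 0.05))              # each redundant given the other

  tab$z <- stats::runif(80, 0, 0.1)          # no effect on y
  mc2 <- model_comparison(tab, "y", c("x", "z"))
  expect_lt(mc2$p[mc2$predictor == "x"], 0.05)
  expect_gt(mc2$p[mc2$predictor == "z"], 0.05)
})

test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(9)
  for (rep in 1:5) {
    Z <- matrix(stats::rnorm(100), 50, 2)
    x <- Z %*% c(1, -0.5) + stats::rnorm(50)
    y <- Z %*% c(-0.3, 0.8) + 0.5 * x + stats::rnorm(50)
    expect_equal(partial_correlation(x, y, Z),
                 brute_partial_cor(x, y, Z), tolerance = 1e-10)
  }
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  expect_equal(partial_correlation(x, y), stats::cor(x, y))
  expect_lt(abs(partial_correlation(x, y, y)), 1e-10)  # y is its own control
})

test_that("Fisher Z comparison behaves per its closed form", {
  same <- fisher_z_compare(0.5, 50, 0.5, 50)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)

  fz <- fisher_z_compare(0.9, 78, 0.3, 78)
  z_manual <- (atanh(0.9) - atanh(0.3)) / sqrt(2 / 75)
  expect_equal(fz$Z, z_manual)
  expect_gt(fz$Z, 0)
  expect_lt(fz$p, 1e-4)

  swap <- fisher_z_compare(0.3, 78, 0.9, 78)
  expect_equal(swap$Z, -fz$Z)
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "\\|r\\| < 1")
})

test_that("Holm step-down matches the hand-computed decisions", {
  # sorted p: .01 vs .05/3 -> reject; .03 vs .05/2 -> fail, stop
  hb <- holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(hb$reject, c(TRUE, FALSE, FALSE))
  expect_equal(hb$p_adj, c(0.03, 0.06, 0.06))
  expect_equal(nrow(holm_bonferroni(numeric())), 0L)
})

test_that("Mann-Whitney wrapper handles the degenerate cases", {
  set.seed(10)
  x <- stats::rnorm(30)
  mw <- mann_whitney(x, x)
  expect_gt(mw$p, 0.9)
  expect_error(mann_whitney(numeric(), x), "non-empty")
  shifted <- mann_whitney(x, x + 5)
  expect_lt(shifted$p, 1e-6)
})

test_that("R-squared of a perfect linear relation is 1 with a degenerate CI", {
  tab <- data.frame(x = 1:20, y = 2 * (1:20) + 3)
  rr <- suppressWarnings(r2_with_ci(tab, "y", "x", n_boot = 100, seed = 11))
  expect_equal(rr$r2, 1.0)
  expect_equal(rr$ci, c(1, 1))
})
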