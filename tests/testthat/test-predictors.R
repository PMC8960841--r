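small_grid <- expand.grid(n_trees = c(100, 300), shrinkage = 0.1,
                          interaction_depth = c(1, 2), n_minobs = 5)

# exact oracle estimator: prediction is a fixed function of the inputs
oracle_model <- function(predictors, f) {
  est <- list(name = "oracle", fit = function(x, y, params) NULL,
              predict = function(model, x) f(x))
  structure(list(model = NULL, estimator = est, predictors = predictors,
                 response = "y"), class = "boosted_model")
}

test_that("tuning recovers a noiseless signal and a noise-only baseline", {
  set.seed(1)
  dat <- data.frame(x1 = runif(120), x2 = runif(120), x3 = runif(120))
  dat$y <- dat$x1
  fit <- tune_boosted_model(dat, "y", grid = small_grid, seed = 2)
  expect_lt(fit$cv_rmse, 0.05)
  expect_lt(sqrt(mean((predict(fit, dat) - dat$y)^2)), 0.02)

  dat$y <- rnorm(120)
  fit0 <- tune_boosted_model(dat, "y", grid = small_grid, seed = 2)
  expect_lt(abs(fit0$cv_rmse - sd(dat$y)), 0.35 * sd(dat$y))

  expect_error(tune_boosted_model(transform(dat, y = 1), "y",
                                  grid = small_grid), "degenerate")
})

test_that("tuning is deterministic for a fixed seed", {
  set.seed(3)
  dat <- data.frame(x1 = runif(60), x2 = runif(60))
  dat$y <- dat$x1 + rnorm(60, sd = 0.3)
  f1 <- tune_boosted_model(dat, "y", grid = small_grid, seed = 7)
  f2 <- tune_boosted_model(dat, "y", grid = small_grid, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$cv_table$cv_rmse, f2$cv_table$cv_rmse, tolerance = 1e-12)
})

test_that("permutation importance concentrates on the true driver", {
  set.seed(4)
  dat <- data.frame(x1 = runif(150), x2 = runif(150), x3 = runif(150))
  dat$y <- dat$x1
  fit <- tune_boosted_model(dat, "y", grid = small_grid, seed = 5)
  imp <- permutation_importance(fit, dat, n_perm = 100, seed = 5)
  tab <- imp$importance
  expect_gte(tab$rel_importance[tab$predictor == "x1"], 90)
  expect_lt(max(tab$rel_importance[tab$predictor != "x1"]), 10)
  expect_equal(sum(tab$rel_importance), 100, tolerance = 0.5)
  expect_equal(imp$top, "x1")
})

test_that("importance ranks an informative copy above independent noise", {
  set.seed(6)
  n <- 150
  dat <- data.frame(signal = runif(n), noise = runif(n))
  dat$y <- dat$signal + rnorm(n, sd = 0.05)
  fit <- tune_boosted_model(dat, "y", grid = small_grid, seed = 6)
  imp <- permutation_importance(fit, dat, n_perm = 50, seed = 6)$importance
  expect_gt(imp$rel_importance[imp$predictor == "signal"],
            imp$rel_importance[imp$predictor == "noise"])
})

test_that("importance is invariant to predictor column order", {
  set.seed(7)
  dat <- data.frame(a = runif(100), b = runif(100), c = runif(100))
  dat$y <- dat$a + 0.5 * dat$b + rnorm(100, sd = 0.1)
  f1 <- tune_boosted_model(dat, "y", predictors = c("a", "b", "c"),
                           grid = small_grid, seed = 8)
  f2 <- tune_boosted_model(dat, "y", predictors = c("c", "b", "a"),
                           grid = small_grid, seed = 8)
  i1 <- permutation_importance(f1, dat, n_perm = 50, seed = 9)$importance
  i2 <- permutation_importance(f2, dat, n_perm = 50, seed = 9)$importance
  i2 <- i2[match(i1$predictor, i2$predictor), ]
  expect_equal(i1$median_increase, i2$median_increase, tolerance = 1e-10)
})

test_that("ALE recovers closed-form slopes for additive models", {
  set.seed(10)
  n <- 400
  dat <- data.frame(x1 = runif(n), x2 = runif(n))
  dat$y <- 3 * dat$x1
  om <- oracle_model(c("x1", "x2"), function(x) 3 * x[, "x1"])
  al <- ale_curve(om, dat, "x1")
  slope <- coef(lm(ale ~ x, data = al$curve))[[2]]
  expect_equal(slope, 3, tolerance = 0.15)       # within 5 percent
  # centring: observation-weighted mean near zero
  mids <- (al$curve$ale[-1] + al$curve$ale[-nrow(al$curve)]) / 2
  expect_lt(abs(sum(al$counts * mids) / sum(al$counts)), 1e-10)
  # unused predictor: identically zero
  al2 <- ale_curve(om, dat, "x2")
  expect_equal(al2$curve$ale, rep(0, nrow(al2$curve)))
})

test_that("ALE stays unbiased under correlated predictors", {
  set.seed(11)
  n <- 500
  x1 <- runif(n)
  x2 <- x1 + rnorm(n, sd = 0.1)                  # strongly correlated
  dat <- data.frame(x1 = x1, x2 = x2, y = x1 + x2)
  om <- oracle_model(c("x1", "x2"), function(x) x[, "x1"] + x[, "x2"])
  al <- ale_curve(om, dat, "x1")
  slope <- coef(lm(ale ~ x, data = al$curve))[[2]]
  expect_equal(slope, 1, tolerance = 0.05)       # not 2: ALE decorrelates
})

test_that("ALE handles constant predictors with a flat flag", {
  dat <- data.frame(x1 = runif(30), x2 = rep(2, 30), y = runif(30))
  om <- oracle_model(c("x1", "x2"), function(x) x[, "x1"])
  al <- ale_curve(om, dat, "x2")
  expect_true(al$flat)
  expect_equal(al$curve$ale, 0)
})

test_that("the predictor table assembles genes, diversity and eigengenes", {
  samples <- data.frame(
    sample_id = paste0("s", 1:4), site = "S1",
    treatment = factor(rep(c("unfertilized", "fertilized"), 2),
                       levels = c("unfertilized", "fertilized")),
    nirK = c(1, 1, 1, 2), nirS = c(3, 1, 3, 2),
    nosZI = c(2, 1, 2, 2), nosZII = c(2, 1, 2, 2),
    end_product_ratio = c(0.2, 0.4, NA, 0.5))
  div <- data.frame(sample_id = paste0("s", 1:4), shannon = 1:4)
  eg <- matrix(1:4, 4, 1, dimnames = list(paste0("s", 1:4), "M1"))
  expect_message(
    tab <- build_predictor_table(samples, diversity = div, eigengenes = eg),
    "without end-product ratio")
  expect_equal(nrow(tab), 3)                       # s3 dropped (NA response)
  expect_equal(tab$nosz_nir[tab$sample_id == "s1"], (2 + 2) / (1 + 3))
  expect_true(all(c("shannon", "module_M1") %in% names(tab)))
  fert_only <- build_predictor_table(samples, treatment = "fertilized")
  expect_true(all(fert_only$treatment == "fertilized"))
})
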