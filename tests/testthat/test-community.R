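test_that("diversity indices match closed forms", {
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:8, ":1", collapse = ","), "):0;"))
  m <- matrix(0, 3, 8, dimnames = list(c("five", "one", "uniform"),
                                       paste0("t", 1:8)))
  m["five", 1:5] <- 2
  m["one", 1] <- 9
  m["uniform", ] <- 1
  dv <- diversity_table(m, star)
  expect_equal(dv$shannon[dv$sample_id == "five"], log(5))
  expect_equal(dv$shannon[dv$sample_id == "one"], 0)
  expect_equal(dv$richness, c(5L, 1L, 8L))
  expect_equal(dv$pd[dv$sample_id == "five"], 5)    # star, unit branches
  expect_equal(dv$pd[dv$sample_id == "uniform"], 8)
  # uniform over 10 OTUs: H' = ln 10
  u <- matrix(1, 2, 10, dimnames = list(c("a", "b"), paste0("x", 1:10)))
  expect_equal(diversity_table(u)$shannon, rep(log(10), 2))
})

test_that("Shannon never exceeds log richness and empty samples warn", {
  set.seed(5)
  m <- matrix(rpois(200, 2), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("o", 1:20)))
  m[1, ] <- 0
  expect_warning(dv <- diversity_table(m), "empty")
  expect_equal(dv$shannon[1], 0)
  expect_equal(dv$richness[1], 0L)
  ok <- dv$richness > 0
  expect_true(all(dv$shannon[ok] <= log(dv$richness[ok]) + 1e-12))
})

test_that("nmds recovers exact configurations and is seed-stable", {
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  nm <- nmds_ordination(d3, seed = 2)
  expect_lt(nm$stress, 1e-6)
  side <- as.vector(dist(nm$points))
  expect_lt(diff(range(side)) / mean(side), 1e-4)   # equilateral

  set.seed(1)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  nm2 <- nmds_ordination(dist(X), seed = 3)
  expect_lt(nm2$stress, 0.01)
  nm3 <- nmds_ordination(dist(X), seed = 3)
  expect_equal(as.vector(dist(nm2$points)), as.vector(dist(nm3$points)),
               tolerance = 1e-10)
  expect_error(nmds_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("permanova separates duplicated groups and rejects constant labels", {
  X <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(10, 10), 10), ncol = 2, byrow = TRUE))
  set.seed(4)
  X <- X + matrix(rnorm(40, sd = 1e-6), ncol = 2)
  rownames(X) <- paste0("s", 1:20)
  grp <- rep(c("a", "b"), each = 10)
  res <- permanova_strata(dist(X), grp, n_perm = 199, seed = 1)
  expect_gt(res$R2, 0.999)
  expect_equal(res$p, 1 / (199 + 1))
  expect_error(permanova_strata(dist(X), rep("a", 20)), "two levels")
})

test_that("permanova p-values are uniform under a free null", {
  set.seed(7)
  ps <- replicate(150, {
    X <- matrix(rnorm(60), 20, 3)
    permanova_strata(dist(X), sample(rep(c("a", "b"), 10)), n_perm = 99,
                     seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("balance LMM reduces to pooled ANOVA when site variance is zero", {
  set.seed(3)
  site <- rep(paste0("S", 1:6), each = 6)
  trt <- factor(rep(rep(c("unfertilized", "fertilized"), each = 3), 6),
                levels = c("unfertilized", "fertilized"))
  y <- rnorm(36)                       # iid: no site component
  res <- fit_balance_lmm(y, trt, site)
  ref <- anova(lm(y ~ trt))
  if (res$method == "fixed") {
    expect_equal(res$F_ratio, ref$`F value`[1], tolerance = 1e-6)
    expect_equal(res$p_raw, ref$`Pr(>F)`[1], tolerance = 1e-6)
  } else {
    # lmer kept a tiny site variance: F must still be close to pooled ANOVA
    expect_equal(res$F_ratio, ref$`F value`[1], tolerance = 0.05)
  }
  expect_equal(res$direction, sign(res$beta))
})

test_that("balance LMM recovers a planted fertilization effect", {
  set.seed(11)
  site <- rep(sprintf("S%02d", 1:14), each = 8)
  trt <- factor(rep(rep(c("unfertilized", "fertilized"), each = 4), 14),
                levels = c("unfertilized", "fertilized"))
  y <- 1 * (trt == "fertilized") + rnorm(14, sd = 0.7)[as.integer(factor(site))] +
    rnorm(112, sd = 0.1)
  res <- fit_balance_lmm(y, trt, site)
  expect_equal(res$beta, 1, tolerance = 0.05)
  expect_equal(res$df_num, 1)
  expect_lt(res$p_raw, 1e-6)
  expect_true(res$method %in% c("Kenward-Roger", "Satterthwaite"))
})

test_that("balance LMM type-I error is near nominal", {
  set.seed(21)
  site_f <- rep(sprintf("S%02d", 1:10), each = 6)
  trt <- factor(rep(rep(c("unfertilized", "fertilized"), each = 3), 10),
                levels = c("unfertilized", "fertilized"))
  ps <- replicate(300, {
    y <- rnorm(10, sd = 0.8)[as.integer(factor(site_f))] + rnorm(60)
    fit_balance_lmm(y, trt, site_f)$p_raw
  })
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("BH adjustment matches hand computation and its properties", {
  expect_equal(fdr_adjust(rep(0.5, 4)), rep(0.5, 4))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("balance-ratio association behaves at the Spearman extremes", {
  set.seed(6)
  ratio <- runif(20)
  bal <- cbind(mono = rank(ratio) + 0, anti = -ratio, flat = rep(1, 20))
  rownames(bal) <- paste0("s", 1:20)
  res <- associate_balances_ratio(bal, ratio)
  expect_equal(res$rho[res$node == "mono"], 1)
  expect_equal(res$rho[res$node == "anti"], -1)
  expect_true(is.na(res$rho[res$node == "flat"]))
  expect_true(res$degenerate[res$node == "flat"])
})
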