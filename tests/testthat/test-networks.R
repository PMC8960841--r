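test_that("correlation matrix has the expected extremes", {
  set.seed(1)
  x <- rnorm(100)
  m <- cbind(a = x, b = -x, c = rnorm(100))
  rownames(m) <- paste0("s", 1:100)
  R <- correlation_matrix(m)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R["a", "b"], -1)
  expect_lt(abs(R["a", "c"]), 0.3)
  m2 <- cbind(m, flat = rep(2, 100))
  expect_message(R2 <- correlation_matrix(m2), "zero-variance")
  expect_false("flat" %in% colnames(R2))
  expect_error(correlation_matrix(m[1:2, ]), "3 samples")
})

test_that("independent Gaussian correlations are small at n = 1000", {
  set.seed(2)
  m <- matrix(rnorm(1000 * 12), 1000, 12,
              dimnames = list(NULL, paste0("o", 1:12)))
  R <- correlation_matrix(m)
  expect_lt(max(abs(R[upper.tri(R)])), 0.12)
})

test_that("RMT scan finds a separating threshold on planted blocks", {
  set.seed(5)
  Sig <- generate_planted_correlation(120, data.frame(size = rep(15, 4),
                                                      rho = 0.85))
  X <- MASS::mvrnorm(250, rep(0, 120), Sig)
  R <- stats::cor(X)
  noise <- is.na(attr(Sig, "modules"))
  noise_max <- max(abs(R[noise, noise][upper.tri(diag(sum(noise)))]))
  sc <- rmt_threshold(R)
  expect_s3_class(sc, "rmt_scan")
  expect_false(is.na(sc$r_T))
  expect_gt(sc$r_T, noise_max)
  expect_lt(sc$r_T, 0.8)
})

test_that("RMT scan signals when no transition exists", {
  R <- diag(60)
  dimnames(R) <- list(paste0("o", 1:60), paste0("o", 1:60))
  sc <- rmt_threshold(R, t_grid = c(0.5, 0.7, 0.9))
  expect_true(is.na(sc$r_T))
  expect_match(sc$note, "no transition")
  expect_error(rmt_threshold(R, t_grid = c(0.9, 0.5)), "increasing")
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(9)
  Sig <- generate_planted_correlation(60, data.frame(size = c(12, 12),
                                                     rho = 0.8))
  X <- MASS::mvrnorm(150, rep(0, 60), Sig)
  R <- stats::cor(X)
  dimnames(R) <- list(paste0("o", 1:60), paste0("o", 1:60))
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(t)
    sum(abs(R[upper.tri(R)]) >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("build_graph thresholds, signs and prunes correctly", {
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  R["a", "b"] <- R["b", "a"] <- 0.9
  R["a", "c"] <- R["c", "a"] <- 0.2
  R["b", "c"] <- R["c", "b"] <- 0.1
  g <- build_graph(R, 0.85, n_samples = 100)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("a", "b"))   # c removed, degree 0
  expect_equal(igraph::E(g)$weight, 0.9)
  g1 <- build_graph(R, 1, n_samples = 100)
  expect_true(isTRUE(attr(g1, "empty")))
  expect_error(build_graph(R, 0, 100), "r_T")
})

test_that("graph edges stay within planted modules", {
  st <- small_study()
  idx <- st$samples$treatment == "unfertilized"
  cl <- clr_transform(impute_zeros(
    st$counts[, st$truth$frequent_otus, drop = FALSE]))
  R <- correlation_matrix(cl[idx, ])
  g <- suppressMessages(build_graph(R, 0.8, n_samples = sum(idx)))
  lab <- rep(NA_character_, 80)
  names(lab) <- st$truth$frequent_otus
  for (m in names(st$truth$modules)) lab[st$truth$modules[[m]]] <- m
  el <- igraph::as_data_frame(g)
  same_mod <- !is.na(lab[el$from]) & !is.na(lab[el$to]) &
    lab[el$from] == lab[el$to]
  expect_gt(mean(same_mod), 0.9)
})

test_that("topology metrics match graph-theory oracles", {
  k3 <- named_graph(igraph::make_full_graph(3), weight = 0.9)
  t3 <- topology_metrics(k3)
  expect_equal(t3$nodes, 3)
  expect_equal(t3$diameter, 1)
  expect_equal(t3$avg_path_length, 1)
  expect_equal(t3$transitivity, 1)
  expect_equal(t3$connectance, 1)

  p4 <- named_graph(igraph::make_graph(~ a - b, b - c, c - d), weight = 0.5)
  t4 <- topology_metrics(p4)
  expect_equal(t4$diameter, 3)
  expect_equal(t4$mean_degree, 1.5)
  expect_equal(t4$transitivity, 0)
  expect_equal(t4$avg_path_length, (1 + 1 + 1 + 2 + 2 + 3) / 6)
  expect_equal(t4$connectance, 3 / 6)

  # negative edges are excluded before computing metrics
  mixed <- named_graph(igraph::make_full_graph(3), weight = c(0.9, -0.8, 0.7))
  tm <- topology_metrics(mixed)
  expect_equal(tm$edges, 2)
  expect_equal(tm$transitivity, 0)

  disc <- named_graph(igraph::disjoint_union(igraph::make_full_graph(3),
                                             igraph::make_full_graph(4)))
  td <- topology_metrics(disc)
  expect_true(td$disconnected)
  expect_equal(td$diameter, 1)     # largest component K4
})

test_that("ER null test flags structure and degenerate metrics", {
  # two K6 cliques plus a bridge: transitivity far above G(n, m)
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  g <- igraph::add_edges(g, c(1, 7))
  obs <- igraph::transitivity(g, type = "global")
  res <- er_null_test("transitivity", obs, igraph::vcount(g),
                      igraph::ecount(g), reps = 200, seed = 3)
  expect_equal(res$p, 1 / 200)
  # mean degree is fixed by n and m: constant nulls, p = 1
  res2 <- er_null_test("mean_degree", 2 * 31 / 12, 12, 31, reps = 50, seed = 1)
  expect_equal(res2$p, 1)
  expect_equal(var(res2$null_values), 0)
  # observed at the null median: p near 1
  res3 <- er_null_test("transitivity", median(res$null_values),
                       12, 31, reps = 200, seed = 3)
  expect_gt(res3$p, 0.5)
  expect_error(er_null_test("transitivity", 1, 4, 10), "maximum")
})

test_that("edge-betweenness modules recover planted structure", {
  g <- named_graph(igraph::disjoint_union(igraph::make_full_graph(6),
                                          igraph::make_full_graph(6)))
  mods <- detect_modules(g)
  expect_equal(length(mods$modules), 2)
  expect_equal(lengths(mods$modules), c(M1 = 6L, M2 = 6L))

  # barbell: the bridge has the highest betweenness and is removed first
  gb <- named_graph(igraph::add_edges(
    igraph::disjoint_union(igraph::make_full_graph(5),
                           igraph::make_full_graph(5)), c(1, 6)))
  comm <- igraph::cluster_edge_betweenness(
    igraph::delete_edge_attr(gb, "weight"))
  first <- igraph::ends(gb, comm$removed.edges[1])
  expect_setequal(as.vector(first), c("v1", "v6"))
  mb <- detect_modules(gb)
  expect_equal(lengths(mb$modules), c(M1 = 5L, M2 = 5L))

  # modules below min_size stay unassigned
  g2 <- named_graph(igraph::disjoint_union(igraph::make_full_graph(6),
                                           igraph::make_full_graph(3)))
  m2 <- detect_modules(g2, min_size = 5)
  expect_equal(length(m2$modules), 1)
  expect_equal(sum(is.na(m2$membership)), 3)
})

test_that("module eigengenes hit their variance-explained limits", {
  set.seed(2)
  n <- 2000
  base <- rnorm(n)
  perf <- sapply(1:6, function(i) 3 * base - 1)
  dimnames(perf) <- list(paste0("s", 1:n), paste0("o", 1:6))
  eg <- module_eigengene(perf, colnames(perf))
  expect_equal(eg$var_explained, 1.0)
  expect_equal(sum(eg$eigengene^2), 1)
  expect_gt(cor(eg$eigengene, base), 0.999)      # oriented with the members

  noise_big <- matrix(rnorm(n * 5), n,
                      dimnames = list(paste0("s", 1:n), paste0("o", 1:5)))
  ve_big <- module_eigengene(noise_big, colnames(noise_big))$var_explained
  noise_small <- noise_big[1:100, ]
  ve_small <- module_eigengene(noise_small, colnames(noise_small))$var_explained
  expect_lt(abs(ve_big - 0.2), 0.05)             # analytic limit 1/5
  expect_lt(abs(ve_big - 0.2), abs(ve_small - 0.2))
})

test_that("eigengenes are invariant to orientation, order and scaling", {
  set.seed(3)
  x <- matrix(rnorm(50 * 6), 50, dimnames = list(paste0("s", 1:50),
                                                 paste0("o", 1:6)))
  x[, 1:5] <- x[, 1:5] + rnorm(50)               # shared signal
  e1 <- module_eigengene(x, colnames(x))
  # negating every member column flips both the principal component and
  # the orientation reference, so the oriented eigengene flips sign as a
  # whole; the summary (spanned direction, variance explained) is intact
  e_neg <- module_eigengene(-x, colnames(x))
  expect_equal(e_neg$eigengene, -e1$eigengene, tolerance = 1e-10)
  expect_equal(e_neg$var_explained, e1$var_explained, tolerance = 1e-12)
  perm <- sample(nrow(x))
  e_perm <- module_eigengene(x[perm, ], colnames(x))
  expect_equal(e_perm$var_explained, e1$var_explained, tolerance = 1e-12)
  x_scaled <- sweep(x, 2, c(10, 0.1, 3, 1, 5, 2), `*`)
  e_scaled <- module_eigengene(x_scaled, colnames(x))
  expect_equal(e_scaled$var_explained, e1$var_explained, tolerance = 1e-12)
  expect_error(module_eigengene(x, c("o1", "zz")), "absent")
  expect_error(module_eigengene(x, paste0("o", 1:4)), "5 module members")
})

test_that("module-covariate correlations hit the Spearman extremes", {
  set.seed(4)
  eg <- data.frame(M1 = 1:20 + 0)
  vars <- data.frame(up = exp(1:20), down = -(1:20) + 0.5,
                     noise = rnorm(20), missing = rep(NA_real_, 20))
  res <- correlate_modules(eg, vars)
  expect_equal(res$rho[res$variable == "up"], 1)
  expect_equal(res$rho[res$variable == "down"], -1)
  expect_false("missing" %in% res$variable)
})
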