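#' Per-sample diversity indices
#'
#' Shannon's index (natural log), observed richness, and Faith's
#' phylogenetic diversity (total branch length of the rooted subtree
#' spanning the present tips).
#'
#' @param mat samples x OTUs non-negative abundance matrix.
#' @param tree rooted phylogeny covering the OTUs (only needed for PD).
#' @return data frame: `sample_id`, `shannon`, `richness`, `pd`.
#' @export
diversity_table <- function(mat, tree = NULL) {
  if (any(mat < 0)) stop("negative abundances")
  shannon <- vegan::diversity(mat, index = "shannon")
  richness <- rowSums(mat > 0)
  empty <- richness == 0
  if (any(empty)) {
    warning(sum(empty), " empty sample(s): diversity set to zero")
    shannon[empty] <- 0
  }
  out <- data.frame(sample_id = rownames(mat), shannon = shannon,
                    richness = as.integer(richness), row.names = NULL)
  if (!is.null(tree)) {
    pdv <- rep(0, nrow(mat))
    if (any(!empty)) {
      res <- picante::pd(mat[!empty, , drop = FALSE], tree,
                         include.root = TRUE)
      pdv[!empty] <- res$PD
    }
    out$pd <- pdv
  }
  out
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Thin wrapper over [vegan::metaMDS()] (monoMDS engine, multiple random
#' starts, best configuration kept) with a fixed seed for reproducibility.
#'
#' @param d distance matrix (symmetric, zero diagonal) or `dist`.
#' @param k target dimension.
#' @param seed integer seed.
#' @param trymax maximum random starts.
#' @return list with `points` (samples x k) and `stress`.
#' @export
nmds_ordination <- function(d, k = 2, seed = 1L, trymax = 20) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("input error: distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  list(points = fit$points, stress = fit$stress)
}

#' Permutational multivariate ANOVA with restricted permutations
#'
#' Distance-based one-factor perMANOVA (Gower-centred partition, vegan's
#' `adonis2`). When `strata` is given, label permutations are restricted
#' to occur within each stratum, so factors confounded with the strata
#' (such as site in a multi-site trial) cannot masquerade as group
#' effects.
#'
#' @param d distance matrix or `dist` over samples.
#' @param groups factor to test.
#' @param strata optional blocking factor restricting permutations.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `R2`, `F`, `p`, `n_perm`, `table` (the adonis2 table).
#' @export
permanova_strata <- function(d, groups, strata = NULL, n_perm = 1000,
                             seed = 1L) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("input error: distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("input error: groups must have at least two levels")
  dat <- data.frame(groups = groups)
  set.seed(seed)
  if (is.null(strata)) {
    ctrl <- permute::how(nperm = n_perm)
  } else {
    strata <- factor(strata)
    singletons <- names(which(table(strata) < 2L))
    if (length(singletons))
      warning("strata with a single sample contribute no permutations: ",
              paste(singletons, collapse = ", "))
    ctrl <- permute::how(nperm = n_perm, blocks = strata)
  }
  tab <- vegan::adonis2(d ~ groups, data = dat, permutations = ctrl)
  list(R2 = tab$R2[1L], F = tab$F[1L], p = tab$`Pr(>F)`[1L],
       n_perm = n_perm, table = tab)
}

#' Mixed-model test of a fertilization effect on one balance
#'
#' Fits `balance ~ treatment + (1 | site)` and tests the treatment term
#' with an F-ratio using the Kenward-Roger denominator degrees of freedom
#' when the pbkrtest package is available, otherwise the Satterthwaite
#' approximation (the method used is recorded). A singular fit (site
#' variance estimated at zero) is refitted as a fixed-intercept linear
#' model and flagged.
#'
#' @param y numeric balance values.
#' @param treatment two-level factor (reference level first).
#' @param site grouping factor (random intercept).
#' @return one-row data frame: `F_ratio`, `df_num`, `df_den`, `p_raw`,
#'   `beta`, `direction`, `method`.
#' @export
fit_balance_lmm <- function(y, treatment, site) {
  treatment <- factor(treatment)
  site <- factor(site)
  if (nlevels(site) < 2L) stop("need at least 2 sites")
  if (nlevels(treatment) != 2L) stop("treatment must have exactly 2 levels")
  ddf <- if (requireNamespace("pbkrtest", quietly = TRUE))
    "Kenward-Roger" else "Satterthwaite"
  dat <- data.frame(y = y, treatment = treatment, site = site)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ treatment + (1 | site), data = dat)))
  beta <- lme4::fixef(fit)[[2L]]
  if (lme4::isSingular(fit, tol = 1e-5)) {
    lmfit <- lm(y ~ treatment, data = dat)
    a <- anova(lmfit)
    return(data.frame(F_ratio = a$`F value`[1L], df_num = 1,
                      df_den = a$Df[2L], p_raw = a$`Pr(>F)`[1L],
                      beta = coef(lmfit)[[2L]],
                      direction = sign(coef(lmfit)[[2L]]),
                      method = "fixed", row.names = NULL))
  }
  a <- suppressMessages(anova(fit, ddf = ddf))
  data.frame(F_ratio = a$`F value`[1L], df_num = a$NumDF[1L],
             df_den = a$DenDF[1L], p_raw = a$`Pr(>F)`[1L],
             beta = beta, direction = sign(beta),
             method = ddf, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p_values numeric vector of p-values.
#' @return q-values (monotone step-up adjustment).
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-balance fertilization tests across a balance matrix
#'
#' Runs [fit_balance_lmm()] on every balance (column) and appends
#' BH-adjusted q-values over the tested family.
#'
#' @param balances samples x balances matrix from [philr_transform()].
#' @param treatment,site factors aligned to the rows of `balances`.
#' @return data frame, one row per balance: `node`, the columns of
#'   [fit_balance_lmm()], and `q_fdr`.
#' @export
test_balances <- function(balances, treatment, site) {
  res <- do.call(rbind, lapply(colnames(balances), function(nd) {
    row <- fit_balance_lmm(balances[, nd], treatment, site)
    cbind(data.frame(node = nd), row)
  }))
  res$q_fdr <- fdr_adjust(res$p_raw)
  res
}

#' Spearman association between balances and the end-product ratio
#'
#' @param balances samples x balances matrix (typically restricted to the
#'   balances significant in [test_balances()]).
#' @param ratio end-product ratio per sample, aligned to rows.
#' @param nodes optional subset of balance columns.
#' @return data frame: `node`, `rho`, `p_rho`; constant balances yield
#'   `NA` with a flag column `degenerate`.
#' @export
associate_balances_ratio <- function(balances, ratio, nodes = NULL) {
  if (is.null(nodes)) nodes <- colnames(balances)
  out <- lapply(nodes, function(nd) {
    b <- balances[, nd]
    if (sd(b) == 0 || sd(ratio) == 0)
      return(data.frame(node = nd, rho = NA_real_, p_rho = NA_real_,
                        degenerate = TRUE))
    ct <- suppressWarnings(cor.test(b, ratio, method = "spearman"))
    data.frame(node = nd, rho = unname(ct$estimate), p_rho = ct$p.value,
               degenerate = FALSE)
  })
  do.call(rbind, out)
}
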