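small_sample_aic <- function(fit) {
  k <- attr(logLik(fit), "df")
  n <- stats::nobs(fit)
  AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Estimate a gas accumulation rate from a bottle time series
#'
#' Fits the N2O accumulation curve of an anaerobic slurry assay and
#' returns the initial accumulation rate. The linear model is a
#' least-squares slope; the saturating model `c(t) = c0 + A (1 - e^{-kt})`
#' is fitted by Levenberg-Marquardt nonlinear least squares and its rate
#' is the initial slope `A * k`. Under `"auto"` both are fitted and the
#' one with the smaller small-sample (corrected) AIC wins. A
#' non-convergent nonlinear fit falls back to the linear model, flagged.
#' Rates are floored at zero.
#'
#' @param ts a `gas_timeseries` (see [generate_gas_timeseries()]) or a
#'   list with `times` and `concentrations`.
#' @param model `"auto"`, `"linear"` or `"saturating"`.
#' @return list: `rate`, `model_used`, `fallback` (logical), `aicc`
#'   (named, when computed), `coefficients`.
#' @export
fit_accumulation_rate <- function(ts, model = c("auto", "linear", "saturating")) {
  model <- match.arg(model)
  t <- ts$times; conc <- ts$concentrations
  if (length(t) < 4L) stop("need at least 4 time points")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  lin <- lm(conc ~ t)
  lin_rate <- unname(coef(lin)[2L])
  fit_sat <- function() {
    rng <- max(conc) - min(conc)
    minpack.lm::nlsLM(conc ~ c0 + A * (1 - exp(-k * t)),
                      start = list(c0 = conc[1L], A = max(rng, 1e-8), k = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  sat <- if (model %in% c("auto", "saturating"))
    tryCatch(fit_sat(), error = function(e) NULL) else NULL
  sat_ok <- !is.null(sat) && all(is.finite(coef(sat))) && coef(sat)[["k"]] > 0
  pick <- switch(model,
    linear = "linear",
    saturating = if (sat_ok) "saturating" else "linear",
    auto = if (sat_ok && small_sample_aic(sat) < small_sample_aic(lin))
      "saturating" else "linear")
  fallback <- model == "saturating" && !sat_ok
  if (pick == "saturating") {
    cf <- coef(sat)
    rate <- cf[["A"]] * cf[["k"]]
    coefs <- cf
  } else {
    rate <- lin_rate
    coefs <- coef(lin)
  }
  aicc <- c(linear = small_sample_aic(lin),
            saturating = if (sat_ok) small_sample_aic(sat) else NA_real_)
  list(rate = max(0, rate), model_used = pick, fallback = fallback,
       aicc = aicc, coefficients = coefs)
}

#' Denitrification end-product ratio
#'
#' Ratio of the potential N2O production rate (assay without acetylene)
#' to the potential denitrification rate (with acetylene, which blocks
#' N2O reduction so that all denitrified N accumulates as N2O). Values
#' above 1 are flagged; a zero denominator yields `NA` with a warning.
#'
#' @param rate_no_ac potential N2O production rate(s).
#' @param rate_ac potential denitrification rate(s).
#' @return numeric ratio(s), attribute `flagged_gt1` marking values > 1.
#' @export
end_product_ratio <- function(rate_no_ac, rate_ac) {
  if (any(rate_no_ac < 0, na.rm = TRUE) || any(rate_ac < 0, na.rm = TRUE))
    stop("rates must be non-negative")
  ratio <- ifelse(rate_ac > 0, rate_no_ac / rate_ac, NA_real_)
  if (any(rate_ac == 0, na.rm = TRUE))
    warning("zero denitrification rate: ratio undefined for ",
            sum(rate_ac == 0, na.rm = TRUE), " sample(s)")
  attr(ratio, "flagged_gt1") <- which(!is.na(ratio) & ratio > 1)
  ratio
}

#' Exact Wilcoxon signed-rank test (two-sided, mid-rank ties)
#'
#' Full conditional null distribution of the positive-rank sum under
#' random sign assignment, computed by convolution over the (doubled, so
#' integer) mid-ranks; exact also in the presence of ties. Zeros are
#' dropped. Used for small paired samples (the per-site percent changes),
#' with a normal approximation above `max_exact`.
#'
#' @param x numeric differences (tested against a zero median).
#' @param max_exact largest n for which the exact distribution is used.
#' @return list: `statistic` (positive-rank sum W), `p`, `n`, `exact`.
#' @export
wilcoxon_signed_exact <- function(x, max_exact = 25) {
  x <- x[!is.na(x) & x != 0]
  n <- length(x)
  if (n == 0L) return(list(statistic = NA_real_, p = 1, n = 0L, exact = TRUE))
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  if (n > max_exact) {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    z <- (W - mu) / sig
    return(list(statistic = W, p = min(1, 2 * pnorm(-abs(z))), n = n,
                exact = FALSE))
  }
  r2 <- as.integer(round(2 * r))          # mid-ranks doubled to integers
  f <- c(1, numeric(sum(r2)))             # counts over possible 2W values
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
    f <- f + shifted
  }
  f <- f / 2^n
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):length(f)])
  list(statistic = W, p = min(1, 2 * min(p_le, p_ge)), n = n, exact = TRUE)
}

#' Fertilization percent change per site with exact signed-rank tests
#'
#' For each metric, computes the site-mean value under each treatment,
#' the percent change `100 * (fertilized - unfertilized) / unfertilized`,
#' and a two-sided exact Wilcoxon signed-rank test of the site-level
#' changes against zero. Sites missing a treatment, or with a
#' non-positive unfertilized mean, are excluded with a message.
#'
#' @param samples data frame with `site`, `treatment` (levels
#'   unfertilized, fertilized) and the metric columns.
#' @param metrics character vector of metric column names.
#' @return list: `changes` (data frame `site`, `metric`,
#'   `percent_change`) and `tests` (data frame `metric`, `n_sites`,
#'   `statistic`, `p`, `exact`).
#' @export
percent_change_test <- function(samples, metrics) {
  df <- as.data.frame(samples)
  stopifnot(all(c("site", "treatment") %in% names(df)),
            all(metrics %in% names(df)))
  changes <- list(); tests <- list()
  for (m in metrics) {
    agg <- stats::aggregate(df[[m]],
                            by = list(site = df$site, treatment = df$treatment),
                            FUN = mean, na.rm = TRUE)
    wide <- stats::reshape(agg, idvar = "site", timevar = "treatment",
                           direction = "wide")
    un <- wide[["x.unfertilized"]]; fe <- wide[["x.fertilized"]]
    ok <- !is.na(un) & !is.na(fe) & un > 0
    if (any(!ok))
      message(sum(!ok), " site(s) excluded for metric ", m)
    pct <- 100 * (fe[ok] - un[ok]) / un[ok]
    changes[[m]] <- data.frame(site = wide$site[ok], metric = m,
                               percent_change = pct)
    wt <- wilcoxon_signed_exact(pct)
    tests[[m]] <- data.frame(metric = m, n_sites = sum(ok),
                             statistic = wt$statistic, p = wt$p,
                             exact = wt$exact)
  }
  list(changes = do.call(rbind, c(changes, list(make.row.names = FALSE))),
       tests = do.call(rbind, c(tests, list(make.row.names = FALSE))))
}

#' ANCOVA: does a covariate's slope differ between groups?
#'
#' Fits `response ~ covariate * group` and reports the F-test of the
#' interaction (equal-slopes hypothesis) plus the standardized regression
#' coefficient of the covariate within each group (slope on z-scored
#' variables).
#'
#' @param response,covariate numeric vectors.
#' @param group two-level factor.
#' @return list: `F_interaction`, `df`, `p`, `beta` (named per group).
#' @export
ancova_interaction <- function(response, covariate, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("group needs at least two levels")
  for (g in levels(group))
    if (sd(covariate[group == g]) == 0)
      stop("singular design: covariate constant within group ", g)
  fit <- lm(response ~ covariate * group)
  a <- suppressWarnings(anova(fit))
  irow <- grep(":", rownames(a))
  # a numerically zero interaction sum of squares (perfectly parallel
  # groups) makes the F ratio 0/0; report no interaction
  if (a$`Sum Sq`[irow] <= 1e-10 * max(sum(a$`Sum Sq`), 1e-300)) {
    a$`F value`[irow] <- 0
    a$`Pr(>F)`[irow] <- 1
  }
  beta <- vapply(levels(group), function(g) {
    idx <- group == g
    unname(coef(lm(scale(response[idx]) ~ scale(covariate[idx])))[2L])
  }, numeric(1))
  list(F_interaction = a$`F value`[irow], df = c(a$Df[irow], a$Df[nrow(a)]),
       p = a$`Pr(>F)`[irow], beta = beta)
}
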