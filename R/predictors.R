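#' Gradient-boosted tree estimator (xgboost backend)
#'
#' The importance and ALE machinery is estimator-agnostic: any list with
#' `fit(x, y, params)` and `predict(model, x)` functions works. This
#' constructor returns the default backend, a gradient-boosted
#' regression-tree ensemble (squared-error loss, single thread, fully
#' deterministic).
#'
#' @return estimator list with elements `fit`, `predict`, `name`.
#' @export
boosted_tree_estimator <- function() {
  list(
    name = "xgboost",
    fit = function(x, y, params) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(eta = params$shrinkage,
                      max_depth = params$interaction_depth,
                      min_child_weight = params$n_minobs,
                      objective = "reg:squarederror",
                      nthread = 1),
        data = dtrain, nrounds = params$n_trees, verbose = 0)
    },
    predict = function(model, x)
      predict(model, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1)))
}

#' Default hyperparameter grid for boosted-model tuning
#'
#' Spans the four tuned dimensions: number of trees, shrinkage
#' (learning rate), interaction depth and minimum observations per node.
#'
#' @return data frame grid.
#' @export
default_boost_grid <- function() {
  expand.grid(n_trees = c(500, 1000, 2000), shrinkage = c(0.01, 0.05, 0.1),
              interaction_depth = 1:3, n_minobs = c(5, 10))
}

#' Tune and fit a boosted regression model by cross-validated grid search
#'
#' Selects hyperparameters by minimum mean k-fold cross-validated RMSE
#' (ties broken toward fewer trees, then smaller depth), refits on all
#' data, and reports the CV RMSE of the chosen configuration.
#'
#' @param data data frame holding predictors and the response.
#' @param response response column name; must be non-constant.
#' @param predictors predictor column names (default: all other numeric
#'   columns). Constant predictors are dropped with a message.
#' @param grid hyperparameter grid (see [default_boost_grid()]).
#' @param folds number of CV folds.
#' @param seed integer seed (controls the fold assignment).
#' @param estimator estimator list (see [boosted_tree_estimator()]).
#' @return object of class `boosted_model`: `model`, `params`, `cv_rmse`,
#'   `cv_table`, `predictors`, `response`, `estimator`, `seed`.
#' @export
tune_boosted_model <- function(data, response, predictors = NULL,
                               grid = default_boost_grid(), folds = 10,
                               seed = 1L, estimator = boosted_tree_estimator()) {
  if (!response %in% names(data)) stop("response column not found")
  y <- data[[response]]
  if (sd(y) == 0) stop("degenerate response: constant values")
  if (is.null(predictors))
    predictors <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], response)
  constant <- predictors[vapply(predictors, function(p) sd(data[[p]]) == 0, TRUE)]
  if (length(constant)) {
    message("dropping constant predictor(s): ", paste(constant, collapse = ", "))
    predictors <- setdiff(predictors, constant)
  }
  if (!length(predictors)) stop("no usable predictors")
  if (!nrow(grid)) stop("empty hyperparameter grid")
  x <- as.matrix(data[, predictors, drop = FALSE])
  n <- nrow(x)
  if (n < folds) stop("need at least `folds` samples")
  set.seed(derive_seed(seed, "cv_folds"))
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  rmse <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    params <- as.list(grid[gidx, ])
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- estimator$fit(x[tr, , drop = FALSE], y[tr], params)
      pr <- estimator$predict(m, x[!tr, , drop = FALSE])
      sqrt(mean((pr - y[!tr])^2))
    }, numeric(1))
    rmse[gidx] <- mean(errs)
  }
  ord <- order(rmse, grid$n_trees, grid$interaction_depth)
  best <- ord[1L]
  params <- as.list(grid[best, ])
  model <- estimator$fit(x, y, params)
  cv_table <- cbind(grid, cv_rmse = rmse)
  structure(list(model = model, params = params, cv_rmse = rmse[best],
                 cv_table = cv_table, predictors = predictors,
                 response = response, estimator = estimator, seed = seed),
            class = "boosted_model")
}

#' @export
predict.boosted_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  object$estimator$predict(object$model, x)
}

#' @export
#' @method print boosted_model
print.boosted_model <- function(x, ...) {
  cat("Boosted regression model (", x$estimator$name, ")\n", sep = "")
  cat(sprintf("  response: %s; %d predictors\n", x$response,
              length(x$predictors)))
  cat(sprintf("  trees %d, shrinkage %.3g, depth %d, min node %d; CV RMSE %.4g\n",
              x$params$n_trees, x$params$shrinkage, x$params$interaction_depth,
              x$params$n_minobs, x$cv_rmse))
  invisible(x)
}

#' Permutation variable importance
#'
#' For each predictor and each permutation, the predictor column is
#' shuffled and the increase in RMSE over the intact data is recorded.
#' A predictor's importance is the median increase over permutations,
#' floored at zero and rescaled so the importances sum to 100 percent.
#'
#' @param fit a `boosted_model` (or any object with a `predict` method,
#'   `predictors` and `response` fields).
#' @param data evaluation data frame containing predictors and response.
#' @param n_perm number of permutations per predictor.
#' @param seed integer seed.
#' @param top_cut relative-importance cut (percent) defining the top set.
#' @return object of class `importance_report`: data frame `importance`
#'   (`predictor`, `median_increase`, `q25`, `q75`, `rel_importance`),
#'   `top` (predictors above `top_cut`), `baseline_rmse`.
#' @export
permutation_importance <- function(fit, data, n_perm = 500, seed = 1L,
                                   top_cut = 5) {
  y <- data[[fit$response]]
  x <- as.data.frame(data)[, fit$predictors, drop = FALSE]
  base_rmse <- sqrt(mean((predict(fit, x) - y)^2))
  n <- nrow(x)
  med <- q25 <- q75 <- setNames(numeric(length(fit$predictors)),
                                fit$predictors)
  for (p in fit$predictors) {
    # per-predictor RNG stream: results do not depend on column order
    set.seed(derive_seed(seed, paste0("perm_", p)))
    incr <- vapply(seq_len(n_perm), function(i) {
      xp <- x
      xp[[p]] <- xp[[p]][sample.int(n)]
      sqrt(mean((predict(fit, xp) - y)^2)) - base_rmse
    }, numeric(1))
    med[p] <- median(incr)
    q25[p] <- quantile(incr, 0.25)
    q75[p] <- quantile(incr, 0.75)
  }
  floored <- pmax(med, 0)
  rel <- if (sum(floored) > 0) 100 * floored / sum(floored)
         else setNames(rep(0, length(floored)), names(floored))
  imp <- data.frame(predictor = fit$predictors, median_increase = med,
                    q25 = q25, q75 = q75, rel_importance = rel,
                    row.names = NULL)
  imp <- imp[order(-imp$rel_importance), ]
  rownames(imp) <- NULL
  structure(list(importance = imp,
                 top = imp$predictor[imp$rel_importance > top_cut],
                 baseline_rmse = base_rmse, n_perm = n_perm),
            class = "importance_report")
}

#' @export
#' @method print importance_report
print.importance_report <- function(x, ...) {
  cat("Permutation importance (", x$n_perm, " permutations, baseline RMSE ",
      signif(x$baseline_rmse, 4), ")\n", sep = "")
  print(head(x$importance[, c("predictor", "rel_importance")], 10),
        row.names = FALSE)
  invisible(x)
}

#' First-order accumulated local effects curve
#'
#' Partitions the predictor's range at empirical quantiles, averages the
#' model-prediction difference between the upper and lower bin edge over
#' the observations falling in each bin (other columns held at their
#' observed values), accumulates the local effects across bins, and
#' centres the curve by the observation-weighted mean. Unlike partial
#' dependence, ALE remains valid when predictors are correlated.
#'
#' @param fit a `boosted_model` (or compatible object).
#' @param data data frame of observations.
#' @param predictor numeric predictor name.
#' @param grid_size number of quantile bins (bins with identical edges
#'   are merged).
#' @return object of class `ale_curve`: data frame `curve` (`x` =
#'   breakpoints, `ale` = centred effect), `predictor`, `counts` per bin,
#'   `flat` flag for constant predictors.
#' @export
ale_curve <- function(fit, data, predictor, grid_size = 10) {
  x <- as.data.frame(data)
  if (!predictor %in% fit$predictors) stop("unknown predictor: ", predictor)
  xv <- x[[predictor]]
  if (sd(xv) == 0) {
    return(structure(list(
      curve = data.frame(x = unique(xv), ale = 0), predictor = predictor,
      counts = length(xv), flat = TRUE), class = "ale_curve"))
  }
  breaks <- unique(as.numeric(quantile(xv, probs = seq(0, 1, length.out = grid_size + 1),
                                       type = 7)))
  k <- length(breaks) - 1L
  bin <- cut(xv, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  local_eff <- numeric(k)
  counts <- integer(k)
  for (b in seq_len(k)) {
    idx <- which(bin == b)
    counts[b] <- length(idx)
    if (!length(idx)) next
    lo <- x[idx, , drop = FALSE]; hi <- lo
    lo[[predictor]] <- breaks[b]
    hi[[predictor]] <- breaks[b + 1L]
    local_eff[b] <- mean(predict(fit, hi) - predict(fit, lo))
  }
  acc <- c(0, cumsum(local_eff))
  # observation-weighted centring: mean of the accumulated effect at the
  # bin each observation falls in (interpolated at bin midpoint level)
  centre <- sum(counts * (acc[-1L] + acc[-length(acc)]) / 2) / sum(counts)
  structure(list(curve = data.frame(x = breaks, ale = acc - centre),
                 predictor = predictor, counts = counts, flat = FALSE),
            class = "ale_curve")
}

#' @export
#' @method print ale_curve
print.ale_curve <- function(x, ...) {
  cat("ALE curve for", x$predictor,
      if (x$flat) "(constant predictor: flat zero)\n" else "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Assemble the predictor table for end-product-ratio modelling
#'
#' Combines edaphic variables, gene relative abundances (adding the
#' nosZ:nir ratio `(nosZI + nosZII) / (nirK + nirS)`), diversity indices
#' and module eigengene values for one treatment's samples, with the
#' denitrification end-product ratio as the response. Samples lacking the
#' response are dropped with a message.
#'
#' @param samples sample metadata data frame (needs `sample_id`,
#'   `treatment`, the edaphic and gene columns, `end_product_ratio`).
#' @param diversity optional data frame from [diversity_table()].
#' @param eigengenes optional samples x modules matrix/data frame of
#'   eigengene values (rownames = sample ids).
#' @param treatment treatment level to subset to (`NULL` keeps all).
#' @return data frame with one row per retained sample; response column
#'   `end_product_ratio`.
#' @export
build_predictor_table <- function(samples, diversity = NULL,
                                  eigengenes = NULL, treatment = NULL) {
  df <- as.data.frame(samples)
  if (!is.null(treatment)) df <- df[df$treatment == treatment, , drop = FALSE]
  if (!"end_product_ratio" %in% names(df))
    stop("samples lack an end_product_ratio column")
  if (all(c("nosZI", "nosZII", "nirK", "nirS") %in% names(df)))
    df$nosz_nir <- (df$nosZI + df$nosZII) / (df$nirK + df$nirS)
  if (!is.null(diversity)) {
    div <- as.data.frame(diversity)
    df <- merge(df, div, by = "sample_id", sort = FALSE)
  }
  if (!is.null(eigengenes)) {
    eg <- as.data.frame(eigengenes)
    eg$sample_id <- rownames(eigengenes)
    names(eg)[names(eg) != "sample_id"] <-
      paste0("module_", setdiff(names(eg), "sample_id"))
    df <- merge(df, eg, by = "sample_id", sort = FALSE)
  }
  missing <- is.na(df$end_product_ratio)
  if (any(missing)) {
    message("dropping ", sum(missing), " sample(s) without end-product ratio")
    df <- df[!missing, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
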