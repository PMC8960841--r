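#' Pearson correlation matrix over OTUs
#'
#' Correlations between all pairs of (log-ratio transformed) OTU
#' abundances across the samples of one treatment. Zero-variance OTUs are
#' excluded with a message.
#'
#' @param x samples x OTUs matrix (CLR-transformed abundances).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  if (nrow(x) < 3L) stop("need at least 3 samples")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " zero-variance OTU(s)")
    x <- x[, sds > 0, drop = FALSE]
  }
  stats::cor(x)
}

# Merge numerically degenerate eigenvalues, then unfold the spectrum to
# unit mean spacing via a smooth monotone cubic spline fitted to the
# empirical cumulative eigenvalue density on quantile knots.
unfold_spacings <- function(eig, merge_tol = 1e-10, spline_knots = 10) {
  e <- sort(eig)
  keep <- c(TRUE, diff(e) > merge_tol)
  e <- e[keep]
  m <- length(e)
  if (m < 12L) return(NULL)
  probs <- seq(0, 1, length.out = max(4L, min(spline_knots, m %/% 2L)))
  xk <- as.numeric(quantile(e, probs, type = 7))
  ok <- c(TRUE, diff(xk) > 0)
  fn <- stats::splinefun(xk[ok], probs[ok], method = "monoH.FC")
  xi <- m * pmin(pmax(fn(e), 0), 1)
  s <- diff(xi)
  s <- s[s >= 0]
  if (!length(s) || mean(s) == 0) return(NULL)
  s / mean(s)
}

#' Random-matrix-theory threshold scan of a correlation matrix
#'
#' For each candidate threshold, entries below it (in absolute value) are
#' zeroed, the eigenvalue spectrum is unfolded to unit mean spacing, and
#' the nearest-neighbour spacing distribution (NNSD) is compared to the
#' exponential law characteristic of uncorrelated (Poisson) spectra. Dense
#' noisy matrices show Gaussian-orthogonal-ensemble level repulsion; as
#' the threshold removes noise correlations the NNSD transitions to
#' exponential. The chosen threshold is the first (smallest) one whose
#' Kolmogorov-Smirnov test against Exp(1) is non-significant. A
#' sum-of-squared-errors curve between the spacing histogram and the
#' exponential density is emitted for goodness-of-fit inspection.
#'
#' @param R correlation matrix (the diagonal is retained throughout; it
#'   shifts the spectrum uniformly and leaves spacings untouched).
#' @param t_grid strictly increasing candidate thresholds in (0, 1).
#' @param alpha significance level for the KS test.
#' @param spline_knots knot count for the spectral unfolding spline.
#' @return object of class `rmt_scan`: data frame `scan` (threshold,
#'   `n_spacings`, `ks_stat`, `ks_p`, `sse`), chosen `r_T` (`NA` with a
#'   note when no threshold passes), `alpha`.
#' @export
rmt_threshold <- function(R, t_grid = seq(0.5, 0.98, by = 0.01),
                          alpha = 0.05, spline_knots = 10) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (nrow(R) < 50L)
    warning("fewer than 50 variables: eigenvalue spacing statistics are weak")
  if (any(diff(t_grid) <= 0) || any(t_grid <= 0) || any(t_grid >= 1))
    stop("t_grid must be strictly increasing within (0, 1)")
  scan <- data.frame(threshold = t_grid, n_spacings = NA_integer_,
                     ks_stat = NA_real_, ks_p = NA_real_, sse = NA_real_)
  for (i in seq_along(t_grid)) {
    A <- R
    A[abs(A) < t_grid[i]] <- 0
    diag(A) <- diag(R)
    eig <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    s <- unfold_spacings(eig, spline_knots = spline_knots)
    if (is.null(s)) next
    ks <- suppressWarnings(stats::ks.test(s, "pexp", 1))
    brk <- seq(0, max(3, max(s)) + 1e-9, length.out = 21L)
    h <- graphics::hist(s, breaks = brk, plot = FALSE)
    mids <- h$mids
    scan$n_spacings[i] <- length(s)
    scan$ks_stat[i] <- unname(ks$statistic)
    scan$ks_p[i] <- ks$p.value
    scan$sse[i] <- sum((h$density - exp(-mids))^2)
  }
  hit <- which(!is.na(scan$ks_p) & scan$ks_p > alpha)
  r_T <- if (length(hit)) t_grid[min(hit)] else NA_real_
  structure(list(scan = scan, r_T = r_T, alpha = alpha,
                 note = if (is.na(r_T)) "no transition detected" else NULL),
            class = "rmt_scan")
}

#' @export
#' @method print rmt_scan
print.rmt_scan <- function(x, ...) {
  cat("RMT threshold scan over", nrow(x$scan), "thresholds\n")
  if (is.na(x$r_T)) cat("  no transition detected (no KS p >", x$alpha, ")\n")
  else cat(sprintf("  chosen r_T = %.2f (first KS p > %g)\n", x$r_T, x$alpha))
  invisible(x)
}

#' Build a signed co-association graph at a correlation threshold
#'
#' Keeps pairs with `|r| >= r_T` (the sign is retained as the edge
#' weight), drops any edge whose BH-adjusted correlation p-value (computed
#' over all pairs, t-distribution) fails `q < q_max`, and removes isolated
#' nodes.
#'
#' @param R correlation matrix with OTU dimnames.
#' @param r_T threshold in (0, 1).
#' @param n_samples number of samples behind `R` (for the t-test).
#' @param q_max FDR ceiling for retained edges.
#' @return igraph object; attribute flag `empty` is set when no edge
#'   survives. Graph attributes record `r_T` and the count of edges
#'   removed by the FDR screen.
#' @export
build_graph <- function(R, r_T, n_samples, q_max = 0.001) {
  if (!(r_T > 0 && r_T <= 1)) stop("r_T must lie in (0, 1]")
  ut <- upper.tri(R)
  r <- R[ut]
  tt <- r * sqrt((n_samples - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tt), df = n_samples - 2)
  q <- p.adjust(p, method = "BH")
  keep <- abs(r) >= r_T & q < q_max
  dropped <- sum(abs(r) >= r_T & q >= q_max)
  A <- matrix(0, nrow(R), ncol(R), dimnames = dimnames(R))
  A[ut][keep] <- r[keep]
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g <- igraph::set_graph_attr(g, "r_T", r_T)
  g <- igraph::set_graph_attr(g, "fdr_dropped", dropped)
  if (dropped > 0)
    message(dropped, " edge(s) above threshold dropped by the FDR screen")
  if (igraph::ecount(g) == 0) attr(g, "empty") <- TRUE
  g
}

# ---- shared topology metric helpers -------------------------------------

positive_subgraph <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$weight > 0],
                                     delete.vertices = FALSE)
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

unweighted <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

avg_jaccard <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  sim <- igraph::similarity(g, method = "jaccard")
  adj <- igraph::as_adj_list(g)
  per_node <- vapply(seq_along(adj), function(i) {
    nb <- as.integer(adj[[i]])
    if (!length(nb)) return(NA_real_)
    mean(sim[i, nb])
  }, numeric(1))
  mean(per_node, na.rm = TRUE)
}

ebet_partition <- function(g) {
  igraph::cluster_edge_betweenness(unweighted(g))
}

#' Topology metrics of a co-association network
#'
#' Computed on the positive-edge subgraph (isolated nodes removed): node
#' and edge counts, diameter and average path length (on the largest
#' connected component, flagged when the graph is disconnected), mean
#' degree, global transitivity, modularity of the edge-betweenness
#' partition, connectance, and the average over nodes of the mean Jaccard
#' similarity between a node's neighbour set and each neighbour's.
#'
#' @param g igraph object with signed `weight` edge attribute.
#' @param positive_only restrict to positive edges first (default).
#' @return object of class `topology_report` (a named list).
#' @export
topology_metrics <- function(g, positive_only = TRUE) {
  if (positive_only) g <- positive_subgraph(g)
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0)
    stop("graph is empty after restriction to positive edges")
  comp <- igraph::components(g)
  disconnected <- comp$no > 1L
  lcc <- if (disconnected) {
    igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  } else g
  lcc_u <- unweighted(lcc)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  part <- ebet_partition(g)
  structure(list(
    nodes = nv, edges = ne,
    diameter = igraph::diameter(lcc_u),
    avg_path_length = igraph::mean_distance(lcc_u),
    mean_degree = mean(igraph::degree(g)),
    transitivity = igraph::transitivity(unweighted(g), type = "global"),
    modularity = igraph::modularity(part),
    connectance = ne / (nv * (nv - 1) / 2),
    avg_jaccard = avg_jaccard(g),
    disconnected = disconnected,
    n_components = comp$no), class = "topology_report")
}

#' @export
#' @method print topology_report
print.topology_report <- function(x, ...) {
  cat("Network topology (positive-edge subgraph)\n")
  cat(sprintf("  nodes %d, edges %d, connectance %.4f\n",
              x$nodes, x$edges, x$connectance))
  cat(sprintf("  diameter %d, avg path %.3f%s\n", x$diameter,
              x$avg_path_length,
              if (x$disconnected) sprintf(" (largest of %d components)",
                                          x$n_components) else ""))
  cat(sprintf("  mean degree %.2f, transitivity %.3f, modularity %.3f, avg Jaccard %.4f\n",
              x$mean_degree, x$transitivity, x$modularity, x$avg_jaccard))
  invisible(x)
}

# named metric functions usable in ER null tests
topology_metric_fn <- function(name) {
  switch(name,
    transitivity = function(g) igraph::transitivity(g, type = "global"),
    diameter = function(g) {
      comp <- igraph::components(g)
      igraph::diameter(igraph::induced_subgraph(
        g, which(comp$membership == which.max(comp$csize))))
    },
    avg_path_length = function(g) {
      comp <- igraph::components(g)
      igraph::mean_distance(igraph::induced_subgraph(
        g, which(comp$membership == which.max(comp$csize))))
    },
    modularity = function(g) igraph::modularity(ebet_partition(g)),
    mean_degree = function(g) mean(igraph::degree(g)),
    avg_jaccard = avg_jaccard,
    stop("unknown metric: ", name))
}

#' Erdos-Renyi null test of a network metric
#'
#' Draws `reps` G(n, m) random graphs with the observed node and edge
#' counts, computes the metric on each, and returns the empirical
#' two-tailed p-value `2 * min(#{null >= obs}, #{null <= obs}) / reps`,
#' floored at `1/reps`. Draws where the metric is undefined are excluded
#' and counted.
#'
#' @param metric metric name (`"transitivity"`, `"diameter"`,
#'   `"avg_path_length"`, `"modularity"`, `"mean_degree"`,
#'   `"avg_jaccard"`) or a function of an igraph object.
#' @param observed observed metric value.
#' @param n_nodes,n_edges null-model dimensions.
#' @param reps number of random graphs.
#' @param seed integer seed.
#' @return list: `p`, `null_values`, `n_excluded`.
#' @export
er_null_test <- function(metric, observed, n_nodes, n_edges, reps = 1000,
                         seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("n_edges exceeds the possible maximum")
  fn <- if (is.function(metric)) metric else topology_metric_fn(metric)
  set.seed(derive_seed(seed, "er_null"))
  vals <- vapply(seq_len(reps), function(i) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    v <- tryCatch(fn(g), error = function(e) NA_real_)
    if (is.null(v) || !is.finite(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  excluded <- sum(is.na(vals))
  vals_ok <- vals[!is.na(vals)]
  if (!length(vals_ok)) stop("metric undefined on every null draw")
  p <- 2 * min(sum(vals_ok >= observed), sum(vals_ok <= observed)) / length(vals_ok)
  p <- min(max(p, 1 / length(vals_ok)), 1)
  list(p = p, null_values = vals_ok, n_excluded = excluded)
}

#' Edge-betweenness module detection
#'
#' Girvan-Newman hierarchical edge removal on the (unweighted) positive
#' edge graph; the partition maximizing modularity is kept, and modules
#' with at least `min_size` nodes are retained (smaller ones are left
#' unassigned). Modules are labelled `M1`, `M2`, ... in decreasing size.
#'
#' @param g igraph object (positive-edge co-association network).
#' @param min_size minimum module size retained.
#' @return list of class `module_partition`: `modules` (named list of OTU
#'   id vectors), `membership` (named module label per node, `NA` when
#'   unassigned), `modularity`, and the raw `communities` object.
#' @export
detect_modules <- function(g, min_size = 5) {
  comm <- ebet_partition(positive_subgraph(g))
  memb <- igraph::membership(comm)
  labels <- names(memb)
  tab <- sort(table(as.integer(memb)), decreasing = TRUE)
  kept <- names(tab)[tab >= min_size]
  modules <- list()
  assign <- setNames(rep(NA_character_, length(memb)), labels)
  for (i in seq_along(kept)) {
    id <- paste0("M", i)
    members <- labels[as.integer(memb) == as.integer(kept[i])]
    modules[[id]] <- members
    assign[members] <- id
  }
  structure(list(modules = modules, membership = assign,
                 modularity = igraph::modularity(comm),
                 communities = comm), class = "module_partition")
}

#' Module eigengene (first principal component of member abundances)
#'
#' Columns (members) are standardized; the eigengene is the unit-norm
#' first principal component score vector across samples, oriented to
#' correlate positively with the members' mean standardized abundance so
#' that larger values mean "module more abundant". Variance explained is
#' the leading eigenvalue's share.
#'
#' @param x samples x OTUs abundance matrix (CLR scale by default in the
#'   pipeline; any per-member monotone rescaling leaves the result
#'   unchanged up to sign because columns are standardized).
#' @param members OTU ids of the module (at least 5).
#' @param orient_to_mean orient the sign as described (default).
#' @return object of class `module_eigengene`: `eigengene` (named by
#'   sample, unit norm), `var_explained`, `members`, `flipped`.
#' @export
module_eigengene <- function(x, members, orient_to_mean = TRUE) {
  missing <- setdiff(members, colnames(x))
  if (length(missing)) stop("members absent from matrix: ",
                            paste(head(missing, 5), collapse = ", "))
  if (length(members) < 5L) stop("need at least 5 module members")
  xm <- x[, members, drop = FALSE]
  sds <- apply(xm, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant member column(s)")
    xm <- xm[, sds > 0, drop = FALSE]
  }
  xs <- scale(xm)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  ve <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  v <- pc$x[, 1L]
  v <- v / sqrt(sum(v^2))
  flipped <- FALSE
  if (orient_to_mean) {
    m <- rowMeans(xs)
    if (sum(v * m) < 0) { v <- -v; flipped <- TRUE }
  }
  structure(list(eigengene = setNames(v, rownames(x)),
                 var_explained = ve, members = colnames(xm),
                 flipped = flipped), class = "module_eigengene")
}

#' Spearman correlations between module eigengenes and sample variables
#'
#' @param eigengenes samples x modules matrix or data frame of eigengene
#'   values.
#' @param vars data frame of numeric sample variables (aligned rows).
#' @param alpha significance level used for the `significant` flag.
#' @return long data frame: `module`, `variable`, `rho`, `p`,
#'   `significant`. Variables that are entirely missing are skipped.
#' @export
correlate_modules <- function(eigengenes, vars, alpha = 0.05) {
  eigengenes <- as.data.frame(eigengenes)
  vars <- as.data.frame(vars)
  stopifnot(nrow(eigengenes) == nrow(vars))
  out <- list()
  for (mod in names(eigengenes)) for (v in names(vars)) {
    y <- vars[[v]]
    if (!is.numeric(y) || all(is.na(y))) next
    ct <- suppressWarnings(cor.test(eigengenes[[mod]], y, method = "spearman"))
    out[[length(out) + 1L]] <- data.frame(
      module = mod, variable = v, rho = unname(ct$estimate), p = ct$p.value,
      significant = ct$p.value <= alpha)
  }
  do.call(rbind, out)
}
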