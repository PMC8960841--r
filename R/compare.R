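edge_keys <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(el)) return(character(0))
  paste(pmin(el$from, el$to), pmax(el$from, el$to), sep = "|")
}

#' Common and unique edges between two networks
#'
#' Edge membership is decided by the unordered node pair; weights are
#' ignored for membership but carried along in the output.
#'
#' @param graph_a,graph_b igraph objects with comparable node labels.
#' @return object of class `network_diff` with data frames `common`
#'   (columns `from`, `to`, `weight_a`, `weight_b`), `unique_a`,
#'   `unique_b`.
#' @export
diff_edges <- function(graph_a, graph_b) {
  ea <- igraph::as_data_frame(graph_a, what = "edges")
  eb <- igraph::as_data_frame(graph_b, what = "edges")
  if (!nrow(ea)) ea <- data.frame(from = character(0), to = character(0),
                                  weight = numeric(0))
  if (!nrow(eb)) eb <- data.frame(from = character(0), to = character(0),
                                  weight = numeric(0))
  if (is.null(ea$weight)) ea$weight <- 1
  if (is.null(eb$weight)) eb$weight <- 1
  ka <- paste(pmin(ea$from, ea$to), pmax(ea$from, ea$to), sep = "|")
  kb <- paste(pmin(eb$from, eb$to), pmax(eb$from, eb$to), sep = "|")
  shared <- intersect(ka, kb)
  split_key <- function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, "", 1L),
               to = vapply(parts, `[`, "", 2L))
  }
  common <- if (length(shared)) {
    df <- split_key(shared)
    df$weight_a <- ea$weight[match(shared, ka)]
    df$weight_b <- eb$weight[match(shared, kb)]
    df
  } else data.frame(from = character(0), to = character(0),
                    weight_a = numeric(0), weight_b = numeric(0))
  ua <- ea[!(ka %in% shared), c("from", "to", "weight")]
  ub <- eb[!(kb %in% shared), c("from", "to", "weight")]
  rownames(ua) <- rownames(ub) <- NULL
  structure(list(common = common, unique_a = ua, unique_b = ub),
            class = "network_diff")
}

#' @export
#' @method print network_diff
print.network_diff <- function(x, ...) {
  cat(sprintf("Network edge comparison: %d common, %d unique to A, %d unique to B\n",
              nrow(x$common), nrow(x$unique_a), nrow(x$unique_b)))
  invisible(x)
}

# weight vector of a node's incident positive edges over a neighbourhood
incidence_vector <- function(g, node, nbrs) {
  v <- setNames(rep(0, length(nbrs)), nbrs)
  if (!node %in% igraph::V(g)$name) return(v)
  inc <- igraph::incident(g, node)
  if (!length(inc)) return(v)
  ends <- igraph::ends(g, inc)
  other <- ifelse(ends[, 1L] == node, ends[, 2L], ends[, 1L])
  w <- igraph::E(g)$weight[as.integer(inc)]
  v[other] <- abs(w)
  v
}

#' Per-node rewiring scores between two networks
#'
#' For each node the incident (positive) edges in each network are
#' represented as a weight vector over the union neighbourhood, with zero
#' for absent edges. Both vectors are normalized to unit length and the
#' rewiring score is the mean squared Euclidean distance of the two
#' vectors to their centroid (equivalently `|v_A - v_B|^2 / 4`): 0 for
#' identical incidence, 0.5 for completely disjoint neighbourhoods. A
#' degree-corrected score divides by the union-neighbourhood size. Nodes
#' present in only one network receive the maximal score (0.5) and are
#' flagged; nodes isolated in both receive 0.
#'
#' @param graph_a,graph_b igraph objects with signed `weight` edges.
#' @param positive_only use only positive edges with `|r|` weights
#'   (default, matching the positive co-association comparisons).
#' @return data frame: `node`, `d_n`, `d_n_corrected`, `n_union`, `flag`.
#' @export
rewiring_scores <- function(graph_a, graph_b, positive_only = TRUE) {
  if (positive_only) {
    graph_a <- positive_subgraph(graph_a)
    graph_b <- positive_subgraph(graph_b)
  }
  na <- igraph::V(graph_a)$name
  nb <- igraph::V(graph_b)$name
  if (!length(intersect(na, nb))) stop("graphs share no node")
  all_nodes <- union(na, nb)
  out <- lapply(all_nodes, function(nd) {
    in_a <- nd %in% na; in_b <- nd %in% nb
    nbr_a <- if (in_a) igraph::V(graph_a)$name[
      as.integer(igraph::neighbors(graph_a, nd))] else character(0)
    nbr_b <- if (in_b) igraph::V(graph_b)$name[
      as.integer(igraph::neighbors(graph_b, nd))] else character(0)
    nbrs <- union(nbr_a, nbr_b)
    if (!in_a || !in_b)
      return(data.frame(node = nd, d_n = 0.5,
                        d_n_corrected = 0.5 / max(1L, length(nbrs)),
                        n_union = length(nbrs),
                        flag = if (in_a) "only_in_A" else "only_in_B"))
    if (!length(nbrs))
      return(data.frame(node = nd, d_n = 0, d_n_corrected = 0, n_union = 0L,
                        flag = "isolated_in_both"))
    va <- incidence_vector(graph_a, nd, nbrs)
    vb <- incidence_vector(graph_b, nd, nbrs)
    norm <- function(v) if (sum(v^2) > 0) v / sqrt(sum(v^2)) else v
    va <- norm(va); vb <- norm(vb)
    d <- sum((va - vb)^2) / 4
    data.frame(node = nd, d_n = d, d_n_corrected = d / length(nbrs),
               n_union = length(nbrs), flag = "shared")
  })
  do.call(rbind, out)
}

#' Cross-tabulate module membership between two partitions
#'
#' Maps every module of network A to its best-matched counterpart in
#' network B (maximum Jaccard overlap) and lists, per pair, the shared
#' OTUs and those present on one side only. The mapping is many-to-one:
#' if a module splits into two in the other network, both halves map to
#' the same counterpart. B modules matched by no A module appear with an
#' `NA` counterpart, as do A modules with zero overlap everywhere.
#'
#' @param modules_a,modules_b named lists of OTU id vectors (from
#'   [detect_modules()], element `modules`).
#' @return list: `table` (data frame `module_a`, `module_b`, `jaccard`,
#'   `n_shared`, `n_a_only`, `n_b_only`) and `members` (named list with
#'   `shared`, `a_only`, `b_only` per matched pair).
#' @export
classify_module_membership <- function(modules_a, modules_b) {
  empty <- data.frame(module_a = character(0), module_b = character(0),
                      jaccard = numeric(0), n_shared = integer(0),
                      n_a_only = integer(0), n_b_only = integer(0))
  if (!length(modules_a) && !length(modules_b))
    return(list(table = empty, members = list()))
  rows <- list(); members <- list()
  matched_b <- character(0)
  for (i in seq_along(modules_a)) {
    a <- modules_a[[i]]
    jac <- vapply(modules_b, function(b)
      length(intersect(a, b)) / length(union(a, b)), numeric(1))
    if (length(jac) && max(jac) > 0) {
      j <- which.max(jac)
      b <- modules_b[[j]]
      matched_b <- c(matched_b, names(modules_b)[j])
      key <- paste(names(modules_a)[i], names(modules_b)[j], sep = ":")
      members[[key]] <- list(shared = intersect(a, b),
                             a_only = setdiff(a, b), b_only = setdiff(b, a))
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = names(modules_a)[i], module_b = names(modules_b)[j],
        jaccard = jac[j], n_shared = length(intersect(a, b)),
        n_a_only = length(setdiff(a, b)), n_b_only = length(setdiff(b, a)))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = names(modules_a)[i], module_b = NA_character_,
        jaccard = 0, n_shared = 0L, n_a_only = length(a), n_b_only = 0L)
    }
  }
  for (j in setdiff(names(modules_b), matched_b))
    rows[[length(rows) + 1L]] <- data.frame(
      module_a = NA_character_, module_b = j, jaccard = 0, n_shared = 0L,
      n_a_only = 0L, n_b_only = length(modules_b[[j]]))
  tab <- if (length(rows)) do.call(rbind, rows) else empty
  list(table = tab, members = members)
}
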