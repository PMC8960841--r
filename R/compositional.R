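#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts by their posterior-expected proportions under a
#' Dirichlet prior and rescales the non-zero parts multiplicatively so
#' that each sample keeps its original total and the ratios between
#' observed parts are untouched. The prior strength defaults to the square
#' root of the sample total with uniform part weights; imputed proportions
#' are capped at a fraction of the smallest observed non-zero proportion
#' of the sample so a replacement can never rival an observed value.
#'
#' @param counts samples x parts count matrix; no all-zero samples.
#' @param strength prior strength per sample; `"sqrt"` (default) uses
#'   `sqrt(total)`, or supply a numeric value used for every sample.
#' @param cap_frac cap on imputed proportions, as a fraction of the
#'   sample's minimum non-zero proportion.
#' @return strictly positive matrix on the original count scale, with
#'   attribute `closure` holding the per-sample totals.
#' @export
impute_zeros <- function(counts, strength = "sqrt", cap_frac = 0.65) {
  if (any(counts < 0)) stop("negative counts")
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("input error: sample with zero total")
  D <- ncol(counts)
  out <- counts
  for (s in seq_len(nrow(counts))) {
    x <- counts[s, ]
    zero <- x == 0
    if (!any(zero)) { out[s, ] <- x; next }
    n <- totals[s]
    s_i <- if (identical(strength, "sqrt")) sqrt(n) else as.numeric(strength)
    p_rep <- (s_i / D) / (n + s_i)
    min_nz <- min(x[!zero]) / n
    p_rep <- min(p_rep, cap_frac * min_nz)
    p <- x / n
    p[zero] <- p_rep
    p[!zero] <- p[!zero] * (1 - sum(zero) * p_rep)
    out[s, ] <- p * n
  }
  attr(out, "closure") <- totals
  out
}

#' Centred log-ratio transform
#'
#' `clr(x)_ij = log(x_ij) - mean_j log(x_ij)`. Rows sum to zero; the
#' transform is invariant to per-sample scaling, which removes the
#' arbitrary sequencing-depth constraint from compositional count data.
#'
#' @param x strictly positive samples x parts matrix.
#' @return real matrix of the same shape.
#' @export
clr_transform <- function(x) {
  if (any(x <= 0)) stop("domain error: clr requires strictly positive entries")
  lx <- log(x)
  sweep(lx, 1L, rowMeans(lx))
}

#' Phylogenetic isometric log-ratio (balance) transform
#'
#' Maps a composition onto the orthonormal balance coordinates of a rooted
#' binary phylogeny. Each internal node contributes one balance
#' contrasting the geometric means of the taxa descending from its two
#' children:
#' \deqn{b_v = \sqrt{n_L n_R / (n_L + n_R)} \, \log( g(x_L) / g(x_R) )}
#' with the first child in the tree's edge order as the numerator, so a
#' positive balance means higher abundance on the numerator side. No taxon
#' or branch-length weighting is applied. Euclidean distance between
#' samples in balance space equals the Aitchison (CLR-Euclidean) distance.
#'
#' @param x strictly positive samples x parts matrix; column names must
#'   equal the tree's tip labels (any order).
#' @param tree rooted binary [ape::phylo] whose tips are the parts.
#' @return samples x (tips - 1) balance matrix; columns named `n<node>`
#'   after the internal node numbers. Attribute `node_info` is a data
#'   frame with the node id, child tip counts `n_num`/`n_den`, and
#'   attribute `basis` lists numerator and denominator tips per node.
#' @export
philr_transform <- function(x, tree) {
  n_tip <- length(tree$tip.label)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("structure error: tree must be rooted and binary")
  if (!setequal(colnames(x), tree$tip.label))
    stop("id error: composition parts must match tree tips")
  if (any(x <= 0)) stop("domain error: strictly positive composition required")
  x <- x[, tree$tip.label, drop = FALSE]
  lx <- log(x)

  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  balances <- matrix(0, nrow(x), length(internal),
                     dimnames = list(rownames(x), paste0("n", internal)))
  info <- data.frame(node = internal, n_num = 0L, n_den = 0L)
  basis <- vector("list", length(internal))
  names(basis) <- paste0("n", internal)
  for (j in seq_along(internal)) {
    nd <- internal[j]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    if (length(kids) != 2L) stop("structure error: non-binary node ", nd)
    num_tips <- tips_under(tree, kids[1L])
    den_tips <- tips_under(tree, kids[2L])
    nL <- length(num_tips); nR <- length(den_tips)
    coefv <- sqrt(nL * nR / (nL + nR))
    g_num <- if (nL == 1L) lx[, num_tips] else rowMeans(lx[, num_tips, drop = FALSE])
    g_den <- if (nR == 1L) lx[, den_tips] else rowMeans(lx[, den_tips, drop = FALSE])
    balances[, j] <- coefv * (g_num - g_den)
    info$n_num[j] <- nL; info$n_den[j] <- nR
    basis[[j]] <- list(numerator = tree$tip.label[num_tips],
                       denominator = tree$tip.label[den_tips])
  }
  attr(balances, "node_info") <- info
  attr(balances, "basis") <- basis
  balances
}

#' Write a balance matrix with its sidecar basis description
#'
#' @param balances output of [philr_transform()].
#' @param path TSV output path; the basis mapping (numerator and
#'   denominator tips per node) goes to `<path>.basis.json`.
#' @export
write_balances <- function(balances, path) {
  df <- data.frame(sample_id = rownames(balances), balances,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basis <- attr(balances, "basis")
  if (!is.null(basis))
    jsonlite::write_json(basis, paste0(path, ".basis.json"))
  invisible(path)
}
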