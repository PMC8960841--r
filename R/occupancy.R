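#' Mean of repeatedly rarefied count tables
#'
#' Subsamples every sample to a common depth without replacement, many
#' times, and returns the element-wise mean table. Rarefying removes
#' library-size effects before the dispersion index is computed; averaging
#' over replicates removes most of the subsampling noise.
#'
#' Each sample uses its own RNG stream derived from `seed` and the sample
#' id, so results do not depend on sample order or on which other samples
#' are present.
#'
#' @param counts samples x OTUs count matrix.
#' @param depth target depth; defaults to the smallest sample total.
#'   Samples whose total is below `depth` are dropped with a warning.
#' @param n_reps number of independent rarefactions averaged.
#' @param seed integer seed.
#' @return real-valued matrix (kept samples x OTUs) of mean rarefied counts.
#' @export
rarefy_mean <- function(counts, depth = NULL, n_reps = 100, seed = 1L) {
  validate_counts(counts)
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  if (depth <= 0) stop("parameter error: depth must be positive")
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped")
    counts <- counts[keep, , drop = FALSE]
  }
  n_otu <- ncol(counts)
  out <- matrix(0, nrow(counts), n_otu, dimnames = dimnames(counts))
  for (s in seq_len(nrow(counts))) {
    set.seed(derive_seed(seed, rownames(counts)[s]))
    reads <- rep.int(seq_len(n_otu), counts[s, ])
    acc <- numeric(n_otu)
    if (length(reads) == depth) {
      acc <- counts[s, ] * n_reps
    } else {
      for (r in seq_len(n_reps)) {
        idx <- sample.int(length(reads), depth)
        acc <- acc + tabulate(reads[idx], nbins = n_otu)
      }
    }
    out[s, ] <- acc / n_reps
  }
  out
}

#' Index of dispersion per OTU
#'
#' For each OTU, computes the mean abundance across samples, the sample
#' variance, the occupancy (proportion of samples where the OTU is
#' present), the index of dispersion `I = (variance / mean) * occupancy`,
#' and an upper-tail p-value of the dispersion statistic `I * (n - 1)`
#' against the chi-squared distribution with `n - 1` degrees of freedom.
#' Under Poisson (random placement) counts the variance-to-mean ratio is
#' near one and the statistic behaves like chi-squared; overdispersed,
#' widely occupied OTUs exceed the upper critical value.
#'
#' @param mat samples x OTUs abundance matrix (typically mean rarefied).
#' @return data frame with one row per OTU: `otu_id`, `mean_abundance`,
#'   `variance`, `occupancy`, `index`, `statistic`, `p_value`.
#' @export
dispersion_records <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 samples")
  n <- nrow(mat)
  mu <- colMeans(mat)
  v <- apply(mat, 2L, var)
  occ <- colMeans(mat > 0)
  I <- ifelse(mu > 0, (v / mu) * occ, 0)
  stat <- I * (n - 1)
  data.frame(otu_id = colnames(mat), mean_abundance = mu, variance = v,
             occupancy = occ, index = I, statistic = stat,
             p_value = pchisq(stat, df = n - 1, lower.tail = FALSE),
             row.names = NULL)
}

#' Dispersion record for a single OTU
#'
#' @param mat samples x OTUs abundance matrix.
#' @param otu OTU id (column name).
#' @return one-row data frame, see [dispersion_records()].
#' @export
dispersion_index <- function(mat, otu) {
  if (!otu %in% colnames(mat)) stop("unknown OTU: ", otu)
  if (nrow(mat) < 2L) stop("need at least 2 samples")
  x <- mat[, otu]
  n <- length(x)
  mu <- mean(x)
  v <- var(x)
  I <- if (mu > 0) (v / mu) * mean(x > 0) else 0
  stat <- I * (n - 1)
  data.frame(otu_id = otu, mean_abundance = mu, variance = v,
             occupancy = mean(x > 0), index = I, statistic = stat,
             p_value = pchisq(stat, df = n - 1, lower.tail = FALSE),
             row.names = NULL)
}

#' Partition OTUs into frequent and rare sets
#'
#' Frequent OTUs are those whose dispersion statistic exceeds the
#' upper-tail chi-squared critical value at `alpha` (equivalently
#' `p_value < alpha`); the rest are rare. The two sets are disjoint and
#' exhaustive.
#'
#' @param records output of [dispersion_records()].
#' @param n_samples number of samples the records were computed from.
#' @param alpha upper-tail significance level.
#' @return list with character vectors `frequent` and `rare`.
#' @export
partition_frequent <- function(records, n_samples, alpha = 0.05) {
  if (n_samples < 2L) stop("parameter error: n_samples must be >= 2")
  crit <- stats::qchisq(1 - alpha, df = n_samples - 1)
  frequent <- records$otu_id[records$statistic > crit]
  list(frequent = frequent, rare = setdiff(records$otu_id, frequent))
}
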