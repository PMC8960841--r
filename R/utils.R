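#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov coef cor cor.test density dist ecdf lm median
#'   na.omit p.adjust pchisq pexp pnorm prcomp predict pt quantile rbinom
#'   rexp rlnorm rmultinom rnorm runif sd setNames var AIC logLik as.formula
#' @importFrom utils read.delim write.table head packageVersion
NULL

# Deterministic per-stage seed derivation: mixes a master seed with a stage
# label so that running a subset of stages reproduces the full-run streams.
# Result is kept inside the 32-bit signed-integer range R requires.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Validate a samples x OTUs count matrix.
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample ids (rownames) and OTU ids (colnames)")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate sample or OTU ids")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and complete")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 samples and 2 OTUs")
  invisible(counts)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Adjusted Rand index between two labelled partitions (vectors aligned on
# names or position). Used for planted-module recovery checks.
#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors over the same items (matched by name when both
#'   are named, otherwise by position). `NA` labels are dropped pairwise.
#' @return numeric scalar in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) return(NA_real_)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
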