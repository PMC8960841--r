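#' Default ground-truth parameters for a synthetic fertilization study
#'
#' Returns the parameter list consumed by [generate_study()]. The defaults
#' emulate a multi-site paired fertilization trial: a log-normal species
#' abundance distribution for frequent OTUs, planted correlated OTU modules
#' whose coupling can differ between treatments, fertilization effects on
#' whole clades, sparse low-occupancy rare OTUs with Poisson-like counts,
#' and an end-product ratio driven through a logistic link by pH, one
#' module's latent abundance and the nosZ:nir gene ratio.
#'
#' @param module_sizes OTU count per planted module.
#' @param module_rho within-module latent correlation, a `length(module_sizes)`
#'   x 2 matrix (columns unfertilized, fertilized) or a single value.
#' @param site_sd,plot_sd standard deviations of the per-(site, OTU) and
#'   per-(sample, OTU) log-abundance noise components.
#' @param sad_sd spread (log scale) of frequent-OTU base abundances.
#' @param n_effect_clades number of clades (of the frequent-OTU tree)
#'   receiving a fertilization log-fold effect.
#' @param effect_size natural-log abundance shift applied to effect-clade
#'   OTUs in fertilized samples.
#' @param clade_size_range admissible clade sizes (tips) for planted effects.
#' @param rare_occupancy_range,rare_lambda_range occupancy and expected
#'   present-sample count ranges for rare OTUs.
#' @param ratio_model named coefficients of the end-product-ratio model:
#'   `intercept`, `ph`, `module` (latent abundance of the first module),
#'   `nosz_nir`, `fert`, and `noise_sd` (on the logit scale).
#' @param depth_meanlog,depth_sdlog sequencing depth log-normal parameters.
#' @return a named list of parameters.
#' @export
study_truth_params <- function(module_sizes = c(20, 20, 20, 20),
                               module_rho = cbind(unfertilized = c(0.8, 0.8, 0.8, 0.2),
                                                  fertilized = c(0.8, 0.8, 0.2, 0.8)),
                               site_sd = 0.75, plot_sd = 0.5, sad_sd = 1.2,
                               n_effect_clades = 2, effect_size = 0.5,
                               clade_size_range = c(8, 40),
                               rare_occupancy_range = c(0.02, 0.22),
                               rare_lambda_range = c(0.5, 3),
                               ratio_model = c(intercept = -1, ph = -0.7,
                                               module = 0.5, nosz_nir = -0.5,
                                               fert = 0.4, noise_sd = 0.3),
                               depth_meanlog = log(4e4), depth_sdlog = 0.2) {
  if (is.null(dim(module_rho)))
    module_rho <- cbind(unfertilized = rep(module_rho, length.out = length(module_sizes)),
                        fertilized = rep(module_rho, length.out = length(module_sizes)))
  stopifnot(nrow(module_rho) == length(module_sizes), all(abs(module_rho) <= 1))
  list(module_sizes = module_sizes, module_rho = module_rho,
       site_sd = site_sd, plot_sd = plot_sd, sad_sd = sad_sd,
       n_effect_clades = n_effect_clades, effect_size = effect_size,
       clade_size_range = clade_size_range,
       rare_occupancy_range = rare_occupancy_range,
       rare_lambda_range = rare_lambda_range,
       ratio_model = ratio_model,
       depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog)
}

#' Planted block-correlation matrix
#'
#' Builds a correlation matrix with equicorrelated diagonal blocks (the
#' planted modules) and a constant between-block correlation, repaired to
#' positive semi-definiteness by eigenvalue clipping.
#'
#' @param n_otus matrix dimension.
#' @param module_spec data frame (or list coercible to one) with columns
#'   `size` and `rho`; blocks occupy the leading rows/columns in order.
#' @param rho_between correlation between members of different modules.
#' @return correlation matrix with attribute `modules` (block id per
#'   variable, `NA` outside blocks).
#' @export
generate_planted_correlation <- function(n_otus, module_spec, rho_between = 0) {
  spec <- as.data.frame(module_spec)
  stopifnot(all(c("size", "rho") %in% names(spec)), all(abs(spec$rho) <= 1))
  if (sum(spec$size) > n_otus) stop("module sizes exceed n_otus")
  R <- diag(n_otus)
  membership <- rep(NA_integer_, n_otus)
  offset <- 0L
  for (m in seq_len(nrow(spec))) {
    idx <- offset + seq_len(spec$size[m])
    R[idx, idx] <- spec$rho[m]
    membership[idx] <- m
    offset <- offset + spec$size[m]
  }
  if (rho_between != 0) {
    for (m1 in seq_len(nrow(spec))) for (m2 in seq_len(nrow(spec))) {
      if (m1 != m2)
        R[which(membership == m1), which(membership == m2)] <- rho_between
    }
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-12) {
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  R <- (R + t(R)) / 2
  attr(R, "modules") <- membership
  R
}

#' Generate a synthetic multi-site fertilization study
#'
#' Produces a full study — count matrix, sample metadata, OTU phylogeny —
#' together with the ground truth used to generate it, so that every
#' downstream stage (occupancy filtering, balance tests, network module
#' detection, variable-importance modelling) has a recovery test.
#'
#' Frequent OTUs follow a multivariate log-normal latent abundance model
#' with site offsets, planted within-module correlation (possibly
#' treatment-specific) and clade-level fertilization effects; rare OTUs are
#' sparse (occupancy below 25 percent) with Poisson-consistent counts.
#' Counts are multinomial draws at a log-normal sequencing depth, which
#' preserves the compositional coupling the log-ratio transforms assume.
#' The phylogeny is a Kingman coalescent over all OTUs, scaled to unit
#' height.
#'
#' @param n_sites number of field trials (sites).
#' @param plots_per_treatment replicate plots per treatment within a site.
#' @param n_frequent,n_rare OTU counts in the two abundance classes.
#' @param truth_params parameter list from [study_truth_params()].
#' @param seed integer master seed.
#' @return a list of class `denit_study` with elements `counts`
#'   (samples x OTUs), `samples` (metadata data frame), `tree`
#'   ([ape::phylo] over all OTUs) and `truth` (class `study_truth`).
#' @export
generate_study <- function(n_sites = 14, plots_per_treatment = 4,
                           n_frequent = 600, n_rare = 3000,
                           truth_params = study_truth_params(),
                           seed = 1L) {
  if (n_sites < 2) stop("parameter error: n_sites must be >= 2")
  if (plots_per_treatment < 2) stop("parameter error: plots_per_treatment must be >= 2")
  p <- truth_params
  if (sum(p$module_sizes) > n_frequent)
    stop("parameter error: module sizes exceed n_frequent")
  set.seed(derive_seed(seed, "study"))

  otu_freq <- sprintf("OTU%04d", seq_len(n_frequent))
  otu_rare <- sprintf("ROTU%04d", seq_len(n_rare))
  otu_ids <- c(otu_freq, otu_rare)
  n_otu <- length(otu_ids)

  treatments <- c("unfertilized", "fertilized")
  design <- expand.grid(plot = seq_len(plots_per_treatment),
                        treatment = treatments, site = sprintf("S%02d", seq_len(n_sites)),
                        stringsAsFactors = FALSE)
  design$treatment <- factor(design$treatment, levels = treatments)
  design$sample_id <- sprintf("%s_%s_%d", design$site,
                              ifelse(design$treatment == "fertilized", "F", "U"),
                              design$plot)
  n_samp <- nrow(design)
  fert <- as.integer(design$treatment == "fertilized")

  ## -- phylogeny: coalescent over all OTUs, unit height, random tip labels
  tree <- ape::rcoal(n_otu, tip.label = sample(otu_ids))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))

  ## planted fertilization effects on clades of the frequent-OTU subtree
  ftree <- ape::keep.tip(tree, otu_freq)
  clade_sizes <- vapply((n_frequent + 1):(2L * n_frequent - 1L), function(nd)
    length(tips_under(ftree, nd)), integer(1))
  candidates <- which(clade_sizes >= p$clade_size_range[1] &
                      clade_sizes <= p$clade_size_range[2]) + n_frequent
  effect_otus <- character(0)
  effect_clades <- list()
  if (p$n_effect_clades > 0 && length(candidates)) {
    picked <- character(0)
    for (nd in sample(candidates)) {
      tips <- tips_under_labels(ftree, nd)
      if (!length(intersect(tips, picked))) {
        effect_clades[[length(effect_clades) + 1L]] <- tips
        picked <- c(picked, tips)
      }
      if (length(effect_clades) >= p$n_effect_clades) break
    }
    effect_otus <- picked
  }
  effects <- setNames(rep(p$effect_size, length(effect_otus)), effect_otus)

  ## -- module membership among frequent OTUs (leading blocks)
  n_mod <- length(p$module_sizes)
  membership <- rep(NA_integer_, n_frequent)
  offset <- 0L
  modules <- list()
  for (m in seq_len(n_mod)) {
    idx <- offset + seq_len(p$module_sizes[m])
    membership[idx] <- m
    modules[[paste0("M", m)]] <- otu_freq[idx]
    offset <- offset + p$module_sizes[m]
  }

  ## -- frequent latent log abundances
  base <- rnorm(n_frequent, 0, p$sad_sd)          # log-normal SAD
  site_ids <- unique(design$site)
  z_site <- matrix(rnorm(length(site_ids) * n_frequent), length(site_ids),
                   dimnames = list(site_ids, NULL))
  g_site <- matrix(rnorm(length(site_ids) * n_mod), length(site_ids))
  w_plot <- matrix(rnorm(n_samp * n_frequent), n_samp)
  h_plot <- matrix(rnorm(n_samp * n_mod), n_samp)

  rho_for <- function(m, trt) p$module_rho[m, ifelse(trt == "fertilized", 2L, 1L)]
  loga <- matrix(0, n_samp, n_frequent,
                 dimnames = list(design$sample_id, otu_freq))
  module_scores <- matrix(0, n_samp, n_mod,
                          dimnames = list(design$sample_id, names(modules)))
  for (s in seq_len(n_samp)) {
    k <- match(design$site[s], site_ids)
    rho <- rep(0, n_frequent)
    fac_site <- rep(0, n_frequent)
    fac_plot <- rep(0, n_frequent)
    for (m in seq_len(n_mod)) {
      mi <- which(membership == m)
      rho[mi] <- rho_for(m, design$treatment[s])
      fac_site[mi] <- g_site[k, m]
      fac_plot[mi] <- h_plot[s, m]
    }
    u <- p$site_sd * (sqrt(rho) * fac_site + sqrt(1 - rho) * z_site[k, ]) +
         p$plot_sd * (sqrt(rho) * fac_plot + sqrt(1 - rho) * w_plot[s, ])
    loga[s, ] <- base + u + ifelse(otu_freq %in% effect_otus,
                                   p$effect_size * fert[s], 0)
    module_scores[s, ] <- p$site_sd * g_site[k, ] + p$plot_sd * h_plot[s, ]
  }
  abund_freq <- exp(loga)

  ## -- rare latent abundances: low occupancy, small Poisson-scale counts
  occ <- runif(n_rare, p$rare_occupancy_range[1], p$rare_occupancy_range[2])
  lambda <- runif(n_rare, p$rare_lambda_range[1], p$rare_lambda_range[2])
  present <- matrix(rbinom(n_samp * n_rare, 1, rep(occ, each = n_samp)),
                    n_samp, n_rare)
  mean_total <- mean(rowSums(abund_freq))
  depth_mean <- exp(p$depth_meanlog + p$depth_sdlog^2 / 2)
  w_rare <- lambda * mean_total / depth_mean
  abund_rare <- sweep(present, 2L, w_rare, `*`)
  colnames(abund_rare) <- otu_rare

  abund <- cbind(abund_freq, abund_rare)[, otu_ids]

  ## -- multinomial counts at log-normal depth
  depth <- pmax(1000L, round(rlnorm(n_samp, p$depth_meanlog, p$depth_sdlog)))
  counts <- t(vapply(seq_len(n_samp), function(s)
    rmultinom(1L, depth[s], abund[s, ])[, 1L], integer(n_otu)))
  dimnames(counts) <- list(design$sample_id, otu_ids)

  ## -- covariates, gene abundances, activities
  rm_coef <- p$ratio_model
  ph_site <- rnorm(length(site_ids), 6.2, 0.6)
  samples <- design[, c("sample_id", "site", "treatment", "plot")]
  samples$pH <- ph_site[match(samples$site, site_ids)] + rnorm(n_samp, 0, 0.1)
  site_ln <- function(mean_log, sd_site, sd_plot, fert_lfc = 0)
    exp(rnorm(length(site_ids), mean_log, sd_site)[match(samples$site, site_ids)] +
        rnorm(n_samp, 0, sd_plot) + fert_lfc * fert)
  samples$org_C <- site_ln(log(2.0), 0.3, 0.1, log(1.15))
  samples$tot_N <- site_ln(log(0.18), 0.3, 0.1, log(1.15))
  samples$C_N <- samples$org_C / samples$tot_N
  samples$NO3 <- site_ln(log(5), 0.4, 0.2, log(1.5))
  samples$NH4 <- site_ln(log(3), 0.4, 0.2, log(1.3))
  samples$P <- site_ln(log(40), 0.4, 0.15)
  samples$Ca <- site_ln(log(2000), 0.35, 0.1, log(1.14))
  samples$gene_16S <- site_ln(log(1e9), 0.4, 0.2)
  samples$nirK <- site_ln(log(0.02), 0.3, 0.2, log(1.3))
  samples$nirS <- site_ln(log(0.015), 0.3, 0.2)
  samples$nosZI <- site_ln(log(0.01), 0.3, 0.2, log(1.25))
  samples$nosZII <- site_ln(log(0.008), 0.3, 0.2, log(1.13))
  nosz_nir <- (samples$nosZI + samples$nosZII) / (samples$nirK + samples$nirS)

  eta <- rm_coef[["intercept"]] +
    rm_coef[["ph"]] * as.numeric(scale(samples$pH)) +
    rm_coef[["module"]] * as.numeric(scale(module_scores[, 1L])) +
    rm_coef[["nosz_nir"]] * as.numeric(scale(log(nosz_nir))) +
    rm_coef[["fert"]] * fert +
    rnorm(n_samp, 0, rm_coef[["noise_sd"]])
  samples$end_product_ratio <- stats::plogis(eta)
  samples$denit_rate <- site_ln(log(50), 0.4, 0.2, log(1.4))
  samples$n2o_rate <- samples$end_product_ratio * samples$denit_rate

  truth <- structure(list(
    modules = modules, module_rho = p$module_rho,
    module_scores = module_scores,
    fert_effect_otus = effects, effect_clades = effect_clades,
    frequent_otus = otu_freq, rare_otus = otu_rare,
    rare_occupancy = setNames(occ, otu_rare),
    ratio_model = rm_coef, ratio_drivers = c("pH", "module_M1", "nosz_nir"),
    site_sd = p$site_sd, plot_sd = p$plot_sd, seed = seed,
    params = p), class = "study_truth")

  structure(list(counts = counts, samples = samples, tree = tree,
                 truth = truth), class = "denit_study")
}

#' @export
#' @method print denit_study
print.denit_study <- function(x, ...) {
  cat("Synthetic fertilization study\n")
  cat(sprintf("  %d samples x %d OTUs (%d frequent, %d rare)\n",
              nrow(x$counts), ncol(x$counts),
              length(x$truth$frequent_otus), length(x$truth$rare_otus)))
  cat(sprintf("  %d sites, treatments: %s\n",
              length(unique(x$samples$site)),
              paste(levels(x$samples$treatment), collapse = ", ")))
  cat(sprintf("  planted modules: %s; %d effect OTUs\n",
              paste(lengths(x$truth$modules), collapse = "/"),
              length(x$truth$fert_effect_otus)))
  invisible(x)
}

#' Simulate a gas accumulation time series
#'
#' Emulates the bottle assay: N2O measured every 0.5 h over 2.5 h. Under
#' the linear model concentration grows as `c0 + rate * t`; under the
#' saturating model as `c0 + A * (1 - exp(-k t))` with the initial slope
#' `A * k` equal to the true rate.
#'
#' @param true_rate initial accumulation rate (amount per hour), >= 0.
#' @param model `"linear"` or `"saturating"`.
#' @param noise_sd Gaussian measurement noise standard deviation.
#' @param seed seed for the noise draw.
#' @param c0 baseline concentration.
#' @param k saturation rate constant (per hour) for the saturating model.
#' @return list of class `gas_timeseries` with `times`, `concentrations`
#'   and `true_rate`.
#' @export
generate_gas_timeseries <- function(true_rate, model = c("linear", "saturating"),
                                    noise_sd = 0, seed = 1L, c0 = 0, k = 1) {
  model <- match.arg(model)
  if (true_rate < 0) stop("parameter error: true_rate must be >= 0")
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")
  times <- seq(0, 2.5, by = 0.5)
  mu <- if (model == "linear") c0 + true_rate * times
        else c0 + (true_rate / k) * (1 - exp(-k * times))
  set.seed(seed)
  conc <- pmax(0, mu + rnorm(length(times), 0, noise_sd))
  structure(list(times = times, concentrations = conc, true_rate = true_rate,
                 model = model, c0 = c0, k = k), class = "gas_timeseries")
}

# Tip indices (integer) under a node of a phylo tree.
tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tips_under, tree = tree))
}

tips_under_labels <- function(tree, node)
  tree$tip.label[tips_under(tree, node)]
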