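`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_stages <- c("simulate", "filter", "transform", "diversity",
                     "balances", "network", "compare", "gbm", "activity")

#' Run the full analysis pipeline from a configuration list
#'
#' Executes the enabled stages in order — simulate, filter (occupancy),
#' transform (zero replacement, CLR, balances), diversity, balances
#' (mixed-model tests), network (per-treatment RMT networks, modules,
#' eigengenes), compare (edge diff and rewiring), gbm (end-product-ratio
#' importance modelling) and activity (percent-change statistics and
#' ANCOVA) — writing each stage's tables and reports under `outdir`, plus
#' a `log.json` with versions and the per-stage seeds derived from the
#' master seed. Given the same configuration and seed the numeric outputs
#' are reproduced exactly.
#'
#' @param config a list. Required: `outdir`. Inputs: either enable the
#'   `simulate` stage (options under `config$simulate` are passed to
#'   [generate_study()]) or provide `counts` (path or matrix), `samples`
#'   (path or data frame) and `tree` (path or `phylo`). Optional entries:
#'   `seed` (master seed, default 1), `stages` (character subset of the
#'   stage names; default: all when simulating, all but simulate
#'   otherwise), and per-stage option lists `filter`, `transform`,
#'   `network`, `gbm`, `activity`.
#' @return invisibly, a list with the in-memory stage results and the
#'   log; side effect: files under `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$outdir)) stop("config error: outdir is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  have_inputs <- !is.null(config$counts)
  stages <- config$stages %||%
    (if (have_inputs) setdiff(pipeline_stages, "simulate") else pipeline_stages)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("config error: unknown stage(s) ", paste(bad, collapse = ", "))
  log <- list(package = as.character(packageVersion("denitnet")),
              r_version = R.version.string, master_seed = seed,
              stages = stages, started = format(Sys.time()),
              stage_seeds = list(), notes = list())
  res <- list()

  counts <- samples <- tree <- NULL
  load_inputs <- function() {
    if (!is.null(config$counts)) {
      counts <<- if (is.character(config$counts))
        read_count_table(config$counts) else config$counts
    }
    if (!is.null(config$samples)) {
      samples <<- if (is.character(config$samples))
        utils::read.csv(config$samples, stringsAsFactors = FALSE)
      else as.data.frame(config$samples)
      if ("treatment" %in% names(samples))
        samples$treatment <<- factor(samples$treatment,
                                     levels = c("unfertilized", "fertilized"))
    }
    if (!is.null(config$tree)) {
      tree <<- if (is.character(config$tree)) read_tree(config$tree)
               else config$tree
    }
  }
  load_inputs()
  need <- function(stage, ...) {
    objs <- list(...)
    miss <- names(objs)[vapply(objs, is.null, TRUE)]
    if (length(miss))
      stop("config error: stage '", stage, "' requires ",
           paste(miss, collapse = ", "))
  }

  if ("simulate" %in% stages) {
    s_seed <- derive_seed(seed, "simulate")
    log$stage_seeds$simulate <- s_seed
    sim_args <- config$simulate %||% list()
    sim_args$seed <- s_seed
    study <- do.call(generate_study, sim_args)
    counts <- study$counts; samples <- study$samples; tree <- study$tree
    res$study <- study
    write_count_table(counts, file.path(outdir, "counts.tsv"))
    utils::write.csv(samples, file.path(outdir, "samples.csv"),
                     row.names = FALSE)
    ape::write.tree(tree, file.path(outdir, "tree.nwk"))
    truth <- study$truth
    jsonlite::write_json(
      list(modules = truth$modules, module_rho = truth$module_rho,
           fert_effect_otus = as.list(truth$fert_effect_otus),
           ratio_model = as.list(truth$ratio_model),
           ratio_drivers = truth$ratio_drivers, seed = truth$seed),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  frequent <- NULL
  if ("filter" %in% stages) {
    need("filter", counts = counts)
    opts <- config$filter %||% list()
    s_seed <- derive_seed(seed, "filter")
    log$stage_seeds$filter <- s_seed
    rare_mat <- rarefy_mean(counts, depth = opts$depth %||% NULL,
                            n_reps = opts$n_reps %||% 100, seed = s_seed)
    rec <- dispersion_records(rare_mat)
    part <- partition_frequent(rec, n_samples = nrow(rare_mat),
                               alpha = opts$alpha %||% 0.05)
    frequent <- part$frequent
    res$dispersion <- rec; res$partition <- part
    write_tsv(rec, file.path(outdir, "dispersion_records.tsv"))
    writeLines(part$frequent, file.path(outdir, "frequent_otus.txt"))
    writeLines(part$rare, file.path(outdir, "rare_otus.txt"))
  }

  clr <- balances <- ftree <- NULL
  if ("transform" %in% stages) {
    need("transform", counts = counts, tree = tree)
    if (is.null(frequent)) frequent <- colnames(counts)
    fc <- counts[, frequent, drop = FALSE]
    comp <- impute_zeros(fc)
    clr <- clr_transform(comp)
    ftree <- ape::keep.tip(tree, frequent)
    balances <- philr_transform(comp, ftree)
    res$clr <- clr; res$balances <- balances; res$ftree <- ftree
    write_tsv(data.frame(sample_id = rownames(clr), clr, check.names = FALSE),
              file.path(outdir, "clr.tsv"))
    write_balances(balances, file.path(outdir, "balances.tsv"))
  }

  diversity <- NULL
  if ("diversity" %in% stages) {
    need("diversity", counts = counts, tree = tree)
    ids <- if (is.null(frequent)) colnames(counts) else frequent
    diversity <- diversity_table(counts[, ids, drop = FALSE],
                                 ape::keep.tip(tree, ids))
    res$diversity <- diversity
    write_tsv(diversity, file.path(outdir, "diversity.tsv"))
    if (!is.null(balances)) {
      s_seed <- derive_seed(seed, "nmds")
      log$stage_seeds$nmds <- s_seed
      nm <- nmds_ordination(dist(balances), seed = s_seed)
      res$nmds <- nm
      write_tsv(data.frame(sample_id = rownames(nm$points), nm$points,
                           stress = nm$stress, check.names = FALSE),
                file.path(outdir, "nmds.tsv"))
    }
  }

  if ("balances" %in% stages) {
    need("balances", balances = balances, samples = samples)
    bt <- test_balances(balances, samples$treatment, samples$site)
    res$balance_tests <- bt
    write_tsv(bt, file.path(outdir, "balance_tests.tsv"))
    sig <- bt$node[bt$q_fdr < 0.01]
    if (length(sig) && "end_product_ratio" %in% names(samples)) {
      assoc <- associate_balances_ratio(balances, samples$end_product_ratio,
                                        nodes = sig)
      res$balance_ratio <- assoc
      write_tsv(assoc, file.path(outdir, "balance_ratio.tsv"))
    }
    s_seed <- derive_seed(seed, "permanova")
    log$stage_seeds$permanova <- s_seed
    pm <- permanova_strata(dist(balances), samples$treatment,
                           strata = samples$site,
                           n_perm = config$n_perm %||% 1000, seed = s_seed)
    res$permanova <- pm
    jsonlite::write_json(pm[c("R2", "F", "p", "n_perm")],
                         file.path(outdir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  graphs <- list(); modules <- list(); eigengenes <- list()
  if ("network" %in% stages) {
    need("network", clr = clr, samples = samples)
    opts <- config$network %||% list()
    for (trt in levels(samples$treatment)) {
      idx <- samples$treatment == trt
      R <- correlation_matrix(clr[samples$sample_id[idx], , drop = FALSE])
      scan <- rmt_threshold(R, t_grid = opts$t_grid %||% seq(0.5, 0.98, 0.01),
                            alpha = opts$alpha %||% 0.05)
      write_tsv(scan$scan, file.path(outdir, paste0("rmt_scan_", trt, ".tsv")))
      if (is.na(scan$r_T)) {
        log$notes[[paste0("network_", trt)]] <- "no RMT transition detected"
        next
      }
      g <- build_graph(R, scan$r_T, n_samples = sum(idx))
      graphs[[trt]] <- g
      write_network(g, file.path(outdir, paste0("network_", trt, ".graphml")),
                    format = "graphml")
      write_network(g, file.path(outdir, paste0("network_", trt, ".tsv")),
                    format = "edge_tsv")
      if (igraph::ecount(g) > 0) {
        top <- topology_metrics(g)
        jsonlite::write_json(unclass(top),
                             file.path(outdir, paste0("topology_", trt, ".json")),
                             auto_unbox = TRUE, digits = NA)
        mod <- detect_modules(g, min_size = opts$min_module_size %||% 5)
        modules[[trt]] <- mod
        write_tsv(data.frame(otu_id = names(mod$membership),
                             module = unname(mod$membership)),
                  file.path(outdir, paste0("modules_", trt, ".tsv")))
        if (length(mod$modules)) {
          eg <- sapply(mod$modules, function(mem)
            module_eigengene(clr, mem)$eigengene)
          rownames(eg) <- rownames(clr)
          eigengenes[[trt]] <- eg
          write_tsv(data.frame(sample_id = rownames(eg), eg,
                               check.names = FALSE),
                    file.path(outdir, paste0("eigengenes_", trt, ".tsv")))
        }
      }
    }
    res$graphs <- graphs; res$modules <- modules; res$eigengenes <- eigengenes
  }

  if ("compare" %in% stages) {
    if (length(graphs) < 2L) {
      log$notes$compare <- "fewer than two networks: comparison skipped"
    } else {
      nd <- diff_edges(graphs[[1L]], graphs[[2L]])
      res$network_diff <- nd
      write_tsv(nd$common, file.path(outdir, "edges_common.tsv"))
      write_tsv(nd$unique_a, file.path(outdir, "edges_unique_a.tsv"))
      write_tsv(nd$unique_b, file.path(outdir, "edges_unique_b.tsv"))
      rw <- tryCatch(rewiring_scores(graphs[[1L]], graphs[[2L]]),
                     error = function(e) {
                       log$notes$rewiring <<- conditionMessage(e)
                       NULL
                     })
      if (!is.null(rw)) {
        res$rewiring <- rw
        write_tsv(rw, file.path(outdir, "rewiring.tsv"))
      }
      if (length(modules) == 2L) {
        cmm <- classify_module_membership(modules[[1L]]$modules,
                                          modules[[2L]]$modules)
        res$module_correspondence <- cmm
        jsonlite::write_json(cmm, file.path(outdir, "module_correspondence.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  if ("gbm" %in% stages) {
    need("gbm", samples = samples)
    opts <- config$gbm %||% list()
    for (trt in levels(samples$treatment)) {
      eg <- eigengenes[[trt]]
      tab <- build_predictor_table(samples, diversity = diversity,
                                   eigengenes = eg, treatment = trt)
      preds <- opts$predictors %||%
        setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                c("end_product_ratio", "plot", "n2o_rate", "denit_rate"))
      s_seed <- derive_seed(seed, paste0("gbm_", trt))
      log$stage_seeds[[paste0("gbm_", trt)]] <- s_seed
      fit <- tune_boosted_model(
        tab, "end_product_ratio", predictors = preds,
        grid = opts$grid %||% expand.grid(n_trees = c(100, 300),
                                          shrinkage = 0.1,
                                          interaction_depth = c(1, 3),
                                          n_minobs = 5),
        folds = opts$folds %||% 10, seed = s_seed)
      imp <- permutation_importance(fit, tab, n_perm = opts$n_perm %||% 500,
                                    seed = s_seed)
      res[[paste0("gbm_", trt)]] <- list(fit = fit, importance = imp)
      write_tsv(imp$importance,
                file.path(outdir, paste0("importance_", trt, ".tsv")))
      for (p in imp$top) {
        al <- ale_curve(fit, tab, p, grid_size = opts$ale_grid %||% 10)
        write_tsv(al$curve,
                  file.path(outdir, sprintf("ale_%s_%s.tsv", trt, p)))
      }
      jsonlite::write_json(
        list(treatment = trt, hyperparameters = fit$params,
             cv_rmse = fit$cv_rmse, seed = s_seed,
             top_predictors = imp$top),
        file.path(outdir, paste0("model_card_", trt, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  if ("activity" %in% stages) {
    need("activity", samples = samples)
    opts <- config$activity %||% list()
    metrics <- opts$metrics %||%
      intersect(c("denit_rate", "n2o_rate", "end_product_ratio",
                  "nirK", "nirS", "nosZI", "nosZII"), names(samples))
    pc <- percent_change_test(samples, metrics)
    res$percent_change <- pc
    write_tsv(pc$changes, file.path(outdir, "site_changes.tsv"))
    write_tsv(pc$tests, file.path(outdir, "change_tests.tsv"))
    if (all(c("end_product_ratio", "pH") %in% names(samples))) {
      an <- ancova_interaction(samples$end_product_ratio, samples$pH,
                               samples$treatment)
      res$ancova_ph <- an
      jsonlite::write_json(an, file.path(outdir, "ancova_ph.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  log$finished <- format(Sys.time())
  jsonlite::write_json(log, file.path(outdir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  res$log <- log
  invisible(res)
}
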