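# Shared fixtures, built once per test run.
.fixtures <- new.env()

# Small two-module study reused across tests (counts, samples, tree, truth).
small_study <- function() {
  if (is.null(.fixtures$small_study)) {
    tp <- study_truth_params(
      module_sizes = c(15, 15),
      module_rho = cbind(unfertilized = c(0.8, 0.8),
                         fertilized = c(0.8, 0.2)),
      depth_meanlog = log(8000))
    .fixtures$small_study <- generate_study(
      n_sites = 8, plots_per_treatment = 3, n_frequent = 80, n_rare = 200,
      truth_params = tp, seed = 5)
  }
  .fixtures$small_study
}

# Random strictly positive composition matrix.
random_composition <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rexp(n * p) + 0.01, n, p,
         dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(p))))
}

# igraph helper: set unit weights and names.
named_graph <- function(g, weight = 1) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- weight
  g
}
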