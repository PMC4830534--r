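# Shared fixture builders. Everything is generated in code; no data files.

# Marker matrix with exact Hardy-Weinberg genotype counts at frequency p:
# n*p^2 A1A1 rows, 2*n*p*(1-p) heterozygotes, n*(1-p)^2 A2A2 rows.
# Counts must come out integer for the chosen n and p.
hwe_column <- function(p, n) {
  n11 <- n * p^2
  n12 <- 2 * n * p * (1 - p)
  n22 <- n * (1 - p)^2
  stopifnot(abs(n11 - round(n11)) < 1e-9, abs(n12 - round(n12)) < 1e-9)
  c(rep(2, round(n11)), rep(1, round(n12)), rep(0, round(n22)))
}

# Small two-trait study used across MME tests; sizes kept tiny so the
# direct (explicit MME) path is cheap.
tiny_study <- function(seed = 11, n_traits = 2, h2 = 0.5, n_loci = 300) {
  simulate_hybrid_study(
    n_lines = 12, n_loci = n_loci, n_per_group = 5, n_traits = n_traits,
    n_add_qtn = 30, n_dom_qtn = 30, h2 = h2, pleiotropy = 0.2, seed = seed
  )
}

# Mid-size study (10 x 10 diallel = 100 hybrids) for simulation-level
# checks that need a less degenerate population.
midi_study <- function(seed = 1, h2 = "historical", n_add_qtn = 60,
                       n_dom_qtn = 60, ...) {
  simulate_hybrid_study(
    n_lines = 20, n_loci = 800, n_per_group = 10, n_traits = 5,
    n_add_qtn = n_add_qtn, n_dom_qtn = n_dom_qtn, h2 = h2, seed = seed, ...
  )
}

# Access the scenario -> per-trait h2 mapping without exporting it.
scenario_h2_for_test <- function(scenario) {
  getFromNamespace("scenario_h2", "gblupad")(scenario, 5L)
}

# Subset a multi-trait variance-component list to one trait.
init_subset_for_test <- function(init, k) {
  lapply(init, function(v) {
    if (is.null(v)) NULL else as.matrix(v)[k, k, drop = FALSE]
  })
}

# Full-size diallel (20 x 20 = 400 hybrids) with a reduced marker panel.
full_study <- function(seed = 1, h2 = "historical", n_loci = 600, ...) {
  simulate_hybrid_study(
    n_lines = 40, n_loci = n_loci, n_per_group = 20, n_traits = 5,
    n_add_qtn = 60, n_dom_qtn = 60, h2 = h2, seed = seed, ...
  )
}
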