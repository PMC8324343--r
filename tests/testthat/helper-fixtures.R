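# Shared fixtures. The reference planted scenario (4 types, 8 TFs, 10
# targets per TF, 200 background genes, fold 4, 200 cells per type) is
# expensive, so it is built lazily and memoised per seed.

.fixture_cache <- new.env(parent = emptyenv())

default_gt <- function(seed = 1L) {
  key <- paste0("gt", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_network(
      n_tfs = 8, n_targets_per_tf = 10, n_types = 4,
      n_background = 200, disjoint = TRUE, seed = seed)
  .fixture_cache[[key]]
}

default_sim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_dataset(default_gt(seed),
                                              simulation_params(seed = seed))
  .fixture_cache[[key]]
}

default_normed <- function(seed = 1L) {
  key <- paste0("normed", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(
      normalize_and_select(filter_genes(default_sim(seed)$counts)))
  .fixture_cache[[key]]
}

default_ras <- function(seed = 1L) {
  key <- paste0("ras", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(
      score_regulon_activity(default_sim(seed)$counts, default_gt(seed),
                             seed = seed))
  .fixture_cache[[key]]
}

# small deterministic count matrix with dimnames for IO and toy tests
toy_counts <- function(nr = 3, nc = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, 3), nr, nc,
              dimnames = list(sprintf("c%d", seq_len(nr)),
                              sprintf("g%d", seq_len(nc))))
  m
}
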