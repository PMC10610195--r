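# Shared in-code fixtures. Everything is generated; nothing binary.

# tiny long-format entries -> perturbation_matrix
pm_from_rows <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(compound = r[[1]], gene = r[[2]], mode = r[[3]],
               score = as.numeric(r[[4]]), stringsAsFactors = FALSE)
  }))
  perturbation_matrix(df)
}

# random long-format entry table on the unit scale (unique keys)
random_entries <- function(n, n_compounds = 6, n_genes = 8, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(compound = sprintf("c%02d", seq_len(n_compounds)),
                      gene = sprintf("G%02d", seq_len(n_genes)),
                      mode = c("KD", "OE"), stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), min(n, nrow(grid))), , drop = FALSE]
  grid$score <- round(runif(nrow(grid), -1, 1), 6)
  rownames(grid) <- NULL
  grid
}

# random bipartite network for oracle tests
random_network <- function(seed, max_compounds = 12, max_targets = 10) {
  set.seed(seed)
  nc <- sample(1:max_compounds, 1)
  nt <- sample(1:max_targets, 1)
  cpds <- sprintf("c%02d", seq_len(nc))
  tgts <- sprintf("T%02d", seq_len(nt))
  all_pairs <- expand.grid(compound = cpds, target = tgts,
                           stringsAsFactors = FALSE)
  keep <- runif(nrow(all_pairs)) < runif(1, 0.1, 0.6)
  if (!any(keep)) keep[sample(nrow(all_pairs), 1)] <- TRUE
  edges <- all_pairs[keep, , drop = FALSE]
  edges$weight <- round(runif(nrow(edges), 0.9, 1), 4)
  bipartite_network(edges)
}

random_ppi <- function(seed, genes = sprintf("T%02d", 1:12)) {
  set.seed(seed)
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.5
  ppi_table(pairs[keep, 1], pairs[keep, 2],
            round(runif(sum(keep)), 4))
}

# small synthetic bundle reused across tests (cheap to build)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(simulation_config(
        n_compounds = 120, n_genes = 390, n_suppressors = 12,
        n_stimulators = 8, n_shams = 40, n_informative_drivers = 6,
        n_coexpressed_drivers = 5, n_hub_proteins = 4,
        n_pathways = 8, pathway_size = 25, n_planted_pathways = 4,
        seed = 11))
    }
    cache
  }
})
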