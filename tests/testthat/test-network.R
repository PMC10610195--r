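# Independent recounts straight off the raw edge list.
brute_degrees <- function(net) {
  list(compound = vapply(net$compounds,
                         function(n) sum(net$edges$compound == n), 0L),
       target = vapply(net$targets,
                       function(n) sum(net$edges$target == n), 0L))
}

test_that("transcriptional network keeps exactly the driver edges", {
  drivers <- driver_catalog(c("KRAS", "MYC"), c("oncogene", "oncogene"))
  net <- build_transcriptional_network(
    list(cpdA = c("KRAS", "FOO"), cpdB = c("BAR")), drivers)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$target, "KRAS")
  expect_equal(net$compounds, "cpdA")

  expect_equal(nrow(build_transcriptional_network(list(), drivers)$edges), 0)
  expect_error(build_transcriptional_network(list(), driver_catalog(
    character(), character())), class = "pertnet_configuration_error")

  b <- small_bundle()
  prof <- coexpressed_targets(b$matrix, identify_modulators(b$matrix))
  net <- build_transcriptional_network(prof, b$drivers)
  oracle <- list()
  for (cpd in names(prof)) {
    for (g in prof[[cpd]]) {
      if (g %in% b$drivers$gene) oracle[[length(oracle) + 1]] <- c(cpd, g)
    }
  }
  expect_equal(nrow(net$edges), length(oracle))
  key <- paste(net$edges$compound, net$edges$target)
  expect_setequal(key, vapply(oracle, paste, "", collapse = " "))
})

test_that("translational network applies the modulator and driver filters", {
  drivers <- driver_catalog("EGFR", "oncogene")
  ba <- bioactivity_table(c("m1", "x1", "m1"), c("EGFR", "EGFR", "OTHER"))
  net <- build_translational_network(ba, "m1", drivers)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$compound, "m1")

  b <- small_bundle()
  calls <- identify_modulators(b$matrix)
  net <- build_translational_network(b$bioactivity, calls, b$drivers)
  keep <- b$bioactivity$compound %in% calls$compound &
    b$bioactivity$protein %in% b$drivers$gene
  expect_equal(nrow(net$edges), sum(keep))
  expect_true(all(net$compounds %in% calls$compound))
})

test_that("degrees, ranks and summaries match brute-force recomputation", {
  one <- bipartite_network(data.frame(compound = "c1", target = "T1"))
  dt <- degree_table(one)
  expect_equal(dt$degree, c(1L, 1L))

  for (seed in 1:25) {
    net <- random_network(seed)
    dt <- degree_table(net)
    bd <- brute_degrees(net)
    for (cls in c("compound", "target")) {
      sub <- dt[dt$class == cls, ]
      expect_equal(setNames(sub$degree, sub$node)[names(bd[[cls]])],
                   bd[[cls]])
      # deterministic ranking: degree desc, then lexicographic
      expect_equal(sub$node,
                   names(bd[[cls]])[order(-bd[[cls]], names(bd[[cls]]))])
    }
    # handshake
    expect_equal(sum(dt$degree[dt$class == "compound"]), nrow(net$edges))
    expect_equal(sum(dt$degree[dt$class == "target"]), nrow(net$edges))
    s <- network_summary(net)
    expect_equal(s$mean_target_degree, nrow(net$edges) / length(net$targets))
    expect_equal(s$mean_compound_degree,
                 nrow(net$edges) / length(net$compounds))
  }
  empty <- bipartite_network(NULL)
  expect_equal(network_summary(empty),
               list(n_nodes = 0L, n_compounds = 0L, n_targets = 0L,
                    n_edges = 0L, mean_target_degree = 0,
                    mean_compound_degree = 0))
})

test_that("top-k hubs saturate, break ties lexicographically and find planted hubs", {
  net <- bipartite_network(data.frame(
    compound = c("c1", "c2", "c1", "c2"),
    target = c("TB", "TB", "TA", "TA")))
  dt <- degree_table(net)
  expect_equal(top_k_hubs(dt, "target", 1), "TA")   # tie -> lexicographic
  expect_equal(top_k_hubs(dt, "target", 10), c("TA", "TB"))

  b <- small_bundle()
  pnet <- build_translational_network(b$bioactivity,
                                      identify_modulators(b$matrix),
                                      b$drivers)
  top <- top_k_hubs(degree_table(pnet), "target",
                    length(b$truth$hub_proteins))
  expect_setequal(top, b$truth$hub_proteins)
})

test_that("core subnetwork uses a strict degree cutoff and shrinks monotonically", {
  edges <- expand.grid(compound = sprintf("c%02d", 1:5),
                       target = "THUB", stringsAsFactors = FALSE)
  edges <- rbind(edges, data.frame(compound = "c01", target = "TLOW"))
  net <- bipartite_network(edges)
  expect_equal(core_subnetwork(net, 4)$targets, "THUB")
  expect_equal(core_subnetwork(net, 5)$targets, character())  # strict >
  expect_setequal(core_subnetwork(net, 0)$targets, c("THUB", "TLOW"))

  for (seed in 1:5) {
    net <- random_network(seed)
    prev <- core_subnetwork(net, 0)$targets
    for (cut in 1:4) {
      cur <- core_subnetwork(net, cut)$targets
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("PPI core induction keeps strictly supra-threshold edges among targets", {
  ppi <- ppi_table(c("A", "A", "B"), c("B", "C", "C"), c(0.7, 0.9, 0.95))
  g <- induce_ppi_core(c("A", "B", "C"), ppi, 0.7)
  expect_equal(nrow(g$edges), 2)          # the 0.7 edge is dropped
  expect_false(any(g$edges$confidence <= 0.7))

  g2 <- induce_ppi_core(c("X", "Y"), ppi, 0.7)
  expect_equal(g2$nodes, c("X", "Y"))
  expect_equal(nrow(g2$edges), 0)

  for (seed in 1:20) {
    ppi <- random_ppi(seed)
    targets <- sprintf("T%02d", sample(12, 6))
    cut <- runif(1)
    g <- induce_ppi_core(targets, ppi, cut)
    oracle <- ppi[ppi$a %in% targets & ppi$b %in% targets &
                    ppi$confidence > cut, ]
    expect_equal(nrow(g$edges), nrow(oracle))
    expect_setequal(paste(g$edges$a, g$edges$b),
                    paste(oracle$a, oracle$b))
  }
})

test_that("compounds outside the modulator list never enter either layer", {
  b <- small_bundle()
  calls <- identify_modulators(b$matrix)
  prof <- coexpressed_targets(b$matrix, calls)
  tnet <- build_transcriptional_network(prof, b$drivers)
  pnet <- build_translational_network(b$bioactivity, calls, b$drivers)
  non_mod <- setdiff(b$matrix$compounds, calls$compound)
  expect_length(intersect(tnet$compounds, non_mod), 0)
  expect_length(intersect(pnet$compounds, non_mod), 0)
})
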