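test_that("identical configs give byte-identical bundles", {
  cfg <- simulation_config(n_compounds = 60, n_genes = 130,
                           driver_fraction = 0.1, n_suppressors = 6,
                           n_stimulators = 4, n_shams = 20,
                           n_informative_drivers = 3,
                           n_coexpressed_drivers = 3, n_hub_proteins = 2,
                           n_pathways = 5, pathway_size = 15,
                           n_planted_pathways = 2, seed = 99)
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  expect_identical(b1$matrix, b2$matrix)
  expect_identical(b1$bioactivity, b2$bioactivity)
  expect_identical(b1$ppi, b2$ppi)
  expect_identical(b1$truth, b2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_bundle(b1, d1)
  p2 <- write_bundle(b2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("zero planted modulators means zero supra-threshold target scores", {
  cfg <- simulation_config(n_compounds = 50, n_genes = 130,
                           driver_fraction = 0.1, n_suppressors = 0,
                           n_stimulators = 0, n_shams = 20,
                           n_informative_drivers = 3,
                           n_coexpressed_drivers = 3, n_hub_proteins = 2,
                           n_pathways = 4, pathway_size = 10,
                           n_planted_pathways = 2, seed = 5)
  b <- generate_dataset(cfg)
  sc <- cbind(b$matrix$kd[, "PLAUR"], b$matrix$oe[, "PLAUR"])
  expect_true(all(sc <= 0.9, na.rm = TRUE))
  expect_equal(nrow(identify_modulators(b$matrix)), 0)
})

test_that("planted labels are recovered exactly across random configs", {
  set.seed(2024)
  for (rep in 1:20) {
    ns <- sample(0:10, 1)
    nt <- sample(0:10, 1)
    cfg <- simulation_config(
      n_compounds = 60, n_genes = 260, driver_fraction = 0.1,
      n_suppressors = ns, n_stimulators = nt, n_shams = sample(5:20, 1),
      n_informative_drivers = sample(2:6, 1),
      n_coexpressed_drivers = sample(2:6, 1), n_hub_proteins = 2,
      n_pathways = 4, pathway_size = 10, n_planted_pathways = 2,
      seed = 1000 + rep)
    b <- generate_dataset(cfg)
    calls <- identify_modulators(b$matrix)
    lbl <- b$truth$labels
    expect_setequal(calls$compound[calls$direction == "suppressor"],
                    names(lbl)[lbl == "suppressor"])
    expect_setequal(calls$compound[calls$direction == "stimulator"],
                    names(lbl)[lbl == "stimulator"])
    expect_setequal(select_sham_compounds(b$matrix),
                    names(lbl)[lbl == "sham"])
  }
})

test_that("informative-driver mean shift lands within 3 standard errors", {
  cfg <- simulation_config(n_compounds = 500, n_genes = 390,
                           driver_fraction = 0.1, n_suppressors = 110,
                           n_stimulators = 90, n_shams = 200,
                           n_informative_drivers = 10,
                           n_coexpressed_drivers = 5, n_hub_proteins = 4,
                           n_pathways = 4, pathway_size = 10,
                           n_planted_pathways = 2, seed = 31)
  b <- generate_dataset(cfg)
  lbl <- b$truth$labels
  mod <- names(lbl)[lbl %in% c("suppressor", "stimulator")]
  sham <- names(lbl)[lbl == "sham"]
  inf <- b$truth$informative_drivers
  x_mod <- b$matrix$kd[mod, inf]
  x_sham <- b$matrix$kd[sham, inf]
  diff_mean <- mean(x_mod) - mean(x_sham)
  se <- sqrt(var(as.vector(x_mod)) / length(x_mod) +
               var(as.vector(x_sham)) / length(x_sham))
  expect_lt(abs(diff_mean - cfg$informative_shift), 3 * se)
})

test_that("emitted driver fraction matches the config within rounding", {
  b <- small_bundle()
  expect_equal(nrow(b$drivers),
               round(b$config$n_genes * b$config$driver_fraction))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_compounds = 10, n_suppressors = 20,
                                 n_stimulators = 0, n_shams = 0),
               class = "pertnet_configuration_error")
  expect_error(simulation_config(modulator_score_range = c(0.8, 0.95)),
               class = "pertnet_configuration_error")
  expect_error(simulation_config(sham_band = c(-0.95, 0.2)),
               class = "pertnet_configuration_error")
})

test_that("reference tables load with the documented shapes", {
  ref <- load_reference_tables()
  expect_equal(nrow(ref$pathway_counts), 10)
  expect_true(all(ref$pathway_counts$denominator == 254))
  expect_equal(nrow(ref$real_modulators), 9)
  expect_equal(ref$real_modulators$direction[
    ref$real_modulators$compound == "Spironolactone"], "suppression")
  expect_equal(sum(ref$real_modulators$direction == "suppression"), 4)
  expect_length(ref$hallmarks, 4)
  expect_equal(pm_score(ref$pair_examples$matrix, "haloperidol", "PLAUR",
                        "OE"), 0.9407)
  expect_equal(pm_score(ref$pair_examples$matrix, "haloperidol", "SMAD4",
                        "KD"), 0.9859)
  expect_length(ref$memberships, 10)
  expect_length(ref$top10_drivers, 10)
})
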