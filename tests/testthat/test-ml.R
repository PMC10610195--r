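# Shared planted-signal dataset: 160 compounds, 20 driver features of
# which 10 carry the class shift.
ml_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(simulation_config(
        n_compounds = 160, n_genes = 260, driver_fraction = 0.1,
        n_suppressors = 40, n_stimulators = 30, n_shams = 70,
        n_informative_drivers = 10, n_coexpressed_drivers = 0,
        n_hub_proteins = 0, n_pathways = 4, pathway_size = 10,
        n_planted_pathways = 2, seed = 17))
    }
    cache
  }
})

ml_dataset <- function(mode = "KD_only", k_features = 20) {
  b <- ml_bundle()
  build_dataset(b$matrix, identify_modulators(b$matrix),
                select_sham_compounds(b$matrix),
                b$drivers$gene[seq_len(k_features)], mode)
}

test_that("dataset assembly mirrors direct matrix lookups and labels by membership", {
  b <- ml_bundle()
  calls <- identify_modulators(b$matrix)
  shams <- select_sham_compounds(b$matrix)
  ds <- build_dataset(b$matrix, calls, shams, b$drivers$gene[1:12],
                      "KD_only")
  expect_equal(nrow(ds$x), nrow(calls) + length(shams))
  expect_equal(sum(ds$y == "modulator"), nrow(calls))
  for (cpd in c(calls$compound[1:3], shams[1:3])) {
    for (g in colnames(ds$x)[1:5]) {
      expect_equal(ds$x[cpd, g], unname(pm_score(b$matrix, cpd, g, "KD")))
    }
  }
  expect_error(build_dataset(b$matrix, calls, calls$compound[1],
                             b$drivers$gene[1:3]),
               class = "pertnet_validation_error")
  expect_error(build_dataset(b$matrix, calls, character(),
                             b$drivers$gene[1:3]),
               class = "pertnet_validation_error")
})

test_that("unmeasured feature values impute to zero and are flagged", {
  pm <- pm_from_rows(list("m1", "PLAUR", "KD", 0.95),
                     list("m1", "D1", "KD", 0.5),
                     list("s1", "PLAUR", "KD", 0.0),
                     list("s1", "D1", "KD", 0.1))
  ds <- build_dataset(pm, "m1", "s1", c("D1", "D2"))
  expect_equal(unname(ds$x["m1", "D2"]), 0)
  expect_true(ds$missing["m1", "D2"])
  expect_false(ds$missing["m1", "D1"])
})

test_that("a label-identical feature ranks first; k is capped with a warning", {
  ds <- ml_dataset()
  ds$x <- cbind(ds$x, ORACLE = as.numeric(ds$y == "modulator"))
  sel <- select_features(ds, k = 1)
  expect_equal(as.character(sel), "ORACLE")
  expect_warning(all_feats <- select_features(ds, k = 1000), "exceeds")
  expect_length(all_feats, ncol(ds$x))
})

test_that("feature selection recovers the planted informative drivers", {
  b <- ml_bundle()
  ds <- build_dataset(b$matrix, identify_modulators(b$matrix),
                      select_sham_compounds(b$matrix), b$drivers$gene,
                      "KD_only")
  sel <- select_features(ds, k = 10)
  expect_gte(length(intersect(sel, b$truth$informative_drivers)), 8)
})

test_that("feature selection is invariant to row order", {
  ds <- ml_dataset()
  perm <- sample(nrow(ds$x))
  ds2 <- ds
  ds2$x <- ds$x[perm, ]
  ds2$y <- ds$y[perm]
  expect_equal(as.character(select_features(ds, k = 8)),
               as.character(select_features(ds2, k = 8)))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    y <- factor(sample(c("modulator", "sham"), 60, replace = TRUE),
                levels = c("modulator", "sham"))
    s <- rnorm(60) + as.numeric(y == "modulator")
    ours <- pertnet:::auc_rank(s, y)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c("sham", "modulator"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("a perfectly separable dataset gives AUC 1 for all seven algorithms", {
  set.seed(12)
  n <- 60
  y <- rep(c("modulator", "sham"), each = n / 2)
  x <- cbind(F1 = ifelse(y == "modulator", 0.8, -0.8) + rnorm(n, sd = 0.01),
             F2 = rnorm(n, sd = 0.1))
  rownames(x) <- sprintf("c%02d", seq_len(n))
  ds <- structure(list(x = x, y = factor(y, c("modulator", "sham")),
                       missing = x * 0 > 1,
                       provenance = list(mode_reduction = "max")),
                  class = "screening_dataset")
  rep <- evaluate_models(ds, folds = 5, seed = 2)
  expect_equal(nrow(rep), 7)
  expect_true(all(rep$cv_auc == 1))
  expect_true(all(rep$holdout_auc == 1))
})

test_that("the report is deterministic for a fixed dataset and seed", {
  ds <- ml_dataset()
  r1 <- evaluate_models(ds, algorithms = c("logistic_regression", "svm",
                                           "neural_network", "knn"),
                        folds = 5, seed = 7)
  r2 <- evaluate_models(ds, algorithms = c("logistic_regression", "svm",
                                           "neural_network", "knn"),
                        folds = 5, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(dim(as.data.frame(r1)), c(4, 9))
})

test_that("protocol guards fire: bad folds and single-class folds", {
  ds <- ml_dataset()
  expect_error(evaluate_models(ds, folds = 1),
               class = "pertnet_protocol_error")
  tiny <- ds
  keep <- c(which(ds$y == "modulator")[1:2], which(ds$y == "sham")[1:2])
  tiny$x <- ds$x[keep, ]
  tiny$y <- droplevels(ds$y[keep])
  tiny$missing <- ds$missing[keep, ]
  expect_error(evaluate_models(tiny, folds = 10),
               class = "pertnet_protocol_error")
})

test_that("external classification is deterministic and memorizes separable training data", {
  b <- ml_bundle()
  calls <- identify_modulators(b$matrix)
  shams <- select_sham_compounds(b$matrix)
  ds <- build_dataset(b$matrix, calls, shams, b$drivers$gene, "KD_only")
  model <- train_screening_model(ds, algorithm = "random_forest", seed = 3)
  res <- classify_external(model, b$matrix, rownames(ds$x))
  expect_equal(res$call, as.character(ds$y))
  res2 <- classify_external(model, b$matrix, rownames(ds$x))
  expect_identical(res, res2)
  expect_equal(nrow(classify_external(model, b$matrix, character())), 0)
  expect_error(train_screening_model(ds, features = "NOT_A_GENE"),
               class = "pertnet_validation_error")
})

test_that("label permutation drives the mean CV AUC of every algorithm to chance", {
  ds <- ml_dataset(k_features = 12)
  null_auc <- permutation_null_auc(ds, n_perm = 100, folds = 5, seed = 19)
  expect_length(null_auc, 7)
  for (alg in names(null_auc)) {
    expect_gte(null_auc[[alg]], 0.4)
    expect_lte(null_auc[[alg]], 0.6)
  }
})
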