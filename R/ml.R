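# Machine-learning screening platform. Driver-gene perturbation scores are
# the features, modulator-vs-sham status the label. Protocol: a stratified
# 70/30 train/test split, stratified k-fold cross-validation on the
# training portion (pooled out-of-fold scores give the CV metrics), and a
# separate confirmation score on the held-out 30%. Seven classifier
# families are benchmarked with fixed library-default hyperparameters.

ML_ALGORITHMS <- c("logistic_regression", "svm", "random_forest",
                   "naive_bayes", "neural_network", "gradient_boosting",
                   "knn")

#' Build the labeled screening dataset
#'
#' One row per modulator/sham compound, one column per feature gene. The
#' feature value is the mode-reduced perturbation score of the gene:
#' `"max"` takes the larger signed score over the measured modes,
#' `"KD_only"`/`"OE_only"` use a single mode. Unmeasured values are imputed
#' to 0 and flagged.
#'
#' @param pm a [perturbation_matrix()].
#' @param modulators `modulator_calls` table or character vector (positive
#'   class).
#' @param shams character vector of sham compounds (negative class).
#' @param feature_genes non-empty character vector of feature genes.
#' @param mode_reduction `"max"`, `"KD_only"` or `"OE_only"`.
#' @return Object of class `screening_dataset`: list with numeric matrix
#'   `x` (compounds x genes), factor `y` (levels `modulator`, `sham`),
#'   logical matrix `missing`, and `provenance` (the reduction used).
#' @export
build_dataset <- function(pm, modulators, shams, feature_genes,
                          mode_reduction = c("max", "KD_only", "OE_only")) {
  mode_reduction <- match.arg(mode_reduction)
  pos <- if (is.data.frame(modulators)) modulators$compound else modulators
  if (!length(feature_genes)) {
    stop_pertnet("feature_genes must be non-empty",
                 class = "pertnet_validation_error")
  }
  if (length(intersect(pos, shams))) {
    stop_pertnet("compound '%s' labeled both modulator and sham",
                 intersect(pos, shams)[1L],
                 class = "pertnet_validation_error")
  }
  if (!length(pos) || !length(shams)) {
    stop_pertnet("both classes must be non-empty",
                 class = "pertnet_validation_error")
  }
  feature_genes <- toupper(feature_genes)
  unknown <- setdiff(c(pos, shams), pm$compounds)
  if (length(unknown)) {
    stop_pertnet("compound '%s' not present in the matrix", unknown[1L],
                 class = "pertnet_lookup_error")
  }
  cpds <- c(pos, shams)
  gidx <- match(feature_genes, pm$genes)
  grab <- function(m) {
    out <- matrix(NA_real_, length(cpds), length(feature_genes),
                  dimnames = list(cpds, feature_genes))
    ok <- !is.na(gidx)
    out[, ok] <- m[cpds, gidx[ok], drop = FALSE]
    out
  }
  kd <- grab(pm$kd)
  oe <- grab(pm$oe)
  x <- switch(mode_reduction,
              KD_only = kd,
              OE_only = oe,
              max = {
                m <- pmax(kd, oe, na.rm = TRUE)
                m[is.na(kd) & is.na(oe)] <- NA_real_
                m
              })
  miss <- is.na(x)
  x[miss] <- 0
  y <- factor(rep(c("modulator", "sham"), c(length(pos), length(shams))),
              levels = c("modulator", "sham"))
  structure(list(x = x, y = y, missing = miss,
                 provenance = list(mode_reduction = mode_reduction)),
            class = "screening_dataset")
}

#' @export
print.screening_dataset <- function(x, ...) {
  cat(sprintf(
    "screening_dataset: %d compounds (%d modulators, %d shams) x %d features (%d imputed values)\n",
    nrow(x$x), sum(x$y == "modulator"), sum(x$y == "sham"), ncol(x$x),
    sum(x$missing)))
  invisible(x)
}

#' Relevance-based feature selection
#'
#' Ranks features by the absolute point-biserial correlation between the
#' feature and the binary class label, a deterministic relevance statistic
#' in the CFS family; ties break lexicographically by gene symbol.
#' Constant features score 0.
#'
#' @param dataset a [build_dataset()] result.
#' @param k keep the top `k` features (warned and capped at the feature
#'   count), or
#' @param threshold keep all features with relevance strictly above this
#'   value (used when `k` is `NULL`).
#' @return Character vector of selected feature genes, ranked; relevance
#'   scores in attribute `relevance`.
#' @export
select_features <- function(dataset, k = NULL, threshold = NULL) {
  y01 <- as.numeric(dataset$y == "modulator")
  rel <- abs(suppressWarnings(cor(dataset$x, y01)))[, 1L]
  rel[is.na(rel)] <- 0
  ord <- order(-rel, names(rel))
  ranked <- names(rel)[ord]
  if (!is.null(k)) {
    if (k > length(ranked)) {
      warning(sprintf("k = %d exceeds the %d available features; returning all",
                      k, length(ranked)))
      k <- length(ranked)
    }
    sel <- ranked[seq_len(k)]
  } else if (!is.null(threshold)) {
    sel <- ranked[rel[ord] > threshold]
  } else {
    stop_pertnet("supply k or threshold", class = "pertnet_usage_error")
  }
  structure(sel, relevance = rel[sel])
}

# Rank (Mann-Whitney) AUC with mid-ranked ties; equivalent to the
# trapezoidal area under the empirical ROC curve.
auc_rank <- function(scores, labels) {
  pos <- labels == "modulator"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(scores, labels, cut = 0.5) {
  pred_pos <- scores >= cut
  is_pos <- labels == "modulator"
  tp <- sum(pred_pos & is_pos)
  fn <- sum(!pred_pos & is_pos)
  fp <- sum(pred_pos & !is_pos)
  tn <- sum(!pred_pos & !is_pos)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_)
}

# Fit one classifier and return P(modulator)-like scores for newdata.
# Library defaults, fixed here for reproducibility; every stochastic
# learner is re-seeded from the protocol seed.
fit_score <- function(algorithm, xtr, ytr, xte, seed) {
  set.seed(seed)
  y01 <- as.numeric(ytr == "modulator")
  switch(algorithm,
    logistic_regression = {
      df <- data.frame(xtr, check.names = FALSE)
      fit <- suppressWarnings(glm(y01 ~ ., data = cbind(y01 = y01, df),
                                  family = binomial()))
      suppressWarnings(as.numeric(
        predict(fit, data.frame(xte, check.names = FALSE),
                type = "response")))
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", probability = TRUE,
                        scale = FALSE)
      pr <- attr(predict(fit, xte, probability = TRUE), "probabilities")
      as.numeric(pr[, "modulator"])
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
      as.numeric(predict(fit, xte, type = "prob")[, "modulator"])
    },
    naive_bayes = {
      keep <- apply(xtr, 2, function(v) {
        all(tapply(v, ytr, sd, na.rm = TRUE) > 1e-9)
      })
      if (!any(keep)) keep[1L] <- TRUE
      fit <- e1071::naiveBayes(xtr[, keep, drop = FALSE], ytr)
      as.numeric(predict(fit, xte[, keep, drop = FALSE],
                         type = "raw")[, "modulator"])
    },
    neural_network = {
      fit <- nnet::nnet(xtr, y01, size = 5, decay = 0.1, maxit = 200,
                        trace = FALSE, MaxNWts = 50000)
      as.numeric(predict(fit, xte))
    },
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(xtr, label = y01, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      tree_method = "exact"),
        dtr, nrounds = 50, verbose = 0)
      as.numeric(predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1)))
    },
    knn = {
      pred <- class::knn(xtr, xte, ytr, k = 5, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "modulator", p, 1 - p)
    },
    stop_pertnet("unknown algorithm '%s'", algorithm,
                 class = "pertnet_usage_error"))
}

# Stratified index split: returns indices of the training portion.
stratified_split <- function(y, train_fraction, seed) {
  set.seed(seed)
  idx <- unlist(lapply(levels(y), function(lv) {
    i <- which(y == lv)
    sample(i, floor(length(i) * train_fraction))
  }))
  sort(idx)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (lv in levels(y)) {
    i <- which(y == lv)
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  f
}

#' Benchmark classifier families on a screening dataset
#'
#' Stratified 70/30 split; stratified k-fold cross-validation on the
#' training portion with pooled out-of-fold scores yielding the CV metrics;
#' the same classifier retrained on the full training portion scores the
#' 30% holdout. AUC uses the rank (trapezoidal) method with mid-ranked
#' ties; accuracy, sensitivity (TP/(TP+FN)) and precision (TP/(TP+FP)) are
#' taken at the 0.5 score cut with `modulator` the positive class.
#'
#' @param dataset a [build_dataset()] result.
#' @param features feature genes to use (default: all).
#' @param algorithms subset of `logistic_regression`, `svm`,
#'   `random_forest`, `naive_bayes`, `neural_network`, `gradient_boosting`,
#'   `knn`.
#' @param folds CV fold count (`>= 2`).
#' @param train_fraction training proportion for the outer split.
#' @param seed integer governing every random choice (split, folds,
#'   learner randomness).
#' @return Object of class `model_report`: data frame with one row per
#'   algorithm (`cv_auc`, `cv_accuracy`, `cv_sensitivity`, `cv_precision`,
#'   `holdout_auc`, `holdout_accuracy`, `holdout_sensitivity`,
#'   `holdout_precision`) and a `protocol` attribute.
#' @export
evaluate_models <- function(dataset, features = colnames(dataset$x),
                            algorithms = ML_ALGORITHMS, folds = 10,
                            train_fraction = 0.7, seed = 42) {
  algorithms <- match.arg(algorithms, ML_ALGORITHMS, several.ok = TRUE)
  if (folds < 2) {
    stop_pertnet("folds must be >= 2", class = "pertnet_protocol_error")
  }
  x <- dataset$x[, features, drop = FALSE]
  y <- dataset$y
  if (min(table(y)) < 2) {
    stop_pertnet("need >= 2 compounds per class",
                 class = "pertnet_validation_error")
  }
  tr <- stratified_split(y, train_fraction, derive_seed(seed, 11))
  xtr <- x[tr, , drop = FALSE]
  ytr <- y[tr]
  xte <- x[-tr, , drop = FALSE]
  yte <- y[-tr]
  fold_id <- stratified_folds(ytr, folds, derive_seed(seed, 23))
  for (f in seq_len(folds)) {
    if (nlevels(droplevels(ytr[fold_id != f])) < 2) {
      stop_pertnet("training fold %d is single-class after stratification", f,
                   class = "pertnet_protocol_error")
    }
  }
  rows <- lapply(algorithms, function(alg) {
    aseed <- derive_seed(seed, 100 + match(alg, ML_ALGORITHMS))
    cv_scores <- numeric(length(ytr))
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      cv_scores[hold] <- fit_score(alg, xtr[!hold, , drop = FALSE],
                                   ytr[!hold], xtr[hold, , drop = FALSE],
                                   derive_seed(aseed, f))
    }
    cvm <- confusion_metrics(cv_scores, ytr)
    ho_scores <- fit_score(alg, xtr, ytr, xte, derive_seed(aseed, 999))
    hom <- confusion_metrics(ho_scores, yte)
    data.frame(algorithm = alg,
               cv_auc = auc_rank(cv_scores, ytr),
               cv_accuracy = cvm$accuracy,
               cv_sensitivity = cvm$sensitivity,
               cv_precision = cvm$precision,
               holdout_auc = auc_rank(ho_scores, yte),
               holdout_accuracy = hom$accuracy,
               holdout_sensitivity = hom$sensitivity,
               holdout_precision = hom$precision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("model_report", "data.frame"),
            protocol = list(folds = folds, train_fraction = train_fraction,
                            seed = seed, n_features = ncol(x),
                            n_train = length(ytr), n_test = length(yte)))
}

#' @export
print.model_report <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf(
    "model_report: %d algorithms, %d features, %d-fold CV on %d train / %d holdout (seed %d)\n",
    nrow(x), p$n_features, p$folds, p$n_train, p$n_test, p$seed))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 3)
  print.data.frame(df)
  invisible(x)
}

#' Train a single screening model for external classification
#'
#' @param dataset a [build_dataset()] result.
#' @param features feature genes.
#' @param algorithm one algorithm name.
#' @param seed integer seed.
#' @return Object of class `screening_model` (closure over the training
#'   data; scoring re-fits deterministically from the stored seed).
#' @export
train_screening_model <- function(dataset, features = colnames(dataset$x),
                                  algorithm = "svm", seed = 42) {
  algorithm <- match.arg(algorithm, ML_ALGORITHMS)
  unknown <- setdiff(features, colnames(dataset$x))
  if (length(unknown)) {
    stop_pertnet("feature gene '%s' absent from the dataset", unknown[1L],
                 class = "pertnet_validation_error")
  }
  structure(list(xtr = dataset$x[, features, drop = FALSE],
                 ytr = dataset$y, features = features,
                 algorithm = algorithm, seed = seed,
                 mode_reduction = dataset$provenance$mode_reduction),
            class = "screening_model")
}

#' Classify external compounds with a trained screening model
#'
#' Feature rows are extracted from the matrix under the model's mode
#' reduction (unmeasured values imputed to 0); calls use the 0.5 score cut.
#'
#' @param model a [train_screening_model()] result.
#' @param pm a [perturbation_matrix()].
#' @param compounds compounds to classify (present in `pm`).
#' @return Data frame `compound`, `score`, `call`
#'   (`modulator`/`sham`).
#' @export
classify_external <- function(model, pm, compounds) {
  if (!length(compounds)) {
    return(data.frame(compound = character(), score = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  }
  unknown_gene <- setdiff(model$features, pm$genes)
  if (length(unknown_gene)) {
    stop_pertnet("feature gene '%s' unknown to the matrix", unknown_gene[1L],
                 class = "pertnet_validation_error")
  }
  unknown <- setdiff(compounds, pm$compounds)
  if (length(unknown)) {
    stop_pertnet("compound '%s' not present in the matrix", unknown[1L],
                 class = "pertnet_lookup_error")
  }
  kd <- pm$kd[compounds, model$features, drop = FALSE]
  oe <- pm$oe[compounds, model$features, drop = FALSE]
  x <- switch(model$mode_reduction,
              KD_only = kd, OE_only = oe,
              max = {
                m <- pmax(kd, oe, na.rm = TRUE)
                m[is.na(kd) & is.na(oe)] <- NA_real_
                m
              })
  x[is.na(x)] <- 0
  scores <- fit_score(model$algorithm, model$xtr, model$ytr, x,
                      derive_seed(model$seed, 7))
  data.frame(compound = compounds, score = scores,
             call = ifelse(scores >= 0.5, "modulator", "sham"),
             stringsAsFactors = FALSE)
}

#' Label-permutation null for the CV protocol
#'
#' Repeatedly permutes the class labels and recomputes the CV AUC,
#' algorithm by algorithm, as a leakage guard: the mean permuted AUC should
#' sit near 0.5.
#'
#' @param dataset a [build_dataset()] result.
#' @param features feature genes.
#' @param algorithms algorithms to control.
#' @param n_perm permutation count.
#' @param folds,train_fraction,seed protocol parameters.
#' @return Named numeric vector: mean permuted CV AUC per algorithm.
#' @export
permutation_null_auc <- function(dataset, features = colnames(dataset$x),
                                 algorithms = ML_ALGORITHMS, n_perm = 100,
                                 folds = 10, train_fraction = 0.7,
                                 seed = 42) {
  aucs <- matrix(NA_real_, n_perm, length(algorithms),
                 dimnames = list(NULL, algorithms))
  for (p in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 5000 + p))
    perm <- dataset
    perm$y <- dataset$y[sample(length(dataset$y))]
    fit_rep <- evaluate_models(perm, features, algorithms, folds,
                               train_fraction,
                               seed = derive_seed(seed, 6000 + p))
    aucs[p, ] <- fit_rep$cv_auc
  }
  colMeans(aucs)
}
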