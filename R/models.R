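#' Model variants
#'
#' The study design compares four Random-Forest variants that differ only
#' in which descriptor block carries real information:
#' * `rf_all` - both descriptor tables as computed;
#' * `rf_protein` - chemical descriptors permuted (protein information only);
#' * `rf_chemical` - enzyme descriptors permuted (chemical information only);
#' * `rf_none` - both permuted (no transferable object information);
#'
#' plus two non-ML baselines: `random_baseline` (Bernoulli draws at the
#' training activity ratio) and `activity_baseline` (top-k chemicals by
#' total training activity).
#'
#' @param name variant name (see above).
#' @param task `"classification"` or `"regression"`.
#' @param rf_hyperparameters named list passed to the forest (see
#'   [train_random_forest()]); ignored by the baselines.
#' @return object of class `model_variant`.
#' @export
model_variant <- function(name = c("rf_all", "rf_protein", "rf_chemical", "rf_none",
                                   "random_baseline", "activity_baseline"),
                          task = c("classification", "regression"),
                          rf_hyperparameters = list()) {
  structure(list(name = match.arg(name), task = match.arg(task),
                 rf_hyperparameters = rf_hyperparameters),
            class = "model_variant")
}

RF_VARIANTS <- c("rf_all", "rf_protein", "rf_chemical", "rf_none")
BASELINE_VARIANTS <- c("random_baseline", "activity_baseline")

#' Apply the permutation ablation of a model variant
#'
#' Permutes the enzyme and/or chemical descriptor tables according to the
#' variant: `rf_all` leaves both unchanged, `rf_protein` permutes the
#' chemical table, `rf_chemical` permutes the enzyme table and `rf_none`
#' permutes both (independent draws derived from `seed`).
#'
#' @param enzyme_table,chemical_table [descriptor_table()]s.
#' @param variant a [model_variant()] or variant name.
#' @param seed RNG seed for the permutation draw(s).
#' @return list with elements `enzyme_table`, `chemical_table`.
#' @export
apply_ablation <- function(enzyme_table, chemical_table, variant, seed) {
  name <- if (inherits(variant, "model_variant")) variant$name else variant
  if (name %in% BASELINE_VARIANTS) {
    stop_eciml("eciml_not_applicable",
               "descriptor ablation does not apply to baseline variants")
  }
  if (!name %in% RF_VARIANTS) {
    stop_eciml("eciml_validation_error", sprintf("unknown variant '%s'", name))
  }
  seed <- assert_seed(seed)
  if (name %in% c("rf_chemical", "rf_none")) {
    enzyme_table <- permute_table(enzyme_table, seed)
  }
  if (name %in% c("rf_protein", "rf_none")) {
    chemical_table <- permute_table(chemical_table, seed + 1L)
  }
  list(enzyme_table = enzyme_table, chemical_table = chemical_table)
}

default_rf_hyperparameters <- function() {
  list(num.trees = 500L, mtry_fraction = NULL, min.node.size = NULL, max.depth = NULL)
}

#' Train a Random Forest on pair features
#'
#' Fits a `ranger` forest on the concatenated descriptor matrix. For
#' classification the targets must be 0/1 and predictions are active-class
#' probabilities; for regression predictions are real values. Given the
#' same seed the fit and its predictions are reproducible.
#'
#' @param features numeric matrix (rows = pairs).
#' @param targets numeric vector aligned with `features` rows.
#' @param task `"classification"` or `"regression"`.
#' @param hyperparameters list; recognized entries `num.trees`,
#'   `mtry_fraction` (fraction of columns tried per split; default
#'   sqrt(p)/p), `min.node.size`, `max.depth` (`NULL` = unlimited).
#' @param seed RNG seed for the forest.
#' @return object of class `trained_model`; see [predict_model()].
#' @export
train_random_forest <- function(features, targets,
                                task = c("classification", "regression"),
                                hyperparameters = list(), seed = 1L) {
  task <- match.arg(task)
  hp <- utils::modifyList(default_rf_hyperparameters(), hyperparameters)
  features <- as.matrix(features)
  if (nrow(features) != length(targets)) {
    stop_eciml("eciml_validation_error", "features and targets are not row-aligned")
  }
  if (task == "classification") {
    if (!all(targets %in% c(0, 1))) {
      stop_eciml("eciml_validation_error", "classification targets must be 0/1")
    }
    if (length(unique(targets)) < 2L) {
      stop_eciml("eciml_degenerate_training",
                 "classification training set contains a single class")
    }
    y <- factor(targets, levels = c(0, 1))
  } else {
    y <- as.numeric(targets)
  }
  p <- ncol(features)
  mtry <- if (!is.null(hp$mtry_fraction)) max(1L, floor(hp$mtry_fraction * p)) else NULL
  colnames(features) <- paste0("f", seq_len(p))
  fit <- ranger::ranger(
    x = features, y = y,
    num.trees = hp$num.trees %||% 500L,
    mtry = mtry,
    min.node.size = hp$min.node.size,
    max.depth = hp$max.depth,
    probability = task == "classification",
    seed = assert_seed(seed), num.threads = 1L,
    verbose = FALSE)
  structure(list(task = task, fit = fit, n_features = p,
                 hyperparameters = hp, seed = seed),
            class = "trained_model")
}

#' Predict from a trained model
#'
#' @param model a `trained_model` from [train_random_forest()].
#' @param features numeric matrix with the training column layout.
#' @return numeric vector: active-class probabilities (classification) or
#'   fitted values (regression).
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop_eciml("eciml_validation_error", "feature dimension differs from training")
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  pred <- stats::predict(model$fit, data = features, num.threads = 1L)$predictions
  if (model$task == "classification") pred[, "1"] else as.numeric(pred)
}

#' Random baseline predictions
#'
#' The random model ignores all enzyme and chemical information: each pair
#' receives an independent Bernoulli draw with success probability equal to
#' the activity ratio of the training set. Scores above 0.5 (i.e. draws of
#' 1) are predicted active.
#'
#' @param training_activity_ratio fraction in \[0, 1\].
#' @param n_pairs number of pairs to score.
#' @param seed RNG seed.
#' @return 0/1 score vector of length `n_pairs`.
#' @export
random_baseline_predict <- function(training_activity_ratio, n_pairs, seed) {
  if (training_activity_ratio < 0 || training_activity_ratio > 1) {
    stop_eciml("eciml_validation_error", "activity ratio must lie in [0, 1]")
  }
  with_seed(seed, stats::rbinom(n_pairs, 1L, training_activity_ratio))
}

#' Fit the activity baseline
#'
#' The activity model uses only the training activity matrix: chemicals
#' are ranked by their total activity over the training enzymes, and for
#' any new enzyme the top-k chemicals are predicted active, where
#' k = round(n_chemicals x training activity ratio) (half-up, floored at
#' 0, capped at n_chemicals). The per-chemical totals double as ranking
#' scores for threshold-free metrics.
#'
#' @param training_matrix binary activity matrix (training enzymes x
#'   chemicals), `NA` = missing.
#' @return list with `chemical_scores` (named totals), `k`, and
#'   `active_chemicals` (ids of the k top-ranked chemicals).
#' @export
activity_baseline_fit <- function(training_matrix) {
  m <- as.matrix(training_matrix)
  if (length(m) == 0L || all(is.na(m))) {
    stop_eciml("eciml_validation_error", "empty training matrix")
  }
  scores <- colSums(m, na.rm = TRUE)
  if (is.null(names(scores))) names(scores) <- paste0("chem", seq_along(scores))
  ratio <- activity_ratio(m)
  k <- min(length(scores), max(0L, floor(length(scores) * ratio + 0.5)))
  ranked <- names(sort(scores, decreasing = TRUE))
  list(chemical_scores = scores, k = k,
       active_chemicals = if (k > 0L) ranked[seq_len(k)] else character(0))
}

#' Predict with the activity baseline
#'
#' @param fit result of [activity_baseline_fit()].
#' @param pairs data.frame with a `chemical_id` column; the enzyme is
#'   irrelevant (the model predicts the same profile for every enzyme).
#' @return list with `scores` (ranking scores) and `labels` (0/1 top-k
#'   predictions).
#' @export
activity_baseline_predict <- function(fit, pairs) {
  idx <- match(pairs$chemical_id, names(fit$chemical_scores))
  if (anyNA(idx)) {
    stop_eciml("eciml_lookup_error", "pair list contains chemicals unseen in training")
  }
  scores <- as.numeric(fit$chemical_scores[idx])
  labels <- as.numeric(pairs$chemical_id %in% fit$active_chemicals)
  list(scores = scores, labels = labels)
}

# Precision at the 0.5 probability cutoff; NA when nothing is predicted
# active.
precision_at_half <- function(labels, scores) {
  pred <- scores > 0.5
  if (!any(pred)) return(NA_real_)
  mean(labels[pred] == 1)
}

#' Random-search hyperparameter tuning
#'
#' Samples `budget` configurations from a documented Random-Forest grid
#' (tree count 100-1000, max depth unlimited/5/10/20, min node size
#' 1/5/10, mtry fraction 0.1-1) and scores each by cross-validation on the
#' given scenario: mean validation precision (classification, maximized)
#' or mean validation MAE (regression, minimized). Deterministic given
#' `seed`.
#'
#' @param dataset an [activity_dataset()].
#' @param variant a [model_variant()] (an RF variant).
#' @param scenario `"LOOT"`, `"LPOT"` or `"LCOT"`.
#' @param budget number of sampled configurations.
#' @param seed RNG seed controlling sampling, splits and forests.
#' @param enzyme_spec,chemical_spec descriptor specs (see [run_cv()]).
#' @param n_folds folds for the internal cross-validation.
#' @return list with `best` (hyperparameter list), `objective`, and
#'   `trace` (data.frame of all evaluated configurations).
#' @export
tune_hyperparameters <- function(dataset, variant, scenario, budget = 10L, seed = 1L,
                                 enzyme_spec = descriptor_spec("composition50"),
                                 chemical_spec = NULL, n_folds = 10L) {
  stopifnot(budget >= 1L, inherits(variant, "model_variant"))
  configs <- with_seed(seed, lapply(seq_len(budget), function(i) {
    list(num.trees = sample(c(100L, 200L, 500L, 1000L), 1L),
         max.depth = sample(list(NULL, 5L, 10L, 20L), 1L)[[1]],
         min.node.size = sample(c(1L, 5L, 10L), 1L),
         mtry_fraction = stats::runif(1, 0.1, 1))
  }))
  objectives <- vapply(seq_along(configs), function(i) {
    v <- model_variant(variant$name, variant$task, configs[[i]])
    res <- run_cv(dataset, enzyme_spec = enzyme_spec, chemical_spec = chemical_spec,
                  variants = list(v), scenario = scenario, seeds = seed,
                  n_folds = n_folds, metrics_extra = variant$task == "classification")
    met <- if (variant$task == "classification") "precision" else "mae"
    vals <- res$records$value[res$records$metric == met]
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  best_i <- if (variant$task == "classification") which.max(objectives) else which.min(objectives)
  trace <- data.frame(
    config = seq_along(configs),
    num.trees = vapply(configs, function(cf) cf$num.trees, integer(1)),
    max.depth = vapply(configs, function(cf) cf$max.depth %||% NA_integer_, integer(1)),
    min.node.size = vapply(configs, function(cf) cf$min.node.size, integer(1)),
    mtry_fraction = vapply(configs, function(cf) cf$mtry_fraction, numeric(1)),
    objective = objectives)
  list(best = configs[[best_i]], objective = objectives[best_i], trace = trace)
}
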