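#' Scenario imbalance filter
#'
#' For the new-enzyme scenario (`"LPOT"`), chemicals are kept only if
#' their activity count lies between 10% and 90% of the number of enzymes
#' (bounds inclusive) and is larger than 1; the new-chemical scenario
#' (`"LCOT"`) applies the symmetric rule to enzymes. `"LOOT"` keeps
#' everything. The filter is computed once on the full binary matrix, as
#' part of preparing the dataset for the scenario.
#'
#' @param binary_matrix binary activity matrix (`NA` = missing).
#' @param scenario `"LOOT"`, `"LPOT"` or `"LCOT"`.
#' @return list with `retained_enzymes`, `retained_chemicals` (ids, or
#'   indices when the matrix has no dimnames).
#' @export
filter_for_scenario <- function(binary_matrix, scenario = c("LOOT", "LPOT", "LCOT")) {
  scenario <- match.arg(scenario)
  m <- as.matrix(binary_matrix)
  enz <- rownames(m) %||% as.character(seq_len(nrow(m)))
  chem <- colnames(m) %||% as.character(seq_len(ncol(m)))
  if (scenario == "LPOT") {
    counts <- colSums(m == 1, na.rm = TRUE)
    keep <- counts >= 0.1 * nrow(m) & counts <= 0.9 * nrow(m) & counts > 1
    if (!any(keep)) {
      stop_eciml("eciml_empty_after_filter",
                 "LPOT filter removed every chemical")
    }
    chem <- chem[keep]
  } else if (scenario == "LCOT") {
    counts <- rowSums(m == 1, na.rm = TRUE)
    keep <- counts >= 0.1 * ncol(m) & counts <= 0.9 * ncol(m) & counts > 1
    if (!any(keep)) {
      stop_eciml("eciml_empty_after_filter",
                 "LCOT filter removed every enzyme")
    }
    enz <- enz[keep]
  }
  list(retained_enzymes = enz, retained_chemicals = chem)
}

pairs_of <- function(m, binary) {
  idx <- which(!is.na(m), arr.ind = TRUE)
  data.frame(enzyme_id = rownames(m)[idx[, 1]],
             chemical_id = colnames(m)[idx[, 2]],
             value = m[idx],
             binary = binary[idx],
             stringsAsFactors = FALSE)
}

#' Build a cross-validation split plan
#'
#' `"LOOT"` partitions the assayed (enzyme, chemical) pairs into
#' `n_folds` random folds; `"LPOT"` partitions the enzymes (after
#' filtering the chemicals); `"LCOT"` partitions the chemicals (after
#' filtering the enzymes). Fold sizes on the split axis differ by at most
#' one, and in LPOT/LCOT no held-out object contributes any training
#' pair. Deterministic given `seed`.
#'
#' @param dataset an [activity_dataset()].
#' @param scenario `"LOOT"`, `"LPOT"` or `"LCOT"`.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return object of class `split_plan` with elements `scenario`,
#'   `n_folds`, `seed`, `retained_enzymes`, `retained_chemicals` and
#'   `folds` (list of `train_pairs` / `validation_pairs` data.frames with
#'   columns `enzyme_id`, `chemical_id`, `value`, `binary`).
#' @export
make_splits <- function(dataset, scenario = c("LOOT", "LPOT", "LCOT"),
                        n_folds = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "activity_dataset"))
  scenario <- match.arg(scenario)
  bm_full <- binary_matrix_of(dataset)
  keep <- filter_for_scenario(bm_full, scenario)
  m <- dataset$activity[keep$retained_enzymes, keep$retained_chemicals, drop = FALSE]
  bm <- bm_full[keep$retained_enzymes, keep$retained_chemicals, drop = FALSE]
  all_pairs <- pairs_of(m, bm)

  axis_size <- switch(scenario,
    LOOT = nrow(all_pairs),
    LPOT = length(keep$retained_enzymes),
    LCOT = length(keep$retained_chemicals))
  if (axis_size < n_folds) {
    stop_eciml("eciml_config_error", sprintf(
      "split axis has %d objects, fewer than n_folds = %d; reduce n_folds",
      axis_size, n_folds))
  }
  assignment <- with_seed(seed, {
    fold_id <- integer(axis_size)
    fold_id[sample.int(axis_size)] <- rep(seq_len(n_folds), length.out = axis_size)
    fold_id
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    if (scenario == "LOOT") {
      val <- assignment == f
      list(train_pairs = all_pairs[!val, , drop = FALSE],
           validation_pairs = all_pairs[val, , drop = FALSE])
    } else if (scenario == "LPOT") {
      val_enz <- keep$retained_enzymes[assignment == f]
      val <- all_pairs$enzyme_id %in% val_enz
      list(train_pairs = all_pairs[!val, , drop = FALSE],
           validation_pairs = all_pairs[val, , drop = FALSE])
    } else {
      val_chem <- keep$retained_chemicals[assignment == f]
      val <- all_pairs$chemical_id %in% val_chem
      list(train_pairs = all_pairs[!val, , drop = FALSE],
           validation_pairs = all_pairs[val, , drop = FALSE])
    }
  })
  structure(
    list(scenario = scenario, n_folds = n_folds, seed = seed,
         retained_enzymes = keep$retained_enzymes,
         retained_chemicals = keep$retained_chemicals,
         folds = folds),
    class = "split_plan"
  )
}

#' Area under the ROC curve
#'
#' Rank-based AUROC: the probability that a random positive is scored
#' higher than a random negative, with ties counted 0.5.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop_eciml("eciml_undefined_metric", "AUROC needs both classes present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: the precision-recall step curve is evaluated at
#' every distinct score threshold and summed as
#' `sum((R_i - R_{i-1}) * P_i)`. Baselines at the positive prevalence for
#' random scores.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(labels, scores) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) {
    stop_eciml("eciml_undefined_metric", "AUPR needs at least one positive")
  }
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  n <- length(l)
  cut <- c(which(diff(s) != 0), n)  # last index at each distinct threshold
  tp <- cumsum(l)[cut]
  precision <- tp / cut
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Regression metrics
#'
#' R2 (squared Pearson correlation between observed and predicted) and
#' MAE (mean absolute error). When the observed values are constant the
#' correlation is undefined: `r2` is returned as `NA` with a warning and
#' `mae` is still computed.
#'
#' @param observed,predicted numeric vectors (length >= 3 for `r2`).
#' @return list with `r2` and `mae`.
#' @export
regression_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  mae <- mean(abs(observed - predicted))
  r2 <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0 || length(observed) < 3L) {
    warning("R2 undefined for constant or too-short input; returning NA")
    NA_real_
  } else {
    stats::cor(observed, predicted)^2
  }
  list(r2 = r2, mae = mae)
}

default_cv_seeds <- function() c(101L, 211L, 307L, 401L, 503L)

resolve_variants <- function(variants, task) {
  lapply(variants, function(v) {
    if (inherits(v, "model_variant")) v else model_variant(v, task)
  })
}

#' Run the cross-validation evaluation
#'
#' The full evaluation driver: for each seed it builds the descriptor
#' tables, applies each variant's permutation ablation (seeded from the
#' split seed), makes the scenario's split plan, trains on the training
#' pairs, scores the validation pairs and records the per-fold metrics
#' (AUPR and AUROC for classification; R2 and MAE for regression).
#' Baselines are evaluated on the same splits. Folds whose validation (or
#' training) set collapses to a single class are skipped and logged; a
#' variant with more than half of its folds skipped aborts the run.
#'
#' @param dataset an [activity_dataset()].
#' @param enzyme_spec [descriptor_spec()] for enzymes (default
#'   `"composition50"`).
#' @param chemical_spec [descriptor_spec()] for chemicals; default uses
#'   Morgan fingerprints when SMILES are available. Required (as an
#'   external spec) when the dataset has no SMILES and RF variants are
#'   requested.
#' @param variants list of [model_variant()]s or variant names.
#' @param scenario `"LOOT"`, `"LPOT"` or `"LCOT"`.
#' @param seeds integer vector of split seeds (default 5 fixed seeds).
#' @param n_folds folds per seed (default 10).
#' @param task default task for variants given as names.
#' @param metrics_extra also record the precision at the 0.5 cutoff
#'   (classification only).
#' @return object of class `cv_result` with `records` (long data.frame:
#'   scenario, variant, seed, fold, metric, value), `aggregates` (mean,
#'   sd, sem, n per variant and metric) and `skips`.
#' @export
run_cv <- function(dataset,
                   enzyme_spec = descriptor_spec("composition50"),
                   chemical_spec = NULL,
                   variants = list("rf_all"),
                   scenario = c("LOOT", "LPOT", "LCOT"),
                   seeds = default_cv_seeds(),
                   n_folds = 10L,
                   task = c("classification", "regression"),
                   metrics_extra = FALSE) {
  stopifnot(inherits(dataset, "activity_dataset"), length(variants) >= 1L)
  scenario <- match.arg(scenario)
  task <- match.arg(task)
  variants <- resolve_variants(variants, task)
  vnames <- vapply(variants, function(v) v$name, character(1))
  need_tables <- any(vnames %in% RF_VARIANTS)

  if (need_tables && is.null(chemical_spec)) {
    if (anyNA(dataset$chemicals$smiles)) {
      stop_eciml("eciml_config_error",
                 "dataset has no SMILES; supply an external chemical_spec")
    }
    chemical_spec <- descriptor_spec("chem_fingerprint")
  }
  etab0 <- ctab0 <- NULL
  if (need_tables) {
    seqs <- stats::setNames(dataset$enzymes$sequence, dataset$enzymes$enzyme_id)
    etab0 <- build_sequence_table(seqs, enzyme_spec)
    smi <- stats::setNames(dataset$chemicals$smiles, dataset$chemicals$chemical_id)
    ctab0 <- build_chemical_table(smi, chemical_spec,
                                  object_ids = dataset$chemicals$chemical_id)
  }

  records <- list()
  skips <- list()
  rec <- function(variant, seed, fold, metric, value) {
    records[[length(records) + 1L]] <<- data.frame(
      scenario = scenario, variant = variant, seed = seed, fold = fold,
      metric = metric, value = value, stringsAsFactors = FALSE)
  }
  skip <- function(variant, seed, fold, reason) {
    skips[[length(skips) + 1L]] <<- data.frame(
      variant = variant, seed = seed, fold = fold, reason = reason,
      stringsAsFactors = FALSE)
  }

  for (seed in seeds) {
    plan <- make_splits(dataset, scenario, n_folds = n_folds, seed = seed)
    tm <- dataset$activity[plan$retained_enzymes, plan$retained_chemicals, drop = FALSE]
    bm <- binary_matrix_of(dataset)[plan$retained_enzymes, plan$retained_chemicals, drop = FALSE]

    tables <- list()
    for (v in variants) {
      if (v$name %in% RF_VARIANTS) {
        tables[[v$name]] <- apply_ablation(etab0, ctab0, v$name, seed)
      }
    }
    for (f in seq_len(n_folds)) {
      fold <- plan$folds[[f]]
      tr <- fold$train_pairs
      va <- fold$validation_pairs
      for (v in variants) {
        y_tr <- if (v$task == "classification") tr$binary else tr$value
        y_va <- if (v$task == "classification") va$binary else va$value
        if (nrow(va) == 0L) { skip(v$name, seed, f, "empty validation fold"); next }
        if (v$task == "classification" && length(unique(va$binary)) < 2L) {
          skip(v$name, seed, f, "single-class validation fold"); next
        }
        scores <- NULL
        if (v$name %in% RF_VARIANTS) {
          if (v$task == "classification" && length(unique(y_tr)) < 2L) {
            skip(v$name, seed, f, "single-class training fold"); next
          }
          tabs <- tables[[v$name]]
          x_tr <- concat_pair_features(tabs$enzyme_table, tabs$chemical_table, tr)
          x_va <- concat_pair_features(tabs$enzyme_table, tabs$chemical_table, va)
          model <- train_random_forest(x_tr, y_tr, v$task,
                                       v$rf_hyperparameters, seed = seed * 100L + f)
          scores <- predict_model(model, x_va)
        } else if (v$name == "random_baseline") {
          ratio <- mean(tr$binary)
          scores <- random_baseline_predict(ratio, nrow(va), seed = seed * 100L + f)
        } else if (v$name == "activity_baseline") {
          if (scenario == "LPOT") {
            train_enz <- setdiff(plan$retained_enzymes, unique(va$enzyme_id))
            fitb <- activity_baseline_fit(bm[train_enz, , drop = FALSE])
            scores <- activity_baseline_predict(fitb, va)$scores
          } else if (scenario == "LCOT") {
            train_chem <- setdiff(plan$retained_chemicals, unique(va$chemical_id))
            fitb <- activity_baseline_fit(t(bm[, train_chem, drop = FALSE]))
            scores <- activity_baseline_predict(
              fitb, data.frame(chemical_id = va$enzyme_id))$scores
          } else {
            stop_eciml("eciml_not_applicable",
                       "the activity baseline is defined for LPOT and LCOT only")
          }
        }
        if (v$task == "classification") {
          rec(v$name, seed, f, "aupr", aupr(y_va, scores))
          rec(v$name, seed, f, "auroc", auroc(y_va, scores))
          if (metrics_extra) rec(v$name, seed, f, "precision",
                                 precision_at_half(y_va, scores))
        } else {
          rm_ <- suppressWarnings(regression_metrics(y_va, scores))
          if (!is.na(rm_$r2)) rec(v$name, seed, f, "r2", rm_$r2)
          rec(v$name, seed, f, "mae", rm_$mae)
        }
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(scenario = character(), variant = character(), seed = integer(),
               fold = integer(), metric = character(), value = numeric())
  skips <- if (length(skips)) do.call(rbind, skips) else
    data.frame(variant = character(), seed = integer(), fold = integer(),
               reason = character())

  total_folds <- length(seeds) * n_folds
  for (vn in vnames) {
    n_skipped <- sum(skips$variant == vn)
    if (n_skipped > 0.5 * total_folds) {
      stop_eciml("eciml_run_error", sprintf(
        "variant '%s' skipped %d of %d folds", vn, n_skipped, total_folds))
    }
  }
  aggregates <- aggregate_records(records)
  structure(list(scenario = scenario, records = records,
                 aggregates = aggregates, skips = skips),
            class = "cv_result")
}

aggregate_records <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(variant = character(), metric = character(),
                      mean = numeric(), sd = numeric(), sem = numeric(),
                      n = integer()))
  }
  out <- do.call(rbind, lapply(split(records, records[c("variant", "metric")], drop = TRUE),
    function(g) {
      v <- g$value[!is.na(g$value)]
      data.frame(variant = g$variant[1], metric = g$metric[1],
                 mean = mean(v), sd = stats::sd(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$metric, out$variant), ]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> scenario %s: %d records, %d skipped folds\n",
              x$scenario, nrow(x$records), nrow(x$skips)))
  print(x$aggregates, row.names = FALSE, digits = 3)
  invisible(x)
}

star_string <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Compare two models with a two-sample test
#'
#' Independent two-sample Student t-test (equal variances by default;
#' Welch via `var_equal = FALSE`) on the per-fold metric values of two
#' models, with the usual significance stars: `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001.
#'
#' @param result_a,result_b `cv_result` objects (or numeric vectors of
#'   per-fold values).
#' @param metric metric name, e.g. `"aupr"`.
#' @param variant_a,variant_b variant to extract when a result contains
#'   several (defaults to the only one present).
#' @param var_equal use the pooled-variance test (default `TRUE`).
#' @return list with `p_value`, `stars`, `estimate` (mean difference a-b)
#'   and `n` (sample sizes).
#' @export
compare_models <- function(result_a, result_b, metric = "aupr",
                           variant_a = NULL, variant_b = NULL, var_equal = TRUE) {
  xa <- extract_metric_values(result_a, metric, variant_a)
  xb <- extract_metric_values(result_b, metric, variant_b)
  if (length(xa) < 2L || length(xb) < 2L) {
    stop_eciml("eciml_validation_error",
               "need at least 2 metric values per model to compare")
  }
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    # degenerate: both samples constant, the t statistic is 0/0 or +-Inf
    p <- if (mean(xa) == mean(xb)) 1 else 0
    return(list(p_value = p, stars = star_string(p),
                estimate = mean(xa) - mean(xb), n = c(length(xa), length(xb))))
  }
  tt <- stats::t.test(xa, xb, var.equal = var_equal)
  list(p_value = tt$p.value, stars = star_string(tt$p.value),
       estimate = mean(xa) - mean(xb), n = c(length(xa), length(xb)))
}

extract_metric_values <- function(result, metric, variant = NULL) {
  if (is.numeric(result)) return(result[!is.na(result)])
  stopifnot(inherits(result, "cv_result"))
  r <- result$records[result$records$metric == metric, ]
  if (!is.null(variant)) r <- r[r$variant == variant, ]
  if (length(unique(r$variant)) > 1L) {
    stop_eciml("eciml_validation_error",
               "result contains several variants; pass variant_a/variant_b")
  }
  r$value[!is.na(r$value)]
}
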