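test_that("the imbalance filter applies the 10%-90% and count>1 rules inclusively", {
  m <- matrix(0, 10, 5, dimnames = list(paste0("e", 1:10), paste0("c", 1:5)))
  m[1, 1] <- 1                 # count 1: fails count > 1
  m[, 2] <- 1                  # count 10 = 100%: above 90%
  m[1:5, 3] <- 1               # count 5: retained
  m[1:9, 4] <- 1               # count 9 = 90%: retained (inclusive)
  m[1, 5] <- 1; m[2, 5] <- 1   # count 2 = 20%: retained
  keep <- filter_for_scenario(m, "LPOT")
  expect_setequal(keep$retained_chemicals, c("c3", "c4", "c5"))
  expect_equal(keep$retained_enzymes, paste0("e", 1:10))

  keep_loot <- filter_for_scenario(m, "LOOT")
  expect_equal(keep_loot$retained_chemicals, paste0("c", 1:5))

  # symmetric rule on enzymes for LCOT
  m2 <- t(m); keep_lcot <- filter_for_scenario(m2, "LCOT")
  expect_setequal(keep_lcot$retained_enzymes, c("c3", "c4", "c5"))

  all_zero <- matrix(0, 4, 4)
  expect_error(filter_for_scenario(all_zero, "LPOT"),
               class = "eciml_empty_after_filter")
})

test_that("split plans partition the split axis with balanced folds, deterministically", {
  ds <- binarize_activity(activity_dataset(
    enzymes = data.frame(enzyme_id = paste0("e", 1:10),
                         sequence = replicate(10, random_peptide(12))),
    chemicals = data.frame(chemical_id = paste0("c", 1:10)),
    activity = matrix(runif(100), 10,
                      dimnames = list(paste0("e", 1:10), paste0("c", 1:10))),
    metadata = dataset_metadata()), threshold = 0.5)

  loot <- make_splits(ds, "LOOT", n_folds = 10, seed = 3)
  sizes <- vapply(loot$folds, function(f) nrow(f$validation_pairs), integer(1))
  expect_equal(sizes, rep(10L, 10))
  all_val <- do.call(rbind, lapply(loot$folds, `[[`, "validation_pairs"))
  expect_equal(nrow(unique(all_val[c("enzyme_id", "chemical_id")])), 100L)

  g <- generate_dataset(synthetic_config(seed = 5))
  lpot <- make_splits(g$dataset, "LPOT", n_folds = 10, seed = 2)
  val_enz <- lapply(lpot$folds, function(f) unique(f$validation_pairs$enzyme_id))
  expect_equal(sort(unlist(val_enz)), sort(lpot$retained_enzymes))
  expect_equal(anyDuplicated(unlist(val_enz)), 0L)

  expect_identical(make_splits(g$dataset, "LPOT", n_folds = 10, seed = 2)$folds,
                   lpot$folds)
  expect_error(make_splits(ds, "LPOT", n_folds = 50, seed = 1),
               class = "eciml_config_error")
})

test_that("no information leaks from validation to training in any plan", {
  g <- generate_dataset(synthetic_config(seed = 11))
  for (scenario in c("LOOT", "LPOT", "LCOT")) {
    plan <- make_splits(g$dataset, scenario, n_folds = 10, seed = 4)
    for (fold in plan$folds) {
      key <- function(p) paste(p$enzyme_id, p$chemical_id)
      expect_length(intersect(key(fold$train_pairs), key(fold$validation_pairs)), 0)
      if (scenario == "LPOT") {
        expect_length(intersect(unique(fold$validation_pairs$enzyme_id),
                                unique(fold$train_pairs$enzyme_id)), 0)
      }
      if (scenario == "LCOT") {
        expect_length(intersect(unique(fold$validation_pairs$chemical_id),
                                unique(fold$train_pairs$chemical_id)), 0)
      }
    }
  }
})

test_that("AUROC matches hand values and the exhaustive pair-counting oracle", {
  expect_equal(auroc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.8, 0.6, 0.4, 0.2)), 0.75)
  expect_error(auroc(c(1, 1), c(0.5, 0.6)), class = "eciml_undefined_metric")

  set.seed(23)
  for (i in 1:15) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(auroc(labels, scores), auroc_pair_oracle(labels, scores),
                 tolerance = 1e-9)
  }

  set.seed(29)
  big <- rbinom(10000, 1, 0.5)
  expect_lt(abs(auroc(big, runif(10000)) - 0.5), 0.02)
})

test_that("AUPR matches hand values and the step-curve enumeration oracle", {
  expect_equal(aupr(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(aupr(c(0, 1, 0), c(0.9, 0.8, 0.1)), 0.5)
  expect_error(aupr(c(0, 0), c(0.4, 0.2)), class = "eciml_undefined_metric")

  set.seed(31)
  for (i in 1:15) {
    n <- sample(4:20, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    expect_equal(aupr(labels, scores), aupr_step_oracle(labels, scores),
                 tolerance = 1e-9)
  }

  set.seed(37)
  labels <- rbinom(10000, 1, 0.2)
  expect_lt(abs(aupr(labels, runif(10000)) - 0.2), 0.03)
})

test_that("regression metrics follow the Pearson-r2 / MAE definitions", {
  obs <- c(1, 2, 3, 4)
  rm1 <- regression_metrics(obs, obs)
  expect_equal(rm1$r2, 1); expect_equal(rm1$mae, 0)

  rm2 <- regression_metrics(obs, obs + 2)
  expect_equal(rm2$r2, 1); expect_equal(rm2$mae, 2)

  rm3 <- regression_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(rm3$r2, 0.25)          # Pearson r = 0.5
  expect_equal(rm3$mae, 2 / 3)

  expect_warning(rm4 <- regression_metrics(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(rm4$r2))
  expect_equal(rm4$mae, 1)
})

test_that("the cross-validation driver fills records, aggregates and skips coherently", {
  g <- generate_dataset(synthetic_config(
    n_families = 2, enzymes_per_family = 8, sequence_length = 40,
    n_classes = 2, chemicals_per_class = 6, seed = 21))
  cspec <- descriptor_spec("external", vectors = g$truth$chemical_features)
  res <- run_cv(g$dataset, chemical_spec = cspec,
                variants = list("rf_all", "random_baseline"),
                scenario = "LOOT", seeds = c(1, 2), n_folds = 5)
  # bookkeeping: records + skips account for every (seed, fold) combination
  for (v in c("rf_all", "random_baseline")) {
    expect_equal(sum(res$records$metric == "aupr" & res$records$variant == v) +
                   sum(res$skips$variant == v), 10L)
  }
  agg <- res$aggregates
  expect_true(all(c("mean", "sd", "sem", "n") %in% names(agg)))
  expect_equal(agg$sem, agg$sd / sqrt(agg$n))

  # rf_all strongly beats the random baseline on block-structured data
  a <- agg[agg$variant == "rf_all" & agg$metric == "aupr", ]
  b <- agg[agg$variant == "random_baseline" & agg$metric == "aupr", ]
  expect_gt(a$mean, b$mean)
})

test_that("regression CV records R2 and MAE", {
  g <- generate_dataset(synthetic_config(
    n_families = 2, enzymes_per_family = 8, sequence_length = 40,
    n_classes = 2, chemicals_per_class = 6, noise_sd = 0.2, seed = 31))
  ds <- g$dataset
  ds$activity <- g$truth$latent_activity   # continuous targets
  ds$metadata$activity_scale <- "raw"
  ds$metadata$activity_threshold <- stats::median(ds$activity)
  cspec <- descriptor_spec("external", vectors = g$truth$chemical_features)
  res <- run_cv(ds, chemical_spec = cspec,
                variants = list(model_variant("rf_all", "regression")),
                scenario = "LOOT", seeds = 1, n_folds = 5)
  expect_setequal(unique(res$records$metric), c("r2", "mae"))
  r2 <- res$aggregates[res$aggregates$metric == "r2", "mean"]
  expect_gt(r2, 0.3)
})

test_that("model comparison reports pooled t-test p-values with the star convention", {
  same <- compare_models(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  sep <- compare_models(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_lt(sep$p_value, 0.001)
  expect_identical(sep$stars, "***")

  set.seed(41)
  for (i in 1:8) {
    xa <- rnorm(10, mean = runif(1, 0, 1), sd = 0.3)
    xb <- rnorm(10, mean = runif(1, 0, 1), sd = 0.3)
    cm <- compare_models(xa, xb)
    expect_equal(cm$p_value, t.test(xa, xb, var.equal = TRUE)$p.value)
    expected_stars <- if (cm$p_value < 0.001) "***" else if (cm$p_value < 0.01) "**"
      else if (cm$p_value < 0.05) "*" else ""
    expect_identical(cm$stars, expected_stars)
  }
  expect_error(compare_models(0.5, c(0.4, 0.6)), class = "eciml_validation_error")
})
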