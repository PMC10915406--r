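test_that("activity ratio covers binary, continuous and boundary cases", {
  expect_equal(activity_ratio(matrix(c(1, 0, 0, 0), 2)), 0.25)
  expect_equal(activity_ratio(matrix(1, 3, 3)), 1)
  expect_equal(activity_ratio(matrix(c(0.2, 0.4, 0.6, 0.8), 2)), 0.5)
  expect_equal(activity_ratio(matrix(c(1, NA, 0, NA), 2)), 0.5)
  expect_error(activity_ratio(matrix(NA_real_, 2, 2)),
               class = "eciml_undefined_statistic")
})

test_that("AOIE is 1 on rank-consistent matrices and matches the enumeration oracle", {
  m <- matrix(rep(c(3, 2, 1), 4), nrow = 3)
  expect_equal(aoie(m), 1)

  m2 <- matrix(c(3, 2, 1, 1, 2, 3), nrow = 3)  # columns (3,2,1) and (1,2,3)
  expect_equal(aoie(m2), aoie_enumeration_oracle(m2), tolerance = 1e-12)

  expect_error(aoie(matrix(1, 1, 3)), class = "eciml_undefined_statistic")
})

test_that("AOIE/AOIC equal the pairwise-concordance oracle on small matrices", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    p <- sample(2:6, 1)
    m <- matrix(sample(0:3, n * p, replace = TRUE), n, p)
    m[sample(length(m), size = floor(length(m) / 6))] <- NA
    if (all(is.na(m))) next
    ok <- tryCatch({
      expect_equal(aoie(m), aoie_enumeration_oracle(m), tolerance = 1e-9)
      expect_equal(aoic(m), aoie_enumeration_oracle(t(m)), tolerance = 1e-9)
      TRUE
    }, eciml_undefined_statistic = function(e) TRUE)
    expect_true(ok)
  }
})

test_that("AOIC is 1 when every enzyme ranks the chemicals identically", {
  m <- matrix(rep(c(4, 3, 2, 1), each = 5), nrow = 5)
  expect_equal(aoic(m), 1)
  # transpose symmetry
  set.seed(5)
  r <- matrix(runif(30), 5, 6)
  expect_equal(aoic(r), aoie(t(r)))
})

test_that("AOIE and AOIC hover around 0.5 for i.i.d. random data", {
  set.seed(99)
  vals_e <- vals_c <- numeric(20)
  for (i in 1:20) {
    m <- matrix(rbinom(50 * 20, 1, 0.3), 50, 20)
    vals_e[i] <- aoie(m)
    vals_c[i] <- aoic(m)
  }
  expect_lt(abs(mean(vals_e) - 0.5), 0.05)
  expect_lt(abs(mean(vals_c) - 0.5), 0.05)
  expect_true(all(vals_e >= 0 & vals_e <= 1))
})

test_that("top-k mean similarity handles constants, short neighbourhoods and monotonicity", {
  s <- matrix(0.4, 4, 4); diag(s) <- 1
  expect_equal(topk_mean_similarity(s, k = 5), 0.4)

  s3 <- matrix(c(1, 0.2, 0.8,
                 0.2, 1, 0.5,
                 0.8, 0.5, 1), 3, byrow = TRUE)
  # per object mean of its two neighbours: (0.5, 0.35, 0.65)
  expect_equal(topk_mean_similarity(s3, k = 5), mean(c(0.5, 0.35, 0.65)))

  s3b <- s3; s3b[1, 2] <- s3b[2, 1] <- 0.9
  expect_gt(topk_mean_similarity(s3b, k = 5), topk_mean_similarity(s3, k = 5))

  # invariant to a simultaneous row/column permutation
  set.seed(3)
  s6 <- matrix(runif(36), 6); s6 <- (s6 + t(s6)) / 2; diag(s6) <- 1
  perm <- sample(6)
  expect_equal(topk_mean_similarity(s6[perm, perm], k = 3),
               topk_mean_similarity(s6, k = 3))

  expect_error(topk_mean_similarity(matrix(1, 1, 1)),
               class = "eciml_undefined_statistic")
})

test_that("normalized Smith-Waterman similarity matches the DP oracle", {
  sub <- blosum62()
  expect_equal(local_alignment_similarity("MKTAYIAK", "MKTAYIAK"), 1)

  s_pkg <- local_alignment_similarity("HEAGAWGHEE", "PAWHEAE")
  s_ora <- sw_similarity_oracle("HEAGAWGHEE", "PAWHEAE", sub)
  expect_equal(s_pkg, s_ora, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:12) {
    a <- random_peptide(sample(3:12, 1))
    b <- random_peptide(sample(3:12, 1))
    expect_equal(local_alignment_similarity(a, b),
                 sw_similarity_oracle(a, b, sub), tolerance = 1e-9)
    expect_equal(local_alignment_similarity(a, b),
                 local_alignment_similarity(b, a), tolerance = 1e-12)
  }
  expect_error(local_alignment_similarity("", "MK"), class = "eciml_domain_error")
})

test_that("protein similarity matrix is symmetric with unit diagonal", {
  set.seed(2)
  seqs <- setNames(replicate(4, random_peptide(30)), paste0("e", 1:4))
  s <- protein_similarity_matrix(seqs)
  expect_equal(diag(s), setNames(rep(1, 4), names(seqs)))
  expect_equal(s, t(s), tolerance = 1e-12)
  expect_equal(s["e1", "e2"],
               local_alignment_similarity(seqs[["e1"]], seqs[["e2"]]),
               tolerance = 1e-12)
})

test_that("Tanimoto similarity behaves on identical, overlapping and disjoint bit sets", {
  a <- integer(16); a[c(1, 2, 3)] <- 1L
  b <- integer(16); b[c(2, 3, 4)] <- 1L
  d <- integer(16); d[c(5, 6)] <- 1L
  expect_equal(tanimoto_bits(a, a), 1)
  expect_equal(tanimoto_bits(a, b), 0.5)   # 2 shared of 4 in the union
  expect_equal(tanimoto_bits(a, d), 0)

  expect_equal(morgan_tanimoto_similarity("CCO", "CCO"), 1)
  s_close <- morgan_tanimoto_similarity("CCO", "CCCO")
  s_far <- morgan_tanimoto_similarity("CCO", "c1ccncc1C(=O)O")
  expect_true(s_close > s_far)
  expect_true(s_close >= 0 && s_close <= 1)
  expect_error(morgan_tanimoto_similarity("notasmiles((", "CCO"),
               class = "eciml_parse_error")
})

test_that("Morgan fingerprints agree with an independent circular fingerprint on ranking", {
  smiles <- c(a = "CCO", b = "CCCO", c = "CCCCO", d = "c1ccccc1O", e = "c1ccncc1")
  fp <- morgan_fingerprints(smiles)
  expect_equal(dim(fp), c(5L, 2048L))
  expect_true(all(fp %in% c(0L, 1L)))

  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ob <- ChemmineR::fingerprintOB(sdf, "ECFP4")@fpma
  tan <- function(m, i, j) {
    u <- sum(m[i, ] | m[j, ]); if (u == 0) 1 else sum(m[i, ] & m[j, ]) / u
  }
  pairs <- t(combn(5, 2))
  ours <- apply(pairs, 1, function(p) tan(fp, p[1], p[2]))
  theirs <- apply(pairs, 1, function(p) tan(ob, p[1], p[2]))
  # same similarity ordering of molecule pairs as OpenBabel's ECFP4
  expect_gt(cor(ours, theirs, method = "spearman"), 0.75)
})

test_that("scenario statistics reflect the scenario's filtering", {
  g <- generate_dataset(synthetic_config(seed = 7))
  st <- compute_statistics(g$dataset, "LOOT", include_similarity = FALSE)
  expect_equal(st$n_enzymes, 40L)
  expect_equal(st$n_chemicals, 20L)

  # toy LPOT case: one chemical active on a single enzyme fails count > 1
  m <- matrix(0, 10, 3, dimnames = list(paste0("e", 1:10), paste0("c", 1:3)))
  m[1:5, 1] <- 1; m[1:4, 2] <- 1; m[1, 3] <- 1
  ds <- activity_dataset(
    enzymes = data.frame(enzyme_id = paste0("e", 1:10),
                         sequence = replicate(10, random_peptide(15))),
    chemicals = data.frame(chemical_id = paste0("c", 1:3)),
    activity = m,
    metadata = dataset_metadata(activity_scale = "binary"))
  st2 <- compute_statistics(ds, "LPOT", include_similarity = FALSE)
  expect_equal(st2$n_chemicals, 2L)
  expect_equal(st2$n_enzymes, 10L)

  # random data: both order indices near 0.5
  noise <- generate_dataset(synthetic_config(
    block_affinity = matrix(0, 4, 4), enzyme_effect_sd = 0,
    chemical_effect_sd = 0, noise_sd = 1, seed = 13))
  st3 <- compute_statistics(noise$dataset, "LOOT", include_similarity = FALSE)
  expect_lt(abs(st3$aoie - 0.5), 0.07)
  expect_lt(abs(st3$aoic - 0.5), 0.07)
})
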