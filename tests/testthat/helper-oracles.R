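# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code
# with the package.

# Smith-Waterman local alignment score, Gotoh affine-gap dynamic program.
# A gap of length k costs gap_open + k * gap_extend.
sw_score_oracle <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in A (move along B)
  F_ <- matrix(NEG, n + 1, m + 1) # gap in B
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F_[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F_[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]], E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

sw_similarity_oracle <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  sw_score_oracle(a, b, sub, gap_open, gap_extend) /
    sqrt(sw_score_oracle(a, a, sub, gap_open, gap_extend) *
         sw_score_oracle(b, b, sub, gap_open, gap_extend))
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# AUROC by exhaustive positive/negative pair counting, ties 0.5.
auroc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# AUPR by explicit enumeration of the precision-recall step curve at every
# distinct score threshold.
aupr_step_oracle <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Activity-order concordance by literal pairwise enumeration: for each
# column, every pair of rows with observed values is compared against the
# ordering given by row sums over the remaining columns; ties count 0.5.
aoie_enumeration_oracle <- function(m) {
  col_scores <- c()
  for (j in seq_len(ncol(m))) {
    global <- rowSums(m[, -j, drop = FALSE], na.rm = TRUE)
    idx <- which(!is.na(m[, j]))
    if (length(idx) < 2) next
    num <- 0
    den <- 0
    for (a in idx) {
      for (b in idx) {
        if (a >= b) next
        den <- den + 1
        dv <- m[a, j] - m[b, j]
        dg <- global[a] - global[b]
        if (dv == 0 || dg == 0) {
          num <- num + 0.5
        } else if (sign(dv) == sign(dg)) {
          num <- num + 1
        }
      }
    }
    col_scores <- c(col_scores, num / den)
  }
  mean(col_scores)
}

# Small synthetic-free toy dataset used across io/evaluation tests.
toy_dataset <- function() {
  activity_dataset(
    enzymes = data.frame(
      enzyme_id = c("e1", "e2", "e3"),
      sequence = c("MKTAYIAKQR", "MKTAYIAKQL", "GGGSSSTTTP")),
    chemicals = data.frame(
      chemical_id = c("c1", "c2"),
      smiles = c("CCO", "CC(=O)O")),
    activity = matrix(c(0.2, 5.0, NA, 0.0, 0.1, 3.0), nrow = 3, byrow = TRUE),
    metadata = dataset_metadata(name = "toy", activity_threshold = 0.5))
}
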