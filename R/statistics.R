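#' Activity ratio of an activity matrix
#'
#' For binary data this is the fraction of assayed pairs that are active;
#' for continuous data it is the mean activity of the enzyme family over
#' the chemical library. Both cases reduce to the mean of the non-missing
#' cells.
#'
#' @param activity_matrix numeric matrix, `NA` = missing.
#' @return fraction (binary) or mean activity (continuous).
#' @export
activity_ratio <- function(activity_matrix) {
  v <- activity_matrix[!is.na(activity_matrix)]
  if (length(v) == 0L) {
    stop_eciml("eciml_undefined_statistic", "all activity cells are missing")
  }
  mean(v)
}

# Pairwise-concordance fraction of one column against a global ordering.
# Ties on either side contribute 0.5; returns NA when no pair has both
# values observed.
column_concordance <- function(column, global) {
  idx <- which(!is.na(column))
  if (length(idx) < 2L) return(NA_real_)
  dv <- sign(outer(column[idx], column[idx], "-"))
  dg <- sign(outer(global[idx], global[idx], "-"))
  up <- upper.tri(dv)
  dv <- dv[up]; dg <- dg[up]
  tie <- dv == 0 | dg == 0
  mean(ifelse(tie, 0.5, dv == dg))
}

#' Activity Order Index at the Enzyme axis (AOIE)
#'
#' Measures how consistently the enzymes are ordered by their activity on
#' each individual chemical, relative to the global enzyme ordering given
#' by row sums over the non-missing cells of all other chemicals (the
#' focal chemical is excluded from the global profile so that its own
#' values cannot bias the comparison). For each chemical, all enzyme
#' pairs with observed values are classified as concordant or discordant
#' against the global order (ties count 0.5); the per-chemical
#' concordance fractions are averaged unweighted. The index lies in
#' \[0, 1\]: 0.5 in expectation for i.i.d. random activity data, 1 when
#' every chemical induces the same enzyme ordering (a chemically
#' unspecific family).
#'
#' @param activity_matrix numeric matrix (enzymes x chemicals), `NA` allowed.
#' @return score in \[0, 1\].
#' @export
aoie <- function(activity_matrix) {
  m <- as.matrix(activity_matrix)
  if (nrow(m) < 2L) {
    stop_eciml("eciml_undefined_statistic", "AOIE needs at least 2 enzymes")
  }
  if (ncol(m) < 1L) {
    stop_eciml("eciml_undefined_statistic", "AOIE needs at least 1 chemical")
  }
  per_col <- vapply(seq_len(ncol(m)), function(j) {
    global <- rowSums(m[, -j, drop = FALSE], na.rm = TRUE)
    column_concordance(m[, j], global)
  }, numeric(1))
  per_col <- per_col[!is.na(per_col)]
  if (length(per_col) == 0L) {
    stop_eciml("eciml_undefined_statistic", "no chemical has two observed enzyme values")
  }
  mean(per_col)
}

#' Activity Order Index at the Chemical axis (AOIC)
#'
#' The mirror image of [aoie()]: per-enzyme chemical orderings are
#' compared with the global chemical ordering given by column sums over
#' the other enzymes. 0.5 in expectation for random data, 1 for a
#' chemical library that is not enzyme-specific at all (every enzyme
#' ranks the chemicals identically).
#'
#' @inheritParams aoie
#' @return score in \[0, 1\].
#' @export
aoic <- function(activity_matrix) {
  m <- as.matrix(activity_matrix)
  if (ncol(m) < 2L) {
    stop_eciml("eciml_undefined_statistic", "AOIC needs at least 2 chemicals")
  }
  aoie(t(m))
}

#' Mean top-k similarity of a similarity matrix
#'
#' For each object, the k largest off-diagonal similarities are averaged
#' (all available neighbours if fewer than k exist); the per-object means
#' are then averaged over all objects.
#'
#' @param similarity_matrix square symmetric similarity matrix.
#' @param k neighbourhood size (default 5).
#' @return grand mean of per-object top-k similarities.
#' @export
topk_mean_similarity <- function(similarity_matrix, k = 5) {
  s <- as.matrix(similarity_matrix)
  n <- nrow(s)
  if (n != ncol(s)) stop_eciml("eciml_validation_error", "similarity matrix must be square")
  if (n < 2L) {
    stop_eciml("eciml_undefined_statistic", "top-k similarity needs at least 2 objects")
  }
  per_obj <- vapply(seq_len(n), function(i) {
    vals <- s[i, -i]
    mean(sort(vals, decreasing = TRUE)[seq_len(min(k, length(vals)))])
  }, numeric(1))
  mean(per_obj)
}

#' Normalized Smith-Waterman sequence similarity
#'
#' Computes the optimal local-alignment score SW(a, b) under a substitution
#' matrix with affine gaps, normalized by the geometric mean of the
#' self-alignment scores: `SW(a,b) / sqrt(SW(a,a) * SW(b,b))`. The result
#' lies in (0, 1], equals 1 for identical sequences and is symmetric.
#' A gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param scoring list with elements `matrix` (name of a substitution
#'   matrix, default `"BLOSUM62"`), `gap_open` (default 11) and
#'   `gap_extend` (default 1).
#' @return similarity fraction in (0, 1].
#' @export
local_alignment_similarity <- function(seq_a, seq_b, scoring = sw_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop_eciml("eciml_domain_error", "sequences must be non-empty")
  }
  sub <- get_substitution_matrix(scoring$matrix)
  sw <- function(x, y) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y), type = "local",
      substitutionMatrix = sub, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
  }
  sw(seq_a, seq_b) / sqrt(sw(seq_a, seq_a) * sw(seq_b, seq_b))
}

#' @rdname local_alignment_similarity
#' @export
sw_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

get_substitution_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Pairwise protein similarity matrix
#'
#' All-vs-all [local_alignment_similarity()] over a set of sequences.
#'
#' @param sequences character vector of amino-acid strings (names become
#'   dimnames).
#' @inheritParams local_alignment_similarity
#' @return symmetric matrix with unit diagonal.
#' @export
protein_similarity_matrix <- function(sequences, scoring = sw_scoring()) {
  validate_sequences(sequences)
  n <- length(sequences)
  sub <- get_substitution_matrix(scoring$matrix)
  set <- Biostrings::AAStringSet(sequences)
  score_many <- function(pat, subj) {
    Biostrings::pairwiseAlignment(pat, subj, type = "local",
      substitutionMatrix = sub, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
  }
  self <- vapply(seq_len(n), function(i) score_many(set[i], set[[i]]), numeric(1))
  s <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      sc <- score_many(set[(i + 1L):n], set[[i]])
      s[i, (i + 1L):n] <- s[(i + 1L):n, i] <- sc / sqrt(self[(i + 1L):n] * self[i])
    }
  }
  dimnames(s) <- list(names(sequences), names(sequences))
  s
}

#' Pairwise chemical similarity matrix
#'
#' All-vs-all Tanimoto similarity of 2048-bit Morgan fingerprints
#' (see [morgan_tanimoto_similarity()]).
#'
#' @param smiles character vector of SMILES (names become dimnames).
#' @param bits,radius fingerprint parameters.
#' @return symmetric matrix with unit diagonal.
#' @export
chemical_similarity_matrix <- function(smiles, bits = 2048L, radius = 2L) {
  fps <- morgan_fingerprints(smiles, bits = bits, radius = radius)
  n <- nrow(fps)
  s <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s[i, j] <- s[j, i] <- tanimoto_bits(fps[i, ], fps[j, ])
      }
    }
  }
  dimnames(s) <- list(names(smiles), names(smiles))
  s
}

#' Dataset characterization statistics
#'
#' Computes the seven indicators that characterize an activity dataset for
#' a given evaluation scenario: numbers of enzymes and chemicals (after the
#' scenario's imbalance filter), activity ratio, AOIE, AOIC, and mean top-k
#' protein and chemical similarities. The new-enzyme scenario (`"LPOT"`)
#' filters chemicals and the new-chemical scenario (`"LCOT"`) filters
#' enzymes, so the respective counts can be smaller than the raw dataset;
#' `"LOOT"` applies no filter.
#'
#' @param dataset an [activity_dataset()].
#' @param scenario `"LOOT"`, `"LPOT"` or `"LCOT"`.
#' @param k top-k neighbourhood size (default 5).
#' @param include_similarity compute the (quadratic-cost) similarity
#'   indicators; set `FALSE` to skip them.
#' @return list of class `dataset_statistics`.
#' @export
compute_statistics <- function(dataset, scenario = c("LOOT", "LPOT", "LCOT"),
                               k = 5, include_similarity = TRUE) {
  stopifnot(inherits(dataset, "activity_dataset"))
  scenario <- match.arg(scenario)
  bm <- binary_matrix_of(dataset)
  keep <- filter_for_scenario(bm, scenario)
  ds <- subset_dataset(dataset, keep$retained_enzymes, keep$retained_chemicals)

  top5p <- top5c <- NA_real_
  if (include_similarity) {
    seqs <- stats::setNames(ds$enzymes$sequence, ds$enzymes$enzyme_id)
    top5p <- topk_mean_similarity(protein_similarity_matrix(seqs), k = k)
    if (!anyNA(ds$chemicals$smiles)) {
      smi <- stats::setNames(ds$chemicals$smiles, ds$chemicals$chemical_id)
      top5c <- topk_mean_similarity(chemical_similarity_matrix(smi), k = k)
    }
  }
  structure(
    list(scenario = scenario,
         n_enzymes = nrow(ds$enzymes),
         n_chemicals = nrow(ds$chemicals),
         activity_ratio = activity_ratio(ds$activity),
         aoie = aoie(ds$activity),
         aoic = aoic(ds$activity),
         top5_protein_similarity = top5p,
         top5_chemical_similarity = top5c),
    class = "dataset_statistics"
  )
}

#' @export
print.dataset_statistics <- function(x, ...) {
  cat(sprintf("<dataset_statistics> scenario %s\n", x$scenario))
  for (f in setdiff(names(x), "scenario")) {
    cat(sprintf("  %-26s %s\n", f, format(x[[f]], digits = 4)))
  }
  invisible(x)
}

# Binary view of a dataset's activity matrix: as-is if already binary,
# otherwise thresholded at the metadata threshold.
binary_matrix_of <- function(dataset) {
  if (dataset$metadata$activity_scale == "binary" || is_binary_matrix(dataset$activity)) {
    return(dataset$activity)
  }
  m <- dataset$activity
  m[!is.na(m)] <- as.numeric(m[!is.na(m)] > dataset$metadata$activity_threshold)
  m
}

subset_dataset <- function(dataset, enzyme_ids, chemical_ids) {
  dataset$enzymes <- dataset$enzymes[match(enzyme_ids, dataset$enzymes$enzyme_id), , drop = FALSE]
  dataset$chemicals <- dataset$chemicals[match(chemical_ids, dataset$chemicals$chemical_id), , drop = FALSE]
  rownames(dataset$enzymes) <- rownames(dataset$chemicals) <- NULL
  dataset$activity <- dataset$activity[enzyme_ids, chemical_ids, drop = FALSE]
  dataset
}
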