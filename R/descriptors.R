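#' Descriptor tables
#'
#' A `descriptor_table` maps object ids (enzymes or chemicals) to
#' fixed-length numeric vectors, and records the descriptor name plus its
#' randomization provenance: `"regular"` (as computed), `"shuffled"`
#' (computed from residue-shuffled sequences) or `"permuted"` (rows
#' reassigned to ids by a random bijection).
#'
#' @param object_ids character vector of ids.
#' @param vectors numeric matrix, one row per id.
#' @param descriptor_name label.
#' @param provenance `"regular"`, `"shuffled"` or `"permuted"`.
#' @param seed RNG seed used for shuffling/permutation (required then).
#' @return object of class `descriptor_table`.
#' @export
descriptor_table <- function(object_ids, vectors, descriptor_name,
                             provenance = c("regular", "shuffled", "permuted"),
                             seed = NULL) {
  provenance <- match.arg(provenance)
  vectors <- as.matrix(vectors)
  if (length(object_ids) != nrow(vectors)) {
    stop_eciml("eciml_validation_error", "one descriptor row per object id required")
  }
  if (anyDuplicated(object_ids)) {
    stop_eciml("eciml_validation_error", "duplicate object ids in descriptor table")
  }
  if (provenance != "regular" && is.null(seed)) {
    stop_eciml("eciml_validation_error",
               "shuffled/permuted tables must record their seed")
  }
  rownames(vectors) <- object_ids
  structure(
    list(object_ids = as.character(object_ids), vectors = vectors,
         descriptor_name = descriptor_name, provenance = provenance,
         seed = seed),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table> %s: %d objects x %d dims (%s%s)\n",
              x$descriptor_name, nrow(x$vectors), ncol(x$vectors), x$provenance,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' Descriptor specification
#'
#' @param kind one of `"aac"`, `"gaac"`, `"gdpc"`, `"composition50"`
#'   (sequence descriptors), `"chem_fingerprint"`, `"chem_physchem"`
#'   (chemical descriptors) or `"external"`.
#' @param ... parameters: `bits`/`radius` for fingerprints, `path` (CSV,
#'   first column object_id) or `vectors` (id-rownamed matrix) for
#'   external descriptors.
#' @return object of class `descriptor_spec`.
#' @export
descriptor_spec <- function(kind = c("aac", "gaac", "gdpc", "composition50",
                                     "chem_fingerprint", "chem_physchem",
                                     "external"), ...) {
  kind <- match.arg(kind)
  parameters <- list(...)
  if (kind == "external" && is.null(parameters$path) && is.null(parameters$vectors)) {
    stop_eciml("eciml_validation_error",
               "external descriptor spec requires `path` or `vectors`")
  }
  structure(list(kind = kind, parameters = parameters), class = "descriptor_spec")
}

clean_sequence <- function(sequence, drop_x = TRUE, min_len = 1L) {
  chars <- strsplit(sequence, "")[[1]]
  if (drop_x) chars <- chars[chars != "X"]
  if (length(chars) < min_len) {
    stop_eciml("eciml_degenerate_sequence",
               "sequence has too few standard residues for this descriptor")
  }
  chars
}

#' Amino acid composition (AAC)
#'
#' Fraction of each of the 20 standard amino acids in the sequence, in
#' fixed alphabetical order `ACDEFGHIKLMNPQRSTVWY`. `X` residues are
#' excluded from numerator and denominator. Components sum to 1.
#'
#' @param sequence amino-acid string.
#' @return named numeric vector of length 20.
#' @export
aac_descriptor <- function(sequence) {
  chars <- clean_sequence(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(chars), paste0("AAC.", AA_ALPHABET))
}

group_of <- function(chars) {
  lookup <- stats::setNames(
    rep(names(AA_GROUPS), lengths(AA_GROUPS)), unlist(AA_GROUPS))
  lookup[chars]
}

#' Grouped amino acid composition (GAAC)
#'
#' Composition over five physicochemical residue groups: aliphatic
#' (GAVLMI), aromatic (FYW), positively charged (KRH), negatively charged
#' (DE) and uncharged (STCPNQ). Components sum to 1.
#'
#' @inheritParams aac_descriptor
#' @return named numeric vector of length 5.
#' @export
gaac_descriptor <- function(sequence) {
  chars <- clean_sequence(sequence)
  groups <- factor(group_of(chars), levels = names(AA_GROUPS))
  counts <- table(groups)
  stats::setNames(as.numeric(counts) / length(chars),
                  paste0("GAAC.", names(AA_GROUPS)))
}

#' Grouped dipeptide composition (GDPC)
#'
#' Frequency of each ordered pair of the five residue groups among the
#' adjacent dipeptides of the sequence (`X` residues are dropped before
#' forming dipeptides). Components sum to 1; requires at least two
#' standard residues.
#'
#' @inheritParams aac_descriptor
#' @return named numeric vector of length 25.
#' @export
gdpc_descriptor <- function(sequence) {
  chars <- clean_sequence(sequence, min_len = 2L)
  g <- group_of(chars)
  lev <- names(AA_GROUPS)
  pair_names <- as.vector(t(outer(lev, lev, paste, sep = ".")))
  first <- g[-length(g)]
  second <- g[-1]
  pairs <- factor(paste(first, second, sep = "."), levels = pair_names)
  counts <- table(pairs)
  stats::setNames(as.numeric(counts) / (length(chars) - 1L),
                  paste0("GDPC.", pair_names))
}

load_external_vectors <- function(parameters, ids, axis) {
  if (!is.null(parameters$vectors)) {
    v <- as.matrix(parameters$vectors)
  } else {
    df <- utils::read.csv(parameters$path, check.names = FALSE)
    v <- as.matrix(df[, -1, drop = FALSE])
    rownames(v) <- as.character(df[[1]])
  }
  missing_ids <- setdiff(ids, rownames(v))
  if (length(missing_ids) > 0L) {
    stop_eciml("eciml_alignment_error", sprintf(
      "external %s descriptor is missing id(s): %s",
      axis, paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  v[ids, , drop = FALSE]
}

#' Build a sequence descriptor table
#'
#' Computes per-enzyme descriptor vectors: `"aac"` (20 dims), `"gaac"`
#' (5), `"gdpc"` (25), their concatenation `"composition50"` (50), or an
#' `"external"` table (pre-computed embeddings) aligned to the given
#' enzyme order.
#'
#' @param sequences named character vector (names = enzyme ids).
#' @param spec a [descriptor_spec()].
#' @return a [descriptor_table()].
#' @export
build_sequence_table <- function(sequences, spec = descriptor_spec("composition50")) {
  stopifnot(inherits(spec, "descriptor_spec"))
  ids <- names(sequences) %||% paste0("enzyme", seq_along(sequences))
  if (spec$kind == "external") {
    v <- load_external_vectors(spec$parameters, ids, "enzyme")
    return(descriptor_table(ids, v, "external"))
  }
  validate_sequences(sequences)
  fun <- switch(spec$kind,
    aac = aac_descriptor,
    gaac = gaac_descriptor,
    gdpc = gdpc_descriptor,
    composition50 = function(s) c(aac_descriptor(s), gaac_descriptor(s), gdpc_descriptor(s)),
    stop_eciml("eciml_validation_error",
               sprintf("'%s' is not a sequence descriptor kind", spec$kind)))
  v <- t(vapply(sequences, fun, fun(sequences[[1]])))
  descriptor_table(ids, v, spec$kind)
}

# Fixed list of 2D physicochemical properties computed for every chemical.
physchem_descriptor <- function(smiles, id = smiles) {
  g <- parse_smiles_graph(smiles, id)
  p <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity))
  n_bonds <- nrow(g$bonds)
  ring_flags <- ring_bond_flags(g)
  n_rings <- n_bonds - g$n + 1L  # cyclomatic number of a connected graph
  degree <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = g$n)
  rotatable <- if (n_bonds > 0L) {
    sum(g$bonds[, 3] == 1 & !ring_flags &
          degree[g$bonds[, 1]] > 1 & degree[g$bonds[, 2]] > 1)
  } else 0L
  c(mw = as.numeric(p$MW), logp = as.numeric(p$logP), tpsa = as.numeric(p$TPSA),
    hbd = as.numeric(p$HBD), hba = as.numeric(p$HBA1),
    rings = max(n_rings, 0L), rotatable_bonds = rotatable, heavy_atoms = g$n)
}

#' Build a chemical descriptor table
#'
#' `"chem_fingerprint"` yields 2048-bit Morgan fingerprints as 0/1
#' vectors; `"chem_physchem"` a fixed list of 2D properties (molecular
#' weight, logP, TPSA, H-bond donors/acceptors, ring count, rotatable
#' bonds, heavy atoms); `"external"` loads pre-computed vectors aligned
#' to the chemical order.
#'
#' @param smiles named character vector of SMILES (names = chemical ids);
#'   may be `NULL` for external descriptors given ids via `object_ids`.
#' @param spec a [descriptor_spec()].
#' @param object_ids ids to align an external table to (defaults to
#'   `names(smiles)`).
#' @return a [descriptor_table()].
#' @export
build_chemical_table <- function(smiles, spec = descriptor_spec("chem_fingerprint"),
                                 object_ids = names(smiles)) {
  stopifnot(inherits(spec, "descriptor_spec"))
  if (spec$kind == "external") {
    if (is.null(object_ids)) {
      stop_eciml("eciml_validation_error", "external chemical table needs object ids")
    }
    v <- load_external_vectors(spec$parameters, object_ids, "chemical")
    return(descriptor_table(object_ids, v, "external"))
  }
  ids <- object_ids %||% paste0("chem", seq_along(smiles))
  if (spec$kind == "chem_fingerprint") {
    bits <- spec$parameters$bits %||% 2048L
    radius <- spec$parameters$radius %||% 2L
    v <- morgan_fingerprints(stats::setNames(smiles, ids), bits = bits, radius = radius)
    return(descriptor_table(ids, v, sprintf("morgan%d_%d", radius * 2L, bits)))
  }
  if (spec$kind == "chem_physchem") {
    v <- t(vapply(seq_along(smiles),
                  function(i) physchem_descriptor(smiles[[i]], ids[i]),
                  numeric(8)))
    return(descriptor_table(ids, v, "physchem2d"))
  }
  stop_eciml("eciml_validation_error",
             sprintf("'%s' is not a chemical descriptor kind", spec$kind))
}

#' Shuffle residues within each sequence
#'
#' The shuffle ablation strategy: every sequence is independently
#' rearranged by a uniformly random permutation of its residues, which
#' destroys order information while preserving each sequence's length and
#' residue composition (so composition descriptors are unchanged).
#'
#' @param sequences named character vector.
#' @param seed RNG seed; the result is a pure function of
#'   `(sequences, seed)`.
#' @return shuffled sequences, same names and lengths.
#' @export
shuffle_sequences <- function(sequences, seed) {
  with_seed(seed, {
    out <- vapply(sequences, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1))
    names(out) <- names(sequences)
    out
  })
}

#' Permute a descriptor table
#'
#' The permutation ablation strategy: descriptor rows are reassigned to
#' object ids by one uniformly random bijection drawn from `seed`. The
#' multiset of vectors is preserved, so a model can still memorize which
#' objects were in training, but the descriptors carry no transferable
#' information about the objects.
#'
#' @param table a [descriptor_table()].
#' @param seed RNG seed.
#' @return a [descriptor_table()] with `provenance = "permuted"`.
#' @export
permute_table <- function(table, seed) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$vectors)
  perm <- with_seed(seed, sample.int(n))
  descriptor_table(table$object_ids, table$vectors[perm, , drop = FALSE],
                   table$descriptor_name, provenance = "permuted", seed = seed)
}

#' Concatenate enzyme and chemical descriptors per pair
#'
#' Builds the model input matrix: one row per (enzyme, chemical) pair,
#' the enzyme descriptor block followed by the chemical descriptor block.
#'
#' @param enzyme_table,chemical_table [descriptor_table()]s.
#' @param pairs data.frame with columns `enzyme_id`, `chemical_id`.
#' @return numeric matrix with `nrow(pairs)` rows.
#' @export
concat_pair_features <- function(enzyme_table, chemical_table, pairs) {
  stopifnot(inherits(enzyme_table, "descriptor_table"),
            inherits(chemical_table, "descriptor_table"))
  ei <- match(pairs$enzyme_id, enzyme_table$object_ids)
  ci <- match(pairs$chemical_id, chemical_table$object_ids)
  if (anyNA(ei) || anyNA(ci)) {
    bad <- c(pairs$enzyme_id[is.na(ei)], pairs$chemical_id[is.na(ci)])
    stop_eciml("eciml_lookup_error", sprintf(
      "unknown id(s) in pair list: %s", paste(utils::head(bad, 5), collapse = ", ")))
  }
  e_cols <- ncol(enzyme_table$vectors)
  c_cols <- ncol(chemical_table$vectors)
  out <- matrix(numeric(0), nrow = nrow(pairs), ncol = e_cols + c_cols)
  if (nrow(pairs) > 0L) {
    out <- cbind(enzyme_table$vectors[ei, , drop = FALSE],
                 chemical_table$vectors[ci, , drop = FALSE])
  }
  colnames(out) <- c(paste0("E.", colnames(enzyme_table$vectors) %||% seq_len(e_cols)),
                     paste0("C.", colnames(chemical_table$vectors) %||% seq_len(c_cols)))
  rownames(out) <- NULL
  out
}
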