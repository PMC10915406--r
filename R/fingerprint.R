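# Circular (Morgan / ECFP-style) fingerprints over the molecular graph
# parsed from SMILES by ChemmineR/OpenBabel. Radius-2, 2048-bit folding by
# default. Atom invariants: element, heavy-atom degree, total bond order,
# ring membership and, when the converted structure records it, tetrahedral
# stereo parity.

# Deterministic 31-bit polynomial hash of an integer vector.
hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 1000003 + (v %% 2147483647)) %% 2147483647
  as.integer(h)
}

ELEMENT_CODES <- c(C = 6, N = 7, O = 8, S = 16, P = 15, F = 9, Cl = 17,
                   Br = 35, I = 53, B = 5, Si = 14, Se = 34, H = 1)

# Parse one SMILES into an atom/bond graph (heavy atoms only).
parse_smiles_graph <- function(smiles, id = smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) {
      stop_eciml("eciml_parse_error",
                 sprintf("cannot parse SMILES for '%s': %s", id, conditionMessage(e)))
    })
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  if (nrow(ab) == 0L) {
    stop_eciml("eciml_parse_error", sprintf("SMILES for '%s' yields no atoms", id))
  }
  elements <- sub("_.*$", "", rownames(ab))
  stereo <- if ("C7" %in% colnames(ab)) {
    p <- ab[, "C7"]
    ifelse(p %in% c(1, 2), p, 0)
  } else rep(0, nrow(ab))
  # bond-free molecules yield a placeholder block without an order column
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || !all(c("C1", "C2", "C3") %in% colnames(bb))) {
    matrix(numeric(0), ncol = 3)
  } else {
    b <- cbind(bb[, "C1"], bb[, "C2"], bb[, "C3"])
    b[b[, 1] >= 1 & b[, 2] >= 1, , drop = FALSE]
  }
  list(elements = elements, stereo = as.numeric(stereo), bonds = bonds,
       n = length(elements))
}

# Bonds that lie on a cycle: removing the bond leaves its endpoints connected.
ring_bond_flags <- function(graph) {
  nb <- graph$bonds
  if (nrow(nb) == 0L) return(logical(0))
  adj <- lapply(seq_len(graph$n), function(i) integer(0))
  for (b in seq_len(nrow(nb))) {
    a1 <- nb[b, 1]; a2 <- nb[b, 2]
    adj[[a1]] <- c(adj[[a1]], b); adj[[a2]] <- c(adj[[a2]], b)
  }
  vapply(seq_len(nrow(nb)), function(b) {
    a1 <- nb[b, 1]; a2 <- nb[b, 2]
    seen <- rep(FALSE, graph$n); seen[a1] <- TRUE
    queue <- a1
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (eb in adj[[v]]) {
        if (eb == b) next
        w <- if (nb[eb, 1] == v) nb[eb, 2] else nb[eb, 1]
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[a2]
  }, logical(1))
}

#' Morgan fingerprint of a molecule
#'
#' Computes a circular substructure fingerprint: atom environments of
#' radius 0..`radius` are hashed and folded onto a fixed-length bit
#' vector (2048 bits by default, the common setting for Tanimoto
#' similarity profiling). Tetrahedral stereo parity enters the atom
#' invariant when the parsed structure records it.
#'
#' @param smiles a single SMILES string.
#' @param bits fingerprint length (default 2048).
#' @param radius neighbourhood radius (default 2, ECFP4-like).
#' @param id label used in parse-error messages.
#' @return integer 0/1 vector of length `bits`.
#' @export
morgan_fingerprint <- function(smiles, bits = 2048L, radius = 2L, id = smiles) {
  g <- parse_smiles_graph(smiles, id)
  n <- g$n
  in_ring <- rep(0L, n)
  ring_flags <- ring_bond_flags(g)
  neighbours <- lapply(seq_len(n), function(i) list(idx = integer(0), order = numeric(0)))
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds[b, 1]; a2 <- g$bonds[b, 2]; o <- g$bonds[b, 3]
      neighbours[[a1]]$idx <- c(neighbours[[a1]]$idx, a2)
      neighbours[[a1]]$order <- c(neighbours[[a1]]$order, o)
      neighbours[[a2]]$idx <- c(neighbours[[a2]]$idx, a1)
      neighbours[[a2]]$order <- c(neighbours[[a2]]$order, o)
      if (ring_flags[b]) { in_ring[a1] <- 1L; in_ring[a2] <- 1L }
    }
  }
  elem_code <- ELEMENT_CODES[g$elements]
  elem_code[is.na(elem_code)] <- 99
  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(elem_code[i], length(neighbours[[i]]$idx),
                sum(neighbours[[i]]$order) * 10, in_ring[i], g$stereo[i]))
  }, integer(1))

  all_ids <- inv
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(n), function(i) {
        nb <- neighbours[[i]]
        if (length(nb$idx) == 0L) return(hash_ints(c(r, inv[i])))
        pairs <- cbind(nb$order * 10, inv[nb$idx])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        hash_ints(c(r, inv[i], as.vector(t(pairs))))
      }, integer(1))
      all_ids <- c(all_ids, inv)
    }
  }
  fp <- integer(bits)
  fp[(unique(all_ids) %% bits) + 1L] <- 1L
  fp
}

#' @rdname morgan_fingerprint
#' @param smiles_vec character vector of SMILES; names are used as
#'   chemical ids in error messages and rownames.
#' @export
morgan_fingerprints <- function(smiles_vec, bits = 2048L, radius = 2L) {
  ids <- names(smiles_vec) %||% as.character(smiles_vec)
  m <- t(vapply(seq_along(smiles_vec), function(i) {
    morgan_fingerprint(smiles_vec[[i]], bits = bits, radius = radius, id = ids[i])
  }, integer(bits)))
  rownames(m) <- ids
  m
}

#' Tanimoto similarity of two bit vectors
#'
#' `|A intersect B| / |A union B|` over the on-bits; defined as 1 when both
#' vectors are empty.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto_bits <- function(a, b) {
  union_n <- sum(a | b)
  if (union_n == 0L) return(1)
  sum(a & b) / union_n
}

#' Tanimoto similarity of Morgan fingerprints of two molecules
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @inheritParams morgan_fingerprint
#' @return similarity in \[0, 1\]; 1 for identical molecules.
#' @export
morgan_tanimoto_similarity <- function(smiles_a, smiles_b, bits = 2048L, radius = 2L) {
  tanimoto_bits(morgan_fingerprint(smiles_a, bits, radius),
                morgan_fingerprint(smiles_b, bits, radius))
}
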