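# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Five-class physicochemical grouping of the standard amino acids
# (iFeature convention).
AA_GROUPS <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error constructor so that contract violations are testable.
stop_eciml <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "eciml_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_eciml("eciml_invalid_seed", "`seed` must be a single finite integer")
  }
  as.integer(seed %% .Machine$integer.max)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(assert_seed(seed), expr)
}

validate_sequences <- function(sequences, what = "sequence") {
  if (length(sequences) == 0L) {
    stop_eciml("eciml_validation_error", "no sequences supplied")
  }
  ok_chars <- c(AA_ALPHABET, "X")
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
      stop_eciml("eciml_validation_error",
                 sprintf("%s %d is empty or not a string", what, i))
    }
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(chars), ok_chars)
    if (length(bad) > 0L) {
      stop_eciml("eciml_validation_error",
                 sprintf("%s %d contains invalid residue(s): %s",
                         what, i, paste(bad, collapse = ", ")))
    }
  }
  invisible(TRUE)
}
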