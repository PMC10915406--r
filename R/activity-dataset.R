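#' Activity dataset container
#'
#' An `activity_dataset` bundles the four ingredients every stage of the
#' pipeline consumes: enzyme sequences, chemical structures (SMILES,
#' optional), an enzymes-by-chemicals activity matrix, and metadata.
#' Missing activity cells (`NA`) mark unassayed pairs; they are excluded
#' from statistics, training pairs and metrics, never imputed.
#'
#' @param enzymes data.frame with columns `enzyme_id`, `sequence`.
#' @param chemicals data.frame with columns `chemical_id` and optionally
#'   `smiles` (may be `NA` when chemicals are described by external numeric
#'   features only).
#' @param activity numeric matrix, rows = enzymes, columns = chemicals.
#'   `NA` denotes a missing (unassayed) cell.
#' @param metadata named list; see [dataset_metadata()].
#'
#' @return An object of class `activity_dataset`.
#' @export
activity_dataset <- function(enzymes, chemicals, activity, metadata = dataset_metadata()) {
  enzymes <- as.data.frame(enzymes, stringsAsFactors = FALSE)
  chemicals <- as.data.frame(chemicals, stringsAsFactors = FALSE)
  if (!all(c("enzyme_id", "sequence") %in% names(enzymes))) {
    stop_eciml("eciml_validation_error", "`enzymes` needs columns enzyme_id, sequence")
  }
  if (!"chemical_id" %in% names(chemicals)) {
    stop_eciml("eciml_validation_error", "`chemicals` needs a chemical_id column")
  }
  if (!"smiles" %in% names(chemicals)) chemicals$smiles <- NA_character_
  enzymes$enzyme_id <- as.character(enzymes$enzyme_id)
  chemicals$chemical_id <- as.character(chemicals$chemical_id)

  if (anyDuplicated(enzymes$enzyme_id)) {
    stop_eciml("eciml_validation_error", "duplicate enzyme_id")
  }
  if (anyDuplicated(chemicals$chemical_id)) {
    stop_eciml("eciml_validation_error", "duplicate chemical_id")
  }
  validate_sequences(enzymes$sequence, "enzyme sequence")

  activity <- as.matrix(activity)
  storage.mode(activity) <- "double"
  if (nrow(activity) != nrow(enzymes) || ncol(activity) != nrow(chemicals)) {
    stop_eciml("eciml_validation_error", sprintf(
      "activity matrix is %d x %d but there are %d enzymes and %d chemicals",
      nrow(activity), ncol(activity), nrow(enzymes), nrow(chemicals)))
  }
  dimnames(activity) <- list(enzymes$enzyme_id, chemicals$chemical_id)

  metadata <- validate_metadata(metadata)
  structure(
    list(enzymes = enzymes, chemicals = chemicals,
         activity = activity, metadata = metadata),
    class = "activity_dataset"
  )
}

#' Dataset metadata
#'
#' @param name dataset name.
#' @param substrate_library `"industrial"` (screened against non-natural
#'   substrate libraries) or `"physiological"` (natural metabolites).
#' @param activity_threshold value above which a raw/log activity counts as
#'   active; used by [binarize_activity()] and scenario filtering.
#' @param activity_scale one of `"raw"`, `"log"`, `"binary"`.
#' @return named list of class `dataset_metadata`.
#' @export
dataset_metadata <- function(name = "unnamed",
                             substrate_library = c("industrial", "physiological"),
                             activity_threshold = 0,
                             activity_scale = c("raw", "log", "binary")) {
  structure(
    list(name = name,
         substrate_library = match.arg(substrate_library),
         activity_threshold = activity_threshold,
         activity_scale = match.arg(activity_scale)),
    class = "dataset_metadata"
  )
}

validate_metadata <- function(metadata) {
  md <- unclass(metadata)
  md$name <- as.character(md$name %||% "unnamed")
  md$substrate_library <- match.arg(md$substrate_library %||% "industrial",
                                    c("industrial", "physiological"))
  md$activity_scale <- match.arg(md$activity_scale %||% "raw",
                                 c("raw", "log", "binary"))
  md$activity_threshold <- as.numeric(md$activity_threshold %||% 0)
  if (!is.finite(md$activity_threshold)) {
    stop_eciml("eciml_validation_error", "activity_threshold must be finite")
  }
  class(md) <- "dataset_metadata"
  md
}

#' @export
print.activity_dataset <- function(x, ...) {
  n_cells <- sum(!is.na(x$activity))
  cat(sprintf("<activity_dataset> %s: %d enzymes x %d chemicals, %d assayed pairs (%s scale)\n",
              x$metadata$name, nrow(x$enzymes), nrow(x$chemicals), n_cells,
              x$metadata$activity_scale))
  invisible(x)
}

#' @export
dim.activity_dataset <- function(x) dim(x$activity)

#' Save an activity dataset to a directory
#'
#' Writes the standard four-file layout: `enzymes.fasta`, `chemicals.csv`
#' (columns `chemical_id,smiles`), `activity.csv` (row ids = enzymes,
#' header = chemical ids, empty cell = missing) and `metadata.yaml`.
#'
#' @param dataset an [activity_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "activity_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  seqs <- Biostrings::AAStringSet(dataset$enzymes$sequence)
  names(seqs) <- dataset$enzymes$enzyme_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "enzymes.fasta"))

  utils::write.csv(dataset$chemicals[, c("chemical_id", "smiles")],
                   file.path(dir, "chemicals.csv"), row.names = FALSE, na = "")

  act <- as.data.frame(dataset$activity)
  # full double precision so that save/load round-trips bit-near-exactly
  act[] <- lapply(act, function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE, scientific = FALSE)))
  act <- cbind(enzyme_id = dataset$enzymes$enzyme_id, act)
  utils::write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE, quote = FALSE)

  yaml::write_yaml(unclass(dataset$metadata), file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Load an activity dataset from a directory
#'
#' Reads the layout written by [save_dataset()]. The activity matrix is
#' aligned to the enzyme order of the FASTA and the chemical order of
#' `chemicals.csv`; `""` and `"NA"` cells are treated as missing.
#'
#' @param dir dataset directory.
#' @return An [activity_dataset()].
#' @export
load_dataset <- function(dir) {
  need <- c("enzymes.fasta", "chemicals.csv", "activity.csv", "metadata.yaml")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop_eciml("eciml_load_error", sprintf("missing file: %s", f))
    }
  }
  seqs <- Biostrings::readAAStringSet(file.path(dir, "enzymes.fasta"))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  enzymes <- data.frame(enzyme_id = ids, sequence = as.character(seqs),
                        stringsAsFactors = FALSE, row.names = NULL)

  chemicals <- utils::read.csv(file.path(dir, "chemicals.csv"),
                               colClasses = "character", na.strings = c("", "NA"))
  if (!all(c("chemical_id", "smiles") %in% names(chemicals))) {
    stop_eciml("eciml_load_error", "chemicals.csv must have columns chemical_id,smiles")
  }

  act_raw <- utils::read.csv(file.path(dir, "activity.csv"), check.names = FALSE,
                             colClasses = "character", na.strings = c("", "NA"))
  if (names(act_raw)[1] != "enzyme_id") {
    stop_eciml("eciml_load_error", "activity.csv must start with an enzyme_id column")
  }
  chem_header <- names(act_raw)[-1]
  if (!setequal(chem_header, chemicals$chemical_id) ||
      anyDuplicated(chem_header)) {
    stop_eciml("eciml_consistency_error",
               "activity.csv column ids do not match chemicals.csv")
  }
  if (!setequal(act_raw$enzyme_id, enzymes$enzyme_id) ||
      anyDuplicated(act_raw$enzyme_id)) {
    stop_eciml("eciml_consistency_error",
               "activity.csv row ids do not match enzymes.fasta")
  }
  m <- as.matrix(act_raw[, -1, drop = FALSE])
  m <- apply(m, 2, as.numeric)
  if (nrow(act_raw) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, chem_header))
  rownames(m) <- act_raw$enzyme_id
  m <- m[enzymes$enzyme_id, chemicals$chemical_id, drop = FALSE]

  metadata <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  activity_dataset(enzymes, chemicals, m, metadata)
}

is_binary_matrix <- function(m) {
  v <- m[!is.na(m)]
  length(v) > 0L && all(v %in% c(0, 1))
}

#' Binarize the activity matrix
#'
#' Each non-missing cell becomes 1 if strictly greater than `threshold`,
#' else 0. Missing cells stay missing. The metadata scale is set to
#' `"binary"`. Applying it to an already-binary dataset is a no-op with a
#' warning.
#'
#' @param dataset an [activity_dataset()].
#' @param threshold activity threshold; defaults to the metadata threshold.
#' @return A binarized [activity_dataset()].
#' @export
binarize_activity <- function(dataset, threshold = dataset$metadata$activity_threshold) {
  stopifnot(inherits(dataset, "activity_dataset"))
  if (!is.finite(threshold)) {
    stop_eciml("eciml_validation_error", "threshold must be finite")
  }
  if (dataset$metadata$activity_scale == "binary") {
    warning("dataset is already binary; returning it unchanged")
    return(dataset)
  }
  m <- dataset$activity
  m[!is.na(m)] <- as.numeric(m[!is.na(m)] > threshold)
  dataset$activity <- m
  dataset$metadata$activity_scale <- "binary"
  dataset$metadata$activity_threshold <- 0.5
  dataset
}

#' Log-transform the activity matrix
#'
#' Replaces each non-missing value v by `log10(v + pseudocount)` and flags
#' the scale as `"log"`. Negative values are a domain error.
#'
#' @param dataset an [activity_dataset()] on the raw scale.
#' @param pseudocount nonnegative offset added before the log (default 1).
#' @return The transformed [activity_dataset()].
#' @export
log_transform_activity <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "activity_dataset"))
  m <- dataset$activity
  v <- m[!is.na(m)]
  if (any(v < 0)) {
    stop_eciml("eciml_domain_error", "negative activity values cannot be log-transformed")
  }
  m[!is.na(m)] <- log10(v + pseudocount)
  dataset$activity <- m
  dataset$metadata$activity_scale <- "log"
  dataset$metadata$activity_threshold <-
    log10(dataset$metadata$activity_threshold + pseudocount)
  dataset
}
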