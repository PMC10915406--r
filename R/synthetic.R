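#' Synthetic dataset configuration
#'
#' Parameters of the synthetic activity-dataset generator. The generator
#' emulates the structure the analysis assumes in real enzyme-family
#' screens: enzyme families with controllable within-family sequence
#' similarity, chemical classes, and a block-structured activity matrix
#' with a controllable activity ratio and noise level.
#'
#' The latent activity of enzyme e and chemical c is
#' `A(e,c) = B[family(e), class(c)] + alpha*u_e + beta*v_c + sigma*eps(e,c)`
#' with `u`, `v`, `eps` standard normal; the binary matrix marks the
#' top `target_activity_ratio` fraction of cells active.
#'
#' @param n_families number of enzyme families F.
#' @param enzymes_per_family family size.
#' @param sequence_length residues per sequence.
#' @param mutation_rate per-position probability that a family member
#'   mutates away from the family template (controls within-family
#'   similarity).
#' @param n_classes number of chemical classes G.
#' @param chemicals_per_class class size.
#' @param chemical_dim dimensionality of numeric chemical features.
#' @param chemical_mode `"numeric"` (Gaussian class centroids; default, no
#'   cheminformatics needed) or `"smiles"` (draws from the packaged
#'   synthetic small-molecule library).
#' @param chemical_noise_sd isotropic noise around class centroids
#'   (numeric mode).
#' @param block_affinity F x G matrix B of family-class affinities;
#'   default `diag(3, F, G)`: each family strongly prefers one class.
#' @param enzyme_effect_sd,chemical_effect_sd,noise_sd the alpha, beta and
#'   sigma scales above.
#' @param target_activity_ratio fraction of active cells after
#'   binarization.
#' @param seed RNG seed; all generation is a pure function of
#'   (config, seed).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 4L,
                             enzymes_per_family = 10L,
                             sequence_length = 200L,
                             mutation_rate = 0.05,
                             n_classes = 4L,
                             chemicals_per_class = 5L,
                             chemical_dim = 8L,
                             chemical_mode = c("numeric", "smiles"),
                             chemical_noise_sd = 0.5,
                             block_affinity = NULL,
                             enzyme_effect_sd = 0.3,
                             chemical_effect_sd = 0.3,
                             noise_sd = 0.3,
                             target_activity_ratio = 0.3,
                             seed = 1L) {
  chemical_mode <- match.arg(chemical_mode)
  if (is.null(block_affinity)) {
    block_affinity <- diag(3, n_families, n_classes)
  }
  block_affinity <- as.matrix(block_affinity)
  stopifnot(n_families >= 1, enzymes_per_family >= 1, sequence_length >= 1,
            n_classes >= 1, chemicals_per_class >= 1,
            nrow(block_affinity) == n_families,
            ncol(block_affinity) == n_classes,
            mutation_rate >= 0, mutation_rate <= 1,
            target_activity_ratio >= 0, target_activity_ratio <= 1,
            enzyme_effect_sd >= 0, chemical_effect_sd >= 0, noise_sd >= 0)
  structure(
    list(n_families = as.integer(n_families),
         enzymes_per_family = as.integer(enzymes_per_family),
         sequence_length = as.integer(sequence_length),
         mutation_rate = mutation_rate,
         n_classes = as.integer(n_classes),
         chemicals_per_class = as.integer(chemicals_per_class),
         chemical_dim = as.integer(chemical_dim),
         chemical_mode = chemical_mode,
         chemical_noise_sd = chemical_noise_sd,
         block_affinity = block_affinity,
         enzyme_effect_sd = enzyme_effect_sd,
         chemical_effect_sd = chemical_effect_sd,
         noise_sd = noise_sd,
         target_activity_ratio = target_activity_ratio,
         seed = assert_seed(seed)),
    class = "synthetic_config"
  )
}

#' Generate family-structured enzyme sequences
#'
#' Draws one uniformly random template per family; each member copies the
#' template and mutates every position independently with probability
#' `mutation_rate` to a uniformly random different residue.
#'
#' @param config a [synthetic_config()].
#' @return list with `sequences` (named character vector, ids
#'   `enz001`, ...) and `family` (named family labels `F1`, ...).
#' @export
generate_sequences <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 11L, {
    n <- config$n_families * config$enzymes_per_family
    ids <- sprintf("enz%03d", seq_len(n))
    family <- rep(sprintf("F%d", seq_len(config$n_families)),
                  each = config$enzymes_per_family)
    seqs <- character(n)
    k <- 0L
    for (f in seq_len(config$n_families)) {
      template <- sample(AA_ALPHABET, config$sequence_length, replace = TRUE)
      for (m in seq_len(config$enzymes_per_family)) {
        k <- k + 1L
        member <- template
        hit <- stats::runif(config$sequence_length) < config$mutation_rate
        if (any(hit)) {
          member[hit] <- vapply(member[hit], function(res) {
            sample(setdiff(AA_ALPHABET, res), 1L)
          }, character(1))
        }
        seqs[k] <- paste(member, collapse = "")
      }
    }
    list(sequences = stats::setNames(seqs, ids),
         family = stats::setNames(family, ids))
  })
}

#' Generate class-structured chemicals
#'
#' Numeric mode: per class a random Gaussian centroid in
#' `chemical_dim` dimensions; members are the centroid plus isotropic
#' noise. SMILES mode: members are drawn without replacement from the
#' packaged class-grouped synthetic small-molecule library.
#'
#' @param config a [synthetic_config()].
#' @return list with `chemical_ids`, `class` (named labels `G1`, ...),
#'   and either `features` (numeric matrix) or `smiles`.
#' @export
generate_chemicals <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 23L, {
    n <- config$n_classes * config$chemicals_per_class
    ids <- sprintf("chem%03d", seq_len(n))
    cls <- rep(sprintf("G%d", seq_len(config$n_classes)),
               each = config$chemicals_per_class)
    if (config$chemical_mode == "numeric") {
      features <- matrix(0, n, config$chemical_dim,
                         dimnames = list(ids, paste0("x", seq_len(config$chemical_dim))))
      k <- 0L
      for (g in seq_len(config$n_classes)) {
        centroid <- stats::rnorm(config$chemical_dim, sd = 3)
        for (m in seq_len(config$chemicals_per_class)) {
          k <- k + 1L
          features[k, ] <- centroid +
            stats::rnorm(config$chemical_dim, sd = config$chemical_noise_sd)
        }
      }
      list(chemical_ids = ids, class = stats::setNames(cls, ids),
           features = features, smiles = NULL)
    } else {
      lib <- synthetic_chemical_library()
      classes <- unique(lib$class)
      if (config$n_classes > length(classes)) {
        stop_eciml("eciml_capacity_error", sprintf(
          "the packaged library has %d scaffold classes, %d requested",
          length(classes), config$n_classes))
      }
      smiles <- character(0)
      for (g in seq_len(config$n_classes)) {
        pool <- lib[lib$class == classes[g], ]
        if (config$chemicals_per_class > nrow(pool)) {
          stop_eciml("eciml_capacity_error", sprintf(
            "class '%s' has %d molecules, %d requested",
            classes[g], nrow(pool), config$chemicals_per_class))
        }
        smiles <- c(smiles, sample(pool$smiles, config$chemicals_per_class))
      }
      list(chemical_ids = ids, class = stats::setNames(cls, ids),
           features = NULL, smiles = stats::setNames(smiles, ids))
    }
  })
}

#' Packaged synthetic small-molecule library
#'
#' A synthetic, class-grouped list of simple small-molecule SMILES
#' shipped with the package (about 100 molecules in 6 scaffold classes).
#' All entries parse under the fingerprint descriptor.
#'
#' @return data.frame with columns `chemical_id`, `smiles`, `class`.
#' @export
synthetic_chemical_library <- function() {
  path <- system.file("extdata", "synthetic_chemical_library.csv",
                      package = "eciml", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate the block-structured activity matrix
#'
#' Draws the latent activity model described in [synthetic_config()] and
#' binarizes it so that exactly `round(target_activity_ratio * n_cells)`
#' cells are active (quantile thresholding; latent ties are broken by
#' deterministic cell order, with a warning when the latent matrix is
#' degenerate).
#'
#' @param config a [synthetic_config()].
#' @param family named family labels (enzyme id -> `F*`).
#' @param class named class labels (chemical id -> `G*`).
#' @return list with `binary` (0/1 matrix), `latent` (real matrix) and
#'   `threshold`.
#' @export
generate_activity <- function(config, family, class) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 37L, {
    ne <- length(family); nc <- length(class)
    fi <- as.integer(sub("^F", "", family))
    gi <- as.integer(sub("^G", "", class))
    u <- stats::rnorm(ne)
    v <- stats::rnorm(nc)
    eps <- matrix(stats::rnorm(ne * nc), ne, nc)
    latent <- config$block_affinity[fi, gi, drop = FALSE] +
      config$enzyme_effect_sd * outer(u, rep(1, nc)) +
      config$chemical_effect_sd * outer(rep(1, ne), v) +
      config$noise_sd * eps
    dimnames(latent) <- list(names(family), names(class))
    if (max(latent) == min(latent)) {
      warning("degenerate all-equal latent matrix; ties broken by cell order")
    }
    n_active <- round(config$target_activity_ratio * ne * nc)
    ord <- rank(-latent, ties.method = "first")
    binary <- matrix(as.numeric(ord <= n_active), ne, nc,
                     dimnames = dimnames(latent))
    threshold <- if (n_active > 0 && n_active < ne * nc) {
      sort(latent, decreasing = TRUE)[n_active]
    } else NA_real_
    list(binary = binary, latent = latent, threshold = threshold)
  })
}

#' Generate a complete synthetic activity dataset
#'
#' Assembles sequences, chemicals and the binarized activity matrix into
#' a saveable [activity_dataset()], together with the generating ground
#' truth for recovery tests.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (an [activity_dataset()]) and `truth`
#'   (class `synthetic_truth`: `family_of_enzyme`, `class_of_chemical`,
#'   `latent_activity`, `chemical_features` (numeric mode), `config`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  enz <- generate_sequences(config)
  chem <- generate_chemicals(config)
  act <- generate_activity(config, enz$family, chem$class)
  dataset <- activity_dataset(
    enzymes = data.frame(enzyme_id = names(enz$sequences),
                         sequence = unname(enz$sequences)),
    chemicals = data.frame(chemical_id = chem$chemical_ids,
                           smiles = if (is.null(chem$smiles)) NA_character_
                                    else unname(chem$smiles)),
    activity = act$binary,
    metadata = dataset_metadata(
      name = sprintf("synthetic_seed%d", config$seed),
      substrate_library = "industrial",
      activity_threshold = 0.5,
      activity_scale = "binary"))
  truth <- structure(
    list(family_of_enzyme = enz$family,
         class_of_chemical = chem$class,
         latent_activity = act$latent,
         chemical_features = chem$features,
         config = config),
    class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}
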