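#' Generate a synthetic two-class feature set
#'
#' Emulates per-image feature representations (e.g. penultimate-layer network
#' activations) as two isotropic unit-variance Gaussian clouds whose means
#' differ by `separation` along a random unit direction. The Bayes-optimal
#' classification accuracy of this generative model is
#' `pnorm(separation / 2)` and is recorded in the returned object.
#'
#' @param n_per_class Images per class.
#' @param dim Feature dimensionality (e.g. 2048 for typical penultimate
#'   layers).
#' @param separation Non-negative distance between the class means, in units
#'   of the within-class standard deviation.
#' @param seed Integer seed for the feature draws.
#' @param id_prefix Prefix for generated image ids (lets train/test sets be
#'   disjoint by construction).
#' @param direction_seed Seed for the random unit direction separating the
#'   class means. Kept separate from `seed` so a train and a test set drawn
#'   with different `seed`s share the same class axis (the default); pass a
#'   different value to decouple them.
#' @return A `feature_set`: list with `features` (matrix, `2*n_per_class` x
#'   `dim`, rownames = image ids), `image_ids`, `labels` ("A"/"B" per row),
#'   and `bayes_accuracy`.
#' @export
generate_feature_set <- function(n_per_class, dim, separation = 2, seed = 1,
                                 id_prefix = "img", direction_seed = 1) {
  if (dim < 1) stop("`dim` must be >= 1", call. = FALSE)
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  u <- with_seed(direction_seed, {
    v <- stats::rnorm(dim)
    v / sqrt(sum(v^2))
  })
  with_seed(seed, {
    n <- 2L * n_per_class
    x <- matrix(stats::rnorm(n * dim), n, dim)
    labels <- rep(c("A", "B"), each = n_per_class)
    offset <- ifelse(labels == "A", separation / 2, -separation / 2)
    x <- x + outer(offset, u)
    ids <- sprintf("%s_%s_%04d", id_prefix, labels, c(seq_len(n_per_class), seq_len(n_per_class)))
    rownames(x) <- ids
    structure(list(features = x, image_ids = ids, labels = labels,
                   bayes_accuracy = stats::pnorm(separation / 2),
                   params = list(n_per_class = n_per_class, dim = dim,
                                 separation = separation, seed = seed,
                                 direction_seed = direction_seed)),
              class = "feature_set")
  })
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d images x %d features, Bayes accuracy %.3f\n",
              nrow(x$features), ncol(x$features), x$bayes_accuracy))
  invisible(x)
}

#' Write / read a feature set as delimited text
#'
#' Features go to `<path>` as a header-less CSV numeric matrix; labels to
#' `<path>.labels.csv` as a two-column table (`image_id,label`).
#'
#' @param fs A `feature_set`.
#' @param path Output path for the feature matrix.
#' @export
write_feature_set <- function(fs, path) {
  utils::write.table(fs$features, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(data.frame(image_id = fs$image_ids, label = fs$labels),
                   paste0(path, ".labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  x <- as.matrix(utils::read.table(path, sep = ","))
  lab <- utils::read.csv(paste0(path, ".labels.csv"), stringsAsFactors = FALSE)
  if (nrow(x) != nrow(lab)) {
    stop("feature matrix and labels table disagree on row count", call. = FALSE)
  }
  dimnames(x) <- list(lab$image_id, NULL)
  structure(list(features = x, image_ids = lab$image_id, labels = lab$label,
                 bayes_accuracy = NA_real_, params = NULL),
            class = "feature_set")
}
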