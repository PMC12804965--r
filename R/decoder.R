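#' Train a resampled linear readout on feature representations
#'
#' The model-observer protocol: per resample, `n_train_per_class` training
#' images are drawn per class without replacement, features are standardized
#' per dimension using the training draw's statistics only, and a linear
#' support vector machine (L2 regularization, hinge loss; cost `C`) is fit
#' and scored on the held-out test set. Test accuracy is summarized over
#' resamples, and every test image gets a signed distance to the learned
#' hyperplane, oriented so that positive means the image lies on its own
#' category's side (so the fraction of positive margins in a resample equals
#' that resample's accuracy exactly).
#'
#' Margins are in units of the standardized feature space; they are not
#' calibrated across feature scalings.
#'
#' @param train,test `feature_set`s sharing a feature dimension, with
#'   disjoint image ids.
#' @param n_train_per_class Training images drawn per class per resample.
#' @param n_resamples Number of training-image resamples.
#' @param C Regularization cost of the SVM (default 1).
#' @param seed Integer seed.
#' @param margin_mode `"mean"` (default): per-image margin averaged across
#'   all resamples; `"final"`: margins from the last fit only.
#' @return A `decoder_result`: list with `n_train_per_class`,
#'   `accuracy_mean`, `accuracy_sd`, `n_resamples`, `per_image_margin`
#'   (named by test image id), `margins` (test images x resamples),
#'   `accuracies`, `test_ids`, `test_labels`, `C`, `seed`, `margin_mode`.
#' @export
train_readout <- function(train, test, n_train_per_class, n_resamples = 100,
                          C = 1, seed = 1, margin_mode = c("mean", "final")) {
  margin_mode <- match.arg(margin_mode)
  stopifnot(inherits(train, "feature_set"), inherits(test, "feature_set"))
  if (ncol(train$features) != ncol(test$features)) {
    stop("train and test feature dimensions differ", call. = FALSE)
  }
  overlap <- intersect(train$image_ids, test$image_ids)
  if (length(overlap)) {
    stop("train and test share image id(s): ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  classes <- sort(unique(train$labels))
  if (length(classes) != 2L) stop("training set must contain exactly 2 classes", call. = FALSE)
  idx_by_class <- lapply(classes, function(cl) which(train$labels == cl))
  if (any(vapply(idx_by_class, length, 1L) < n_train_per_class)) {
    stop("fewer than `n_train_per_class` training images in a class", call. = FALSE)
  }
  x_test <- test$features
  y_test <- test$labels
  n_test <- nrow(x_test)
  with_seed(seed, {
    margins <- matrix(NA_real_, n_test, n_resamples)
    accuracies <- numeric(n_resamples)
    for (r in seq_len(n_resamples)) {
      tr_idx <- unlist(lapply(idx_by_class, sample, size = n_train_per_class))
      xt <- train$features[tr_idx, , drop = FALSE]
      yt <- factor(train$labels[tr_idx], levels = classes)
      mu <- colMeans(xt)
      sdv <- apply(xt, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xt_std <- sweep(sweep(xt, 2, mu), 2, sdv, "/")
      fit <- e1071::svm(xt_std, yt, kernel = "linear", cost = C, scale = FALSE)
      w <- t(fit$coefs) %*% fit$SV          # weight vector in standardized space
      wn <- sqrt(sum(w^2))
      xs <- sweep(sweep(x_test, 2, mu), 2, sdv, "/")
      f <- drop(xs %*% t(w)) - fit$rho      # libsvm decision value
      pos_class <- fit$levels[1]            # positive decision value => this class
      dist <- f / wn
      oriented <- dist * ifelse(y_test == pos_class, 1, -1)
      margins[, r] <- oriented
      accuracies[r] <- mean(oriented > 0)
    }
    per_image <- if (margin_mode == "mean") rowMeans(margins) else margins[, n_resamples]
    names(per_image) <- test$image_ids
    structure(list(n_train_per_class = n_train_per_class,
                   accuracy_mean = mean(accuracies),
                   accuracy_sd = stats::sd(accuracies),
                   n_resamples = n_resamples,
                   per_image_margin = per_image, margins = margins,
                   accuracies = accuracies, test_ids = test$image_ids,
                   test_labels = y_test, C = C, seed = seed,
                   margin_mode = margin_mode),
              class = "decoder_result")
  })
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("decoder_result: %d train/class, accuracy %.3f +/- %.3f (%d resamples)\n",
              x$n_train_per_class, x$accuracy_mean, x$accuracy_sd, x$n_resamples))
  invisible(x)
}

#' Per-image d-prime-style vector from decoder margins
#'
#' Converts the oriented hyperplane distances of a [train_readout()] result
#' into an `i1_vector`-compatible per-image difficulty vector (larger = more
#' confidently correct), optionally category-mean-subtracted (`normalize =
#' TRUE`) to give a model i1n directly comparable to behavioral i1n.
#'
#' @param result A `decoder_result`.
#' @param labels Optional per-image categories (named by image id or in test
#'   order); defaults to the test labels stored in `result`.
#' @param normalize Subtract per-category means.
#' @return An `i1_vector` (or `i1n_vector`) whose `dprime` column holds the
#'   margin-based values.
#' @export
margin_i1 <- function(result, labels = NULL, normalize = FALSE) {
  stopifnot(inherits(result, "decoder_result"))
  if (is.null(labels)) {
    labels <- result$test_labels
  } else {
    if (!is.null(names(labels))) {
      if (!setequal(names(labels), result$test_ids)) {
        stop("`labels` names do not match the decoder's test image ids", call. = FALSE)
      }
      labels <- unname(labels[result$test_ids])
    } else if (length(labels) != length(result$test_ids)) {
      stop("`labels` length does not match the number of test images", call. = FALSE)
    }
  }
  out <- data.frame(image_id = result$test_ids, category = as.character(labels),
                    dprime = unname(result$per_image_margin),
                    n_presented = result$n_resamples,
                    hr = NA_real_, fa = NA_real_, unscorable = FALSE,
                    stringsAsFactors = FALSE)
  out <- structure(out, class = c("i1_vector", "data.frame"))
  if (normalize) normalize_i1(out) else out
}

#' Decoder learning curve over training-set size
#'
#' Runs [train_readout()] at each value of `n_train_grid` and locates the
#' saturation point: the smallest training size whose mean accuracy is
#' within `tol` of the maximum over the grid.
#'
#' @param train,test `feature_set`s (see [train_readout()]).
#' @param n_train_grid Increasing vector of training images per class.
#' @param n_resamples,C,seed Passed to [train_readout()] (each grid point
#'   gets a distinct seed derived from `seed`).
#' @param tol Saturation tolerance on accuracy (default 0.005).
#' @return A `learning_curve`: list with `results` (one `decoder_result` per
#'   grid value), `n_train_grid`, `accuracy` (means), `accuracy_sd`,
#'   `saturation_n`, `tol`.
#' @export
learning_curve <- function(train, test, n_train_grid, n_resamples = 100,
                           C = 1, seed = 1, tol = 0.005) {
  if (length(n_train_grid) == 0L) stop("`n_train_grid` is empty", call. = FALSE)
  results <- lapply(seq_along(n_train_grid), function(i) {
    train_readout(train, test, n_train_grid[i], n_resamples = n_resamples,
                  C = C, seed = child_seed(seed, i))
  })
  acc <- vapply(results, function(r) r$accuracy_mean, numeric(1))
  sat <- n_train_grid[which(acc >= max(acc) - tol)[1]]
  structure(list(results = results, n_train_grid = n_train_grid,
                 accuracy = acc,
                 accuracy_sd = vapply(results, function(r) r$accuracy_sd, numeric(1)),
                 saturation_n = sat, tol = tol),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("learning curve:\n")
  for (i in seq_along(x$n_train_grid)) {
    cat(sprintf("  n = %4d: %.3f +/- %.3f\n", x$n_train_grid[i],
                x$accuracy[i], x$accuracy_sd[i]))
  }
  cat(sprintf("  saturation at n = %d (tol %.3f)\n", x$saturation_n, x$tol))
  invisible(x)
}
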