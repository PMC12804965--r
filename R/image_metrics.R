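#' Tabulate per-image and per-category response counts
#'
#' Reduces a trial table to the sufficient statistics of the image-level
#' signal-detection analysis: per image, the number of presentations and the
#' number of correct responses (hits); per category, the false-alarm counts —
#' trials whose true category was the *other* one but whose response was this
#' category. The false-alarm pool is shared across all images of a category.
#'
#' @param trials A trial table (see [simulate_trials()] /
#'   [read_trials_csv()]).
#' @return An `image_counts` object: list with `images` (data.frame
#'   `image_id, category, n_presented, n_correct`, ordered by image_id),
#'   `categories` (data.frame `category, fa_num, fa_den`), and `n_trials`.
#' @export
tabulate_counts <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("trial table is empty", call. = FALSE)
  }
  bad <- which(!(trials$true_category %in% c("A", "B")) |
                 !(trials$response_category %in% c("A", "B")))
  if (length(bad)) {
    stop("unknown category label in trial row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  img <- as.character(trials$image_id)
  correct <- as.integer(trials$true_category == trials$response_category)
  n_corr <- rowsum(correct, img)                  # sorted by image_id
  n_pres <- rowsum(rep(1L, length(img)), img)
  ids <- rownames(n_corr)
  cat_of <- trials$true_category[!duplicated(img)]
  names(cat_of) <- img[!duplicated(img)]
  images <- data.frame(image_id = ids, category = unname(cat_of[ids]),
                       n_presented = as.integer(n_pres[, 1]),
                       n_correct = as.integer(n_corr[, 1]),
                       stringsAsFactors = FALSE)
  categories <- data.frame(
    category = c("A", "B"),
    fa_num = c(sum(trials$true_category == "B" & trials$response_category == "A"),
               sum(trials$true_category == "A" & trials$response_category == "B")),
    fa_den = c(sum(trials$true_category == "B"),
               sum(trials$true_category == "A")),
    stringsAsFactors = FALSE
  )
  structure(list(images = images, categories = categories,
                 n_trials = nrow(trials)),
            class = "image_counts")
}

#' @export
print.image_counts <- function(x, ...) {
  cat(sprintf("image_counts: %d trials over %d images (A: %d, B: %d)\n",
              x$n_trials, nrow(x$images), sum(x$images$category == "A"),
              sum(x$images$category == "B")))
  invisible(x)
}

# Clip an empirical rate of exactly 0 or 1 to 1/(2N) / 1 - 1/(2N); other
# rates pass through untouched.
clip_rate <- function(k, n) {
  r <- k / n
  r[k == 0L] <- 1 / (2 * n[k == 0L])
  r[k == n] <- 1 - 1 / (2 * n[k == n])
  r
}

#' Per-image d-prime (the i1 vector)
#'
#' For each image j, `d'_j = z(HR_j) - z(FA_j)` where `HR_j` is the hit rate
#' of image j (proportion of its presentations answered with its own
#' category), `FA_j` is the false-alarm rate of j's *category* (proportion of
#' other-category trials answered with j's category — shared across all
#' images of a category, so within-category i1 differences are driven by hit
#' rates alone), and `z` is the standard-normal quantile function. Empirical
#' rates of exactly 0 or 1 are clipped to `1/(2N)` / `1 - 1/(2N)` with N the
#' relevant denominator, keeping d' finite and monotone in the counts.
#'
#' Images whose category has a zero false-alarm denominator are flagged
#' `unscorable` (d' = NA), not dropped.
#'
#' @param counts An [tabulate_counts()] result.
#' @return An `i1_vector`: data.frame with columns `image_id`, `category`,
#'   `dprime`, `n_presented`, `hr`, `fa`, `unscorable`.
#' @export
dprime_per_image <- function(counts) {
  stopifnot(inherits(counts, "image_counts"))
  im <- counts$images
  hr <- clip_rate(im$n_correct, im$n_presented)
  cats <- counts$categories
  fa_rate <- ifelse(cats$fa_den > 0, clip_rate(cats$fa_num, cats$fa_den), NA_real_)
  names(fa_rate) <- cats$category
  fa <- unname(fa_rate[im$category])
  unscorable <- is.na(fa)
  dprime <- stats::qnorm(hr) - stats::qnorm(fa)
  out <- data.frame(image_id = im$image_id, category = im$category,
                    dprime = dprime, n_presented = im$n_presented,
                    hr = hr, fa = fa, unscorable = unscorable,
                    stringsAsFactors = FALSE)
  structure(out, class = c("i1_vector", "data.frame"))
}

#' Category-mean-normalize an i1 vector (i1n)
#'
#' Subtracts from each image's d' the mean d' of all scored images of the
#' same category, removing any overall difficulty difference between the two
#' classes. Per-category means of the result are zero by construction.
#'
#' @param i1 An `i1_vector` from [dprime_per_image()].
#' @return An `i1n_vector` (same columns; `dprime` now category-centred).
#' @export
normalize_i1 <- function(i1) {
  stopifnot(inherits(i1, "i1_vector"))
  scored <- !i1$unscorable & is.finite(i1$dprime)
  for (cc in unique(i1$category)) {
    sel <- scored & i1$category == cc
    if (!any(sel)) {
      stop("category '", cc, "' has no scorable images", call. = FALSE)
    }
    i1$dprime[sel] <- i1$dprime[sel] - mean(i1$dprime[sel])
  }
  class(i1) <- c("i1n_vector", "i1_vector", "data.frame")
  i1
}

#' Compute i1 / i1n directly from a trial table
#'
#' Convenience wrappers chaining [tabulate_counts()], [dprime_per_image()]
#' and [normalize_i1()].
#'
#' @param trials A trial table.
#' @return [compute_i1()]: an `i1_vector`; [compute_i1n()]: an `i1n_vector`.
#' @export
compute_i1 <- function(trials) dprime_per_image(tabulate_counts(trials))

#' @rdname compute_i1
#' @export
compute_i1n <- function(trials) normalize_i1(compute_i1(trials))

#' Cross-validated lapse-rate estimate
#'
#' The lapse rate is the error floor attributed to non-perceptual failures.
#' It is estimated as the held-out error rate of the best image: trials are
#' randomly partitioned into two halves; the image with the highest accuracy
#' in one half (ties broken by larger trial count, then lexicographic id) is
#' identified, and its error rate is measured in the other half. Both
#' directions of each partition contribute, and the estimate is averaged
#' over `n_partitions` random partitions.
#'
#' @param trials A trial table with at least one image having >= 2 trials.
#' @param n_partitions Number of random half-splits to average over.
#' @param seed Integer seed.
#' @param correction_model Which correction formula this estimate is meant to
#'   feed (`"always_wrong"` or `"guess"`); stored, not used here.
#' @return A `lapse_estimate`: list with `lapse` (the estimate),
#'   `per_partition` (data.frame: partition, direction, best_image,
#'   n_heldout, error_rate), `n_partitions`, `correction_model`.
#' @export
estimate_lapse <- function(trials, n_partitions = 50, seed = 1,
                           correction_model = c("always_wrong", "guess")) {
  correction_model <- match.arg(correction_model)
  if (nrow(trials) < 2L) stop("need at least 2 trials", call. = FALSE)
  img <- as.character(trials$image_id)
  if (max(table(img)) < 2L) {
    stop("need at least one image with >= 2 trials", call. = FALSE)
  }
  correct <- as.integer(trials$true_category == trials$response_category)

  best_in <- function(k, n) {
    acc <- k / n
    ord <- order(-acc, -n, names(n))
    names(n)[ord[1]]
  }
  rows <- vector("list", 2L * n_partitions)
  for (p in seq_len(n_partitions)) {
    done <- FALSE
    for (attempt in 0:9) {
      halves <- split_trials(trials, seed = child_seed(seed, 100L * p + attempt))
      tallies <- lapply(halves, function(h) {
        hi <- as.character(h$image_id)
        hc <- as.integer(h$true_category == h$response_category)
        k <- rowsum(hc, hi); n <- rowsum(rep(1L, length(hi)), hi)
        list(k = stats::setNames(k[, 1], rownames(k)),
             n = stats::setNames(n[, 1], rownames(n)))
      })
      ok <- TRUE
      cand <- vector("list", 2L)
      for (d in 1:2) {
        sel <- tallies[[d]]; held <- tallies[[3 - d]]
        best <- best_in(sel$k, sel$n)
        if (!best %in% names(held$n)) { ok <- FALSE; break }
        cand[[d]] <- data.frame(
          partition = p, direction = d, best_image = best,
          n_heldout = unname(held$n[best]),
          error_rate = unname(1 - held$k[best] / held$n[best]),
          stringsAsFactors = FALSE)
      }
      if (ok) { rows[[2L * p - 1L]] <- cand[[1]]; rows[[2L * p]] <- cand[[2]]; done <- TRUE; break }
    }
    if (!done) {
      stop("best image repeatedly absent from the held-out half; ",
           "too few trials per image", call. = FALSE)
    }
  }
  per_partition <- do.call(rbind, rows)
  structure(list(lapse = mean(per_partition$error_rate),
                 per_partition = per_partition,
                 n_partitions = n_partitions,
                 correction_model = correction_model, seed = seed),
            class = "lapse_estimate")
}

#' @export
print.lapse_estimate <- function(x, ...) {
  cat(sprintf("lapse_estimate: %.4f (%d partitions, model '%s')\n",
              x$lapse, x$n_partitions, x$correction_model))
  invisible(x)
}

#' Lapse-corrected accuracy
#'
#' Removes the estimated lapse floor from an observed proportion correct.
#' Under the `always_wrong` model every lapse trial is an error, so
#' `p_corr = p_obs / (1 - lambda)`. Under the `guess` model a lapse trial is
#' correct half the time; the measured best-image error rate `lambda` then
#' corresponds to an effective lapse probability `lambda* = 2 lambda` and
#' `p_corr = (p_obs - lambda*/2) / (1 - lambda*)`. Results are clamped to
#' `[0, 1]`.
#'
#' @param p_obs Observed proportion(s) correct, each in `[0, 1]`.
#' @param lapse Measured lapse rate (best-image held-out error rate), or a
#'   [estimate_lapse()] result.
#' @param model Correction model, `"always_wrong"` (default) or `"guess"`.
#' @return Corrected proportion(s) correct.
#' @export
lapse_corrected_accuracy <- function(p_obs, lapse,
                                     model = c("always_wrong", "guess")) {
  model <- match.arg(model)
  if (inherits(lapse, "lapse_estimate")) lapse <- lapse$lapse
  if (any(p_obs < 0 | p_obs > 1)) stop("`p_obs` must lie in [0, 1]", call. = FALSE)
  if (lapse < 0) stop("`lapse` must be >= 0", call. = FALSE)
  if (model == "always_wrong") {
    if (lapse >= 1) stop("`lapse` must be < 1", call. = FALSE)
    p <- p_obs / (1 - lapse)
  } else {
    lam <- 2 * lapse
    if (lam >= 1) stop("effective lapse 2*lambda must be < 1", call. = FALSE)
    p <- (p_obs - lam / 2) / (1 - lam)
  }
  pmin(1, pmax(0, p))
}

#' Pooled task performance with a trial bootstrap
#'
#' Overall proportion correct across all trials in the table (pooled over
#' subjects), with uncertainty from resampling trials with replacement
#' `n_boot` times. If a lapse estimate is supplied, the correction is applied
#' to the point estimate and to every bootstrap replicate.
#'
#' @param trials A trial table.
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param lapse Optional lapse rate or [estimate_lapse()] result.
#' @param model Lapse-correction model, see [lapse_corrected_accuracy()].
#' @return A `pooled_performance`: list with `accuracy` (lapse-corrected if a
#'   lapse was given), `accuracy_raw`, `boot_mean`, `boot_sd`, `n_trials`,
#'   `n_boot`, `lapse`.
#' @export
pooled_performance <- function(trials, n_boot = 1000, seed = 1, lapse = NULL,
                               model = c("always_wrong", "guess")) {
  model <- match.arg(model)
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  if (nrow(trials) == 0L) stop("trial table is empty", call. = FALSE)
  correct <- as.numeric(trials$true_category == trials$response_category)
  n <- length(correct)
  lam <- if (inherits(lapse, "lapse_estimate")) lapse$lapse else lapse
  fix <- function(p) if (is.null(lam)) p else lapse_corrected_accuracy(p, lam, model)
  boot <- with_seed(seed, {
    # resampling n binary trials with replacement is exactly Binomial(n, phat)
    stats::rbinom(n_boot, n, mean(correct)) / n
  })
  boot <- fix(boot)
  structure(list(accuracy = fix(mean(correct)), accuracy_raw = mean(correct),
                 boot_mean = mean(boot), boot_sd = stats::sd(boot),
                 n_trials = n, n_boot = n_boot,
                 lapse = if (is.null(lam)) NA_real_ else lam, model = model),
            class = "pooled_performance")
}

#' @export
print.pooled_performance <- function(x, ...) {
  cat(sprintf("pooled accuracy: %.4f (raw %.4f, boot sd %.4f, %d trials)\n",
              x$accuracy, x$accuracy_raw, x$boot_sd, x$n_trials))
  invisible(x)
}
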