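#' Define a stimulus condition
#'
#' A condition is a filter over stimulus metadata: an orientation, a lighting
#' context, or both (NULL = no constraint). The three canonical conditions of
#' the face-context analysis are provided by [canonical_conditions()]:
#' upright = (upright, lit from above), inverted = (inverted, lit from
#' below), reversed = (upright, contrast reversed) — each restricted to one
#' lighting context so orientation and lighting effects do not interact.
#'
#' @param orientation `"upright"`, `"inverted"`, or NULL.
#' @param lighting `"above"`, `"below"`, `"reversed"`, or NULL.
#' @param label Condition label used in outputs.
#' @param include_tokens Whether token images match (default FALSE).
#' @return A `condition_spec`.
#' @export
condition_spec <- function(orientation = NULL, lighting = NULL, label,
                           include_tokens = FALSE) {
  structure(list(orientation = orientation, lighting = lighting,
                 label = label, include_tokens = include_tokens),
            class = "condition_spec")
}

#' @rdname condition_spec
#' @export
canonical_conditions <- function() {
  list(upright = condition_spec("upright", "above", label = "upright"),
       inverted = condition_spec("inverted", "below", label = "inverted"),
       reversed = condition_spec("upright", "reversed", label = "reversed"))
}

#' Image ids matching a condition
#'
#' @param spec A [condition_spec()].
#' @param stimuli A `stimulus_set`.
#' @return Character vector of matching image ids.
#' @export
condition_images <- function(spec, stimuli) {
  keep <- rep(TRUE, nrow(stimuli))
  if (!is.null(spec$orientation)) keep <- keep & stimuli$orientation == spec$orientation
  if (!is.null(spec$lighting)) keep <- keep & stimuli$lighting == spec$lighting
  if (!spec$include_tokens) keep <- keep & !stimuli$is_token
  stimuli$image_id[keep]
}

# Per-image sufficient statistics of a condition: counts restricted to the
# condition's images, with the clipped z(hit rate) precomputed.
condition_stats <- function(trials, spec, stimuli) {
  ids <- condition_images(spec, stimuli)
  sub <- trials[trials$image_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("condition '", spec$label, "' matches no trials", call. = FALSE)
  }
  counts <- tabulate_counts(sub)
  im <- counts$images
  if (length(unique(im$category)) < 2L) {
    stop("condition '", spec$label, "' has trials from only one category",
         call. = FALSE)
  }
  im$wrong <- im$n_presented - im$n_correct
  im$zhr <- stats::qnorm(clip_rate(im$n_correct, im$n_presented))
  im
}

# Mean per-image d-prime over image subsets, with the category false-alarm
# pools recomputed from the subset, vectorized over the columns of an index
# matrix. `st` is a condition_stats() frame; `idx` is k x n_boot.
subset_mean_dprime <- function(st, idx) {
  k <- nrow(idx)
  take <- function(v) matrix(v[idx], nrow = k)
  zhr_mean <- colMeans(take(st$zhr))
  isA <- as.numeric(st$category == "A")
  nA <- colSums(take(isA))
  nB <- k - nA
  wA <- colSums(take(st$wrong * isA));  pA <- colSums(take(st$n_presented * isA))
  wB <- colSums(take(st$wrong * (1 - isA))); pB <- colSums(take(st$n_presented * (1 - isA)))
  # FA for category A pools the wrong responses to the subset's B images;
  # a one-category subsample has no false-alarm pool and yields NA
  zfa <- function(w, p) {
    out <- rep(NA_real_, length(p))
    ok <- p > 0
    out[ok] <- stats::qnorm(clip_rate(w[ok], p[ok]))
    out
  }
  zhr_mean - (nA * zfa(wB, pB) + nB * zfa(wA, pA)) / k
}

#' Condition-wise mean d-prime
#'
#' Subsets the trial table to the images matching a condition, computes the
#' per-image d-prime vector within that subset (the false-alarm pools are
#' restricted to the subset's trials), and returns the per-image vector and
#' its mean.
#'
#' @param trials A trial table.
#' @param spec A [condition_spec()].
#' @param stimuli The `stimulus_set` the trials were collected on.
#' @return List with `mean_dprime`, `i1` (the within-condition `i1_vector`),
#'   `label`, `n_images`, `n_trials`.
#' @export
condition_dprime <- function(trials, spec, stimuli) {
  ids <- condition_images(spec, stimuli)
  sub <- trials[trials$image_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("condition '", spec$label, "' matches no trials", call. = FALSE)
  }
  i1 <- compute_i1(sub)
  scored <- !i1$unscorable & is.finite(i1$dprime)
  list(mean_dprime = mean(i1$dprime[scored]), i1 = i1, label = spec$label,
       n_images = nrow(i1), n_trials = nrow(sub))
}

#' Condition effect size with an image-subsampling bootstrap
#'
#' The effect is the difference in mean per-image d-prime between two
#' conditions (`cond_b` minus `cond_a`; e.g. inverted minus upright gives
#' the inversion effect, negative for a deficit). Uncertainty comes from an
#' image-subsampling bootstrap: each replicate draws `subsample_k` images
#' (default 25, without replacement) from each condition's image set,
#' recomputes the mean per-image d-prime within each subsample — including
#' the category false-alarm pools, so the uncertainty in the category
#' reference rates propagates — and takes the difference. The 95% CI is the
#' 2.5/97.5 percentile interval of the replicates.
#'
#' Subsample draws are made per condition in lexicographic label order, so
#' swapping `cond_a` and `cond_b` under the same seed pairs the identical
#' subsamples and negates every replicate exactly.
#'
#' @param trials A trial table.
#' @param cond_a,cond_b [condition_spec()]s (effect = b minus a).
#' @param stimuli The `stimulus_set`.
#' @param n_boot Number of bootstrap replicates.
#' @param subsample_k Images drawn per condition per replicate.
#' @param seed Integer seed.
#' @param replace Sample images with replacement (conventional bootstrap)
#'   instead of the default without-replacement subsampling.
#' @return An `effect_estimate`: list with `delta_dprime` (full-condition
#'   point estimate), `ci_low`, `ci_high`, `boot_samples`, `n_boot`,
#'   `subsample_k`, `label_a`, `label_b`, `seed`.
#' @export
effect_size <- function(trials, cond_a, cond_b, stimuli, n_boot = 1000,
                        subsample_k = 25, seed = 1, replace = FALSE) {
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  st_a <- condition_stats(trials, cond_a, stimuli)
  st_b <- condition_stats(trials, cond_b, stimuli)
  if (!replace && (subsample_k > nrow(st_a) || subsample_k > nrow(st_b))) {
    stop("`subsample_k` exceeds the number of scored images in a condition",
         call. = FALSE)
  }
  draw <- function(n_img) {
    vapply(seq_len(n_boot),
           function(i) sample.int(n_img, subsample_k, replace = replace),
           integer(subsample_k))
  }
  with_seed(seed, {
    # draw per condition in lexicographic label order => swapping the two
    # conditions mirrors the subsample pairing exactly
    if (cond_a$label <= cond_b$label) {
      idx_a <- draw(nrow(st_a)); idx_b <- draw(nrow(st_b))
    } else {
      idx_b <- draw(nrow(st_b)); idx_a <- draw(nrow(st_a))
    }
    boot <- subset_mean_dprime(st_b, matrix(idx_b, nrow = subsample_k)) -
      subset_mean_dprime(st_a, matrix(idx_a, nrow = subsample_k))
    full <- function(st) subset_mean_dprime(st, matrix(seq_len(nrow(st)), ncol = 1))
    delta <- full(st_b) - full(st_a)
    ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    structure(list(delta_dprime = delta, ci_low = ci[1], ci_high = ci[2],
                   boot_samples = boot, n_boot = n_boot,
                   subsample_k = subsample_k, label_a = cond_a$label,
                   label_b = cond_b$label, seed = seed),
              class = "effect_estimate")
  })
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect %s - %s: delta d' = %.3f [%.3f, %.3f] (%d boots, k = %d)\n",
              x$label_b, x$label_a, x$delta_dprime, x$ci_low, x$ci_high,
              x$n_boot, x$subsample_k))
  invisible(x)
}

#' Compare two condition effects
#'
#' Tests whether two effect estimates (e.g. the face and object inversion
#' effects) differ. `percentile_diff` (default) forms all pairwise
#' differences between the two bootstrap replicate arrays and reports the
#' two-sided sign-crossing probability — a purely resampling-based
#' comparison. `welch_boot` runs a two-sample Welch t-test over the replicate
#' arrays; note the replicates are resamples, not independent observations,
#' so its p-value is an emulation, flagged in the returned `note`.
#'
#' @param eff_1,eff_2 [effect_size()] results carrying bootstrap samples.
#' @param method `"percentile_diff"` or `"welch_boot"`.
#' @return List with `statistic`, `p_value`, `method`, `note`.
#' @export
compare_effects <- function(eff_1, eff_2,
                            method = c("percentile_diff", "welch_boot")) {
  method <- match.arg(method)
  for (e in list(eff_1, eff_2)) {
    if (!inherits(e, "effect_estimate") || is.null(e$boot_samples) ||
        length(e$boot_samples) == 0L) {
      stop("both effects must carry bootstrap samples", call. = FALSE)
    }
  }
  b1 <- eff_1$boot_samples[is.finite(eff_1$boot_samples)]
  b2 <- eff_2$boot_samples[is.finite(eff_2$boot_samples)]
  if (method == "percentile_diff") {
    d <- outer(b1, b2, "-")
    p_gt <- mean(d > 0); p_lt <- mean(d < 0)
    p <- min(1, 2 * min(p_gt, p_lt) + mean(d == 0))
    list(statistic = mean(b1) - mean(b2), p_value = p, method = method,
         note = "two-sided sign-crossing probability of the bootstrap difference distribution")
  } else {
    tt <- stats::t.test(b1, b2)
    list(statistic = unname(tt$statistic), p_value = tt$p.value, method = method,
         note = "Welch t over bootstrap replicates; replicates are not independent observations")
  }
}
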