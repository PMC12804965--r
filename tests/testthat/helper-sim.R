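# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A trial table built directly from per-image (n_presented, n_correct)
# counts, deterministic and order-stable.
trials_from_counts <- function(image_id, category, n_presented, n_correct,
                               pool_id = "pool", subject_id = "s1") {
  stopifnot(all(n_correct <= n_presented))
  rows <- lapply(seq_along(image_id), function(i) {
    correct <- c(rep(TRUE, n_correct[i]), rep(FALSE, n_presented[i] - n_correct[i]))
    other <- if (category[i] == "A") "B" else "A"
    data.frame(subject_id = subject_id, pool_id = pool_id,
               image_id = image_id[i], true_category = category[i],
               response_category = ifelse(correct, category[i], other),
               session = "s", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A random trial table over a small image set, for oracle comparisons.
random_trials <- function(n_images = 10, n_trials = 500, seed = 1,
                          pool_id = "pool") {
  set.seed(seed)
  ids <- sprintf("im%02d", seq_len(n_images))
  cats <- rep(c("A", "B"), length.out = n_images)
  idx <- sample.int(n_images, n_trials, replace = TRUE)
  resp <- ifelse(runif(n_trials) < 0.7, cats[idx],
                 ifelse(cats[idx] == "A", "B", "A"))
  data.frame(subject_id = "s1", pool_id = pool_id, image_id = ids[idx],
             true_category = cats[idx], response_category = resp,
             session = "s", stringsAsFactors = FALSE)
}

# Independent single-pass brute-force i1: recount every trial in a plain
# loop and apply z(HR) - z(FA) with the 1/(2N) clipping rule. Shares no code
# with the package implementation.
brute_force_i1 <- function(trials) {
  ids <- sort(unique(trials$image_id))
  clip <- function(k, n) {
    r <- k / n
    if (k == 0) r <- 1 / (2 * n)
    if (k == n) r <- 1 - 1 / (2 * n)
    r
  }
  out <- data.frame(image_id = ids, dprime = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    np <- 0L; nc <- 0L; cat_j <- NA_character_
    for (i in seq_len(nrow(trials))) {
      if (trials$image_id[i] == ids[j]) {
        np <- np + 1L
        cat_j <- trials$true_category[i]
        if (trials$response_category[i] == trials$true_category[i]) nc <- nc + 1L
      }
    }
    fa_num <- 0L; fa_den <- 0L
    for (i in seq_len(nrow(trials))) {
      if (trials$true_category[i] != cat_j) {
        fa_den <- fa_den + 1L
        if (trials$response_category[i] == cat_j) fa_num <- fa_num + 1L
      }
    }
    if (fa_den > 0) {
      out$dprime[j] <- qnorm(clip(nc, np)) - qnorm(clip(fa_num, fa_den))
    }
  }
  out
}

# Small stimulus set shared by several tests (62 images).
small_stimuli <- function(seed = 42) generate_stimulus_set(n_per_context = 5, seed = seed)
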