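test_that("counts tally hits and shared false-alarm pools exactly", {
  tr <- trials_from_counts("im1", "A", 4, 3)
  counts <- tabulate_counts(tr)
  expect_equal(counts$images$n_presented, 4L)
  expect_equal(counts$images$n_correct, 3L)

  # one-category table: FA denominator for the other category is every trial
  cat_a_only <- trials_from_counts(c("a1", "a2"), c("A", "A"), c(5, 5), c(4, 2))
  counts <- tabulate_counts(cat_a_only)
  expect_equal(counts$categories$fa_den[counts$categories$category == "B"], 10)
  expect_equal(counts$categories$fa_den[counts$categories$category == "A"], 0)

  expect_error(tabulate_counts(cat_a_only[0, ]), "empty")
  bad <- cat_a_only
  bad$response_category[3] <- "C"
  expect_error(tabulate_counts(bad), "unknown category label")
})

test_that("counts agree with an independent single-pass tally on random tables", {
  tr <- random_trials(n_images = 12, n_trials = 2000, seed = 3)
  counts <- tabulate_counts(tr)
  manual_pres <- table(tr$image_id)
  manual_corr <- tapply(tr$true_category == tr$response_category, tr$image_id, sum)
  expect_equal(counts$images$n_presented,
               as.integer(manual_pres[counts$images$image_id]),
               ignore_attr = TRUE)
  expect_equal(counts$images$n_correct,
               as.integer(manual_corr[counts$images$image_id]),
               ignore_attr = TRUE)
})

test_that("per-image d-prime follows z(HR) - z(FA) with boundary clipping", {
  # HR = FA = 0.5 => d' = 0
  tr <- trials_from_counts(c("a1", "b1"), c("A", "B"), c(10, 10), c(5, 5))
  i1 <- compute_i1(tr)
  expect_equal(i1$dprime, c(0, 0), tolerance = 1e-12)

  # HR = 0.841345, FA = 0.158655 => d' = 2.000 (z of 0.841345 is 1)
  tr <- trials_from_counts(c("a1", "b1"), c("A", "B"),
                           c(200000, 200000), c(168269, 168269))
  i1 <- compute_i1(tr)
  expect_lt(abs(i1$dprime[1] - 2.0), 1e-3)

  # a 20/20 hit rate clips to 1 - 1/40 = 0.975
  tr <- trials_from_counts(c("a1", "b1"), c("A", "B"), c(20, 20), c(20, 10))
  i1 <- compute_i1(tr)
  expect_equal(i1$dprime[i1$image_id == "a1"], qnorm(0.975) - qnorm(0.5),
               tolerance = 1e-12)

  # clipping only activates at rates of exactly 0 or 1
  tr <- trials_from_counts(c("a1", "a2", "b1"), c("A", "A", "B"),
                           c(10, 10, 10), c(9, 0, 5))
  i1 <- compute_i1(tr)
  expect_equal(i1$hr[i1$image_id == "a1"], 0.9)
  expect_equal(i1$hr[i1$image_id == "a2"], 1 / 20)
})

test_that("images without a false-alarm pool are flagged unscorable, not dropped", {
  tr <- trials_from_counts(c("a1", "a2"), c("A", "A"), c(5, 5), c(4, 2))
  i1 <- compute_i1(tr)
  expect_equal(nrow(i1), 2L)
  expect_true(all(i1$unscorable))
  expect_true(all(is.na(i1$dprime)))
})

test_that("i1 matches the brute-force oracle on random tables", {
  for (s in 1:10) {
    tr <- random_trials(n_images = 8, n_trials = 300, seed = s)
    got <- compute_i1(tr)
    want <- brute_force_i1(tr)
    expect_equal(got$dprime[match(want$image_id, got$image_id)], want$dprime,
                 tolerance = 1e-9)
  }
})

test_that("i1n removes category means and is shift-invariant", {
  # constant vector -> all zeros
  tr <- trials_from_counts(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"),
                           rep(10, 4), c(7, 7, 7, 7))
  expect_equal(compute_i1n(tr)$dprime, rep(0, 4), tolerance = 1e-12)

  # two-point means: A {1, 3}, B {0, 2} -> {-1, +1, -1, +1}
  i1 <- structure(data.frame(image_id = c("a1", "a2", "b1", "b2"),
                             category = c("A", "A", "B", "B"),
                             dprime = c(1, 3, 0, 2), n_presented = 10,
                             hr = NA_real_, fa = NA_real_, unscorable = FALSE,
                             stringsAsFactors = FALSE),
                  class = c("i1_vector", "data.frame"))
  expect_equal(normalize_i1(i1)$dprime, c(-1, 1, -1, 1))

  # random tables: per-category means vanish; adding a constant to one
  # category's d' values leaves i1n unchanged
  tr <- random_trials(n_images = 10, n_trials = 800, seed = 5)
  i1 <- compute_i1(tr)
  i1n <- normalize_i1(i1)
  expect_true(all(abs(tapply(i1n$dprime, i1n$category, mean)) < 1e-12))
  shifted <- i1
  shifted$dprime[shifted$category == "A"] <- shifted$dprime[shifted$category == "A"] + 1.7
  expect_equal(normalize_i1(shifted)$dprime, i1n$dprime, tolerance = 1e-12)

  one_cat <- trials_from_counts(c("a1", "a2"), c("A", "A"), c(5, 5), c(4, 2))
  expect_error(compute_i1n(one_cat), "no scorable images")
})

test_that("lapse estimation is zero for a perfect observer and non-negative at chance", {
  stim <- small_stimuli()
  perfect <- observer_model("p", setNames(rep(1, nrow(stim)), stim$image_id))
  tr <- simulate_trials(perfect, stim, 3000, seed = 1)
  est <- estimate_lapse(tr, n_partitions = 5, seed = 2)
  expect_equal(est$lapse, 0)

  coin <- observer_model("c", setNames(rep(0.5, nrow(stim)), stim$image_id))
  tr <- simulate_trials(coin, stim, 3000, seed = 3)
  est <- estimate_lapse(tr, n_partitions = 5, seed = 4)
  expect_gte(est$lapse, 0)
})

test_that("lapse correction formulas are exact and clamp at the boundaries", {
  expect_equal(lapse_corrected_accuracy(0.7, 0), 0.7)
  expect_equal(lapse_corrected_accuracy(0.7, 0, model = "guess"), 0.7)
  expect_equal(lapse_corrected_accuracy(0.98, 0.02), 1.0)
  expect_equal(lapse_corrected_accuracy(0.88, 0.02), 0.88 / 0.98)
  # guess model: lambda* = 2 lambda
  expect_equal(lapse_corrected_accuracy(0.88, 0.02, model = "guess"),
               (0.88 - 0.02) / 0.96)
  expect_error(lapse_corrected_accuracy(0.5, 1), "lapse")
  expect_error(lapse_corrected_accuracy(0.5, 0.5, model = "guess"), "lapse")
  expect_error(lapse_corrected_accuracy(1.2, 0.1), "p_obs")
})

test_that("pooled performance bootstraps trials with the binomial spread", {
  all_correct <- trials_from_counts(c("a1", "b1"), c("A", "B"), c(50, 50), c(50, 50))
  pp <- pooled_performance(all_correct, n_boot = 200, seed = 1)
  expect_equal(pp$accuracy, 1)
  expect_equal(pp$boot_sd, 0)

  tr <- trials_from_counts(c("a1", "b1"), c("A", "B"), c(5000, 5000), c(3900, 3900))
  pp <- pooled_performance(tr, n_boot = 1000, seed = 2)
  se <- sqrt(0.78 * 0.22 / 10000)
  expect_lt(abs(pp$boot_sd - se) / se, 0.30)
  expect_equal(pp$accuracy_raw, 0.78)

  # pooling two equal-size subjects at 0.7 and 0.9 gives 0.8
  s1 <- trials_from_counts(c("a1", "b1"), c("A", "B"), c(500, 500), c(350, 350),
                           subject_id = "s1")
  s2 <- trials_from_counts(c("a1", "b1"), c("A", "B"), c(500, 500), c(450, 450),
                           subject_id = "s2")
  pp <- pooled_performance(rbind(s1, s2), n_boot = 10, seed = 3)
  expect_equal(pp$accuracy_raw, 0.8)

  expect_error(pooled_performance(tr, n_boot = 0, seed = 1), "n_boot")
})

test_that("d-prime estimates track latent sensitivity on simulated pools", {
  stim <- small_stimuli()
  obs <- make_observer(stim, mean_dprime = 1.5, sd_dprime = 0.3, lapse = 0,
                       seed = 6)
  tr <- simulate_trials(obs, stim, nrow(stim) * 500, seed = 7)
  i1 <- compute_i1(tr)
  lat <- obs$dprime_latent[i1$image_id]
  expect_lt(mean(abs(i1$dprime - lat)), 0.15)
  expect_gt(cor(i1$dprime, lat), 0.7)
})
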