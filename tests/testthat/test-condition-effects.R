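stim <- generate_stimulus_set(25, seed = 1)

test_that("an all-matching condition reproduces the global mean d-prime", {
  obs <- make_observer(stim, mean_dprime = 1.5, sd_dprime = 0.4, lapse = 0, seed = 1)
  tr <- simulate_trials(obs, stim, 20000, seed = 2)
  all_spec <- condition_spec(label = "all", include_tokens = TRUE)
  cd <- condition_dprime(tr, all_spec, stim)
  i1 <- compute_i1(tr)
  expect_equal(cd$mean_dprime, mean(i1$dprime[!i1$unscorable]), tolerance = 1e-12)
})

test_that("disjoint conditions partition the trials", {
  obs <- make_observer(stim, lapse = 0, seed = 3)
  tr <- simulate_trials(obs, stim, 15000, seed = 4)
  specs <- list(condition_spec(orientation = "upright", label = "up",
                               include_tokens = TRUE),
                condition_spec(orientation = "inverted", label = "inv"))
  counts <- vapply(specs, function(sp) condition_dprime(tr, sp, stim)$n_trials,
                   numeric(1))
  expect_equal(sum(counts), nrow(tr))
})

test_that("an injected inversion deficit is recovered by condition d-prime", {
  conds <- canonical_conditions()
  cond_ids <- c(condition_images(conds$upright, stim),
                condition_images(conds$inverted, stim))
  w <- as.numeric(stim$image_id %in% cond_ids)
  obs <- make_observer(stim, mean_dprime = 1.54, sd_dprime = 0.4, lapse = 0,
                       seed = 5, shifts = c(inverted_below = -0.31))
  tr <- simulate_trials(obs, stim, 500 * length(cond_ids), seed = 6, weights = w)
  delta <- condition_dprime(tr, conds$inverted, stim)$mean_dprime -
    condition_dprime(tr, conds$upright, stim)$mean_dprime
  expect_lt(abs(delta - (-0.31)), 0.1)
})

test_that("effect bootstrap behaves at its edges", {
  conds <- canonical_conditions()
  obs <- make_observer(stim, lapse = 0, seed = 7)
  tr <- simulate_trials(obs, stim, 30000, seed = 8)

  self <- effect_size(tr, conds$upright, conds$upright, stim, n_boot = 400,
                      seed = 9)
  expect_lt(self$ci_low, 0)
  expect_gt(self$ci_high, 0)
  expect_lt(abs(mean(self$boot_samples)), 0.1)

  one <- effect_size(tr, conds$upright, conds$inverted, stim, n_boot = 1, seed = 10)
  expect_equal(one$ci_low, one$ci_high)
  expect_equal(one$ci_low, one$boot_samples[1])

  expect_error(effect_size(tr, conds$upright, conds$inverted, stim,
                           subsample_k = 60, seed = 11), "subsample_k")
})

test_that("swapping the conditions mirrors every bootstrap replicate exactly", {
  conds <- canonical_conditions()
  obs <- make_observer(stim, lapse = 0, seed = 12)
  tr <- simulate_trials(obs, stim, 20000, seed = 13)
  ab <- effect_size(tr, conds$upright, conds$inverted, stim, n_boot = 300, seed = 14)
  ba <- effect_size(tr, conds$inverted, conds$upright, stim, n_boot = 300, seed = 14)
  expect_equal(ba$boot_samples, -ab$boot_samples, tolerance = 1e-12)
  expect_equal(ba$delta_dprime, -ab$delta_dprime, tolerance = 1e-12)
})

test_that("the CI straddles the bootstrap median", {
  conds <- canonical_conditions()
  obs <- make_observer(stim, seed = 15, shifts = c(inverted_below = -0.5))
  tr <- simulate_trials(obs, stim, 30000, seed = 16)
  eff <- effect_size(tr, conds$upright, conds$inverted, stim, n_boot = 500, seed = 17)
  med <- median(eff$boot_samples)
  expect_lte(eff$ci_low, med)
  expect_lte(med, eff$ci_high)
})

test_that("effect comparisons separate unequal shifts and equal ones", {
  conds <- canonical_conditions()
  cond_ids <- c(condition_images(conds$upright, stim),
                condition_images(conds$inverted, stim))
  w <- as.numeric(stim$image_id %in% cond_ids)
  face <- make_observer(stim, mean_dprime = 2.68, sd_dprime = 0.4, lapse = 0,
                        seed = 18, shifts = c(inverted_below = -0.9), pool_id = "face")
  obj <- make_observer(stim, mean_dprime = 2.68, sd_dprime = 0.4, lapse = 0,
                       seed = 19, shifts = c(inverted_below = -0.1), pool_id = "obj")
  tr_face <- simulate_trials(face, stim, 200 * length(cond_ids), seed = 20, weights = w)
  tr_obj <- simulate_trials(obj, stim, 200 * length(cond_ids), seed = 21, weights = w)
  e_face <- effect_size(tr_face, conds$upright, conds$inverted, stim,
                        n_boot = 500, seed = 22)
  e_obj <- effect_size(tr_obj, conds$upright, conds$inverted, stim,
                       n_boot = 500, seed = 23)
  for (m in c("percentile_diff", "welch_boot")) {
    cmp <- compare_effects(e_face, e_obj, method = m)
    expect_lt(cmp$p_value, 0.01)
  }

  same <- compare_effects(e_face, e_face)
  expect_gt(same$p_value, 0.9)
  t_same <- compare_effects(e_face, e_face, method = "welch_boot")
  expect_lt(abs(t_same$statistic), 1e-8)

  broken <- e_obj
  broken$boot_samples <- numeric(0)
  expect_error(compare_effects(e_face, broken), "bootstrap")
})

test_that("null effects are rarely flagged", {
  conds <- canonical_conditions()
  flags <- vapply(1:20, function(k) {
    obs <- make_observer(stim, mean_dprime = 1.5, sd_dprime = 0.4, lapse = 0,
                         seed = 400 + k)
    tr <- simulate_trials(obs, stim, 30000, seed = 500 + k)
    eff <- effect_size(tr, conds$upright, conds$inverted, stim, n_boot = 200,
                       seed = 600 + k)
    abs(mean(eff$boot_samples)) < 2 * sd(eff$boot_samples)
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})
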