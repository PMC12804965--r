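test_that("stratified splits conserve trials with per-image balance", {
  tr2 <- trials_from_counts("im1", "A", 2, 1)
  halves <- split_trials(tr2, seed = 1)
  expect_equal(nrow(halves[[1]]), 1L)
  expect_equal(nrow(halves[[2]]), 1L)

  tr <- random_trials(n_images = 15, n_trials = 10000, seed = 2)
  halves <- split_trials(tr, seed = 3)
  rejoined <- rbind(halves[[1]], halves[[2]])
  key <- function(d) sort(do.call(paste, d))
  expect_equal(key(rejoined), key(tr))
  n1 <- table(halves[[1]]$image_id)
  n2 <- table(halves[[2]]$image_id)
  ids <- union(names(n1), names(n2))
  d <- abs(as.integer(n1[ids]) - as.integer(n2[ids]))
  d[is.na(d)] <- 1L
  expect_true(all(d <= 1L))
})

test_that("byte-identical pools give a noise-corrected correlation of exactly 1", {
  stim <- small_stimuli()
  obs <- make_observer(stim, mean_dprime = 1.5, sd_dprime = 0.6, lapse = 0, seed = 4)
  tr <- simulate_trials(obs, stim, 4000, seed = 40)
  nc <- noise_corrected_correlation(tr, tr, n_partitions = 5, seed = 5)
  expect_equal(nc$r_cross, nc$r_internal_a, tolerance = 1e-12)
  expect_equal(nc$r_internal_a, nc$r_internal_b, tolerance = 1e-12)
  expect_equal(nc$r_nc, 1, tolerance = 1e-12)
})

test_that("internal consistency hits its ceiling and floor cases", {
  stim <- small_stimuli()
  # deterministic observer, balanced design: both halves identical
  p <- setNames(rep(c(0, 1), length.out = nrow(stim)), stim$image_id)
  det <- trials_from_counts(stim$image_id, stim$category,
                            rep(20L, nrow(stim)),
                            as.integer(20 * p[stim$image_id]))
  expect_equal(internal_consistency(det, n_partitions = 3, seed = 1), 1,
               tolerance = 1e-9)

  # strong image signal, many trials
  big <- generate_stimulus_set(10, seed = 2)   # 122 images
  pvals <- setNames(seq(0.15, 0.95, length.out = nrow(big)), big$image_id)
  obs <- observer_model("m", pvals)
  tr <- simulate_trials(obs, big, nrow(big) * 500, seed = 3)
  expect_gt(internal_consistency(tr, n_partitions = 5, seed = 4), 0.9)

  # no image signal at all
  flat <- observer_model("f", setNames(rep(0.75, nrow(big)), big$image_id))
  tr <- simulate_trials(flat, big, nrow(big) * 50, seed = 5)
  expect_lt(abs(internal_consistency(tr, n_partitions = 20, seed = 6)), 0.15)
})

test_that("internal consistency grows with trials per image", {
  stim <- small_stimuli()
  mean_ic <- vapply(c(16, 48, 144), function(tpi) {
    mean(vapply(1:20, function(rep) {
      obs <- make_observer(stim, mean_dprime = 1.5, sd_dprime = 0.5, lapse = 0,
                           seed = 100 + rep)
      tr <- simulate_trials(obs, stim, nrow(stim) * tpi, seed = 200 + rep)
      internal_consistency(tr, n_partitions = 3, seed = 300 + rep)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ic) > 0))
})

test_that("noise-corrected correlation recovers linked-pool structure", {
  stim <- generate_stimulus_set(10, seed = 1)
  # independent re-simulations of one observer: latent correlation 1
  obs <- make_observer(stim, mean_dprime = 1.5, sd_dprime = 0.5, lapse = 0, seed = 2)
  ta <- simulate_trials(obs, stim, nrow(stim) * 150, seed = 3)
  tb <- simulate_trials(obs, stim, nrow(stim) * 150, seed = 4)
  nc <- noise_corrected_correlation(ta, tb, n_partitions = 8, seed = 5)
  expect_lt(abs(nc$r_nc - 1), 0.1)

  # uncorrelated pools
  lk <- make_linked_observers(stim, rho = 0, sd_dprime = 0.5, lapses = c(0, 0),
                              seed = 6)
  ta <- simulate_trials(lk$observer_a, stim, nrow(stim) * 150, seed = 7)
  tb <- simulate_trials(lk$observer_b, stim, nrow(stim) * 150, seed = 8)
  nc0 <- noise_corrected_correlation(ta, tb, n_partitions = 8, seed = 9)
  expect_lt(abs(nc0$r_nc), 0.15)
})

test_that("both ceiling conventions are reported and consistent", {
  stim <- small_stimuli()
  lk <- make_linked_observers(stim, rho = 0.6, sd_dprime = 0.6, lapses = c(0, 0),
                              seed = 10)
  tr_a <- simulate_trials(lk$observer_a, stim, 4000, seed = 100)
  tr_b <- simulate_trials(lk$observer_b, stim, 4000, seed = 110)
  nc <- noise_corrected_correlation(tr_a, tr_b, n_partitions = 5, seed = 12)
  expect_equal(nc$ceiling, sqrt(nc$r_internal_a * nc$r_internal_b))
  expect_equal(nc$r_nc_printed_sum,
               nc$r_cross / sqrt(nc$r_internal_a + nc$r_internal_b))
  nc2 <- noise_corrected_correlation(tr_a, tr_b, n_partitions = 5, seed = 12,
                                     denominator_mode = "printed_sum")
  expect_equal(nc2$r_nc, nc$r_nc_printed_sum)
  expect_equal(nc2$r_cross, nc$r_cross)
})

test_that("r_nc is exactly invariant to consistent image relabeling", {
  stim <- small_stimuli()
  lk <- make_linked_observers(stim, rho = 0.5, sd_dprime = 0.5, seed = 13)
  ta <- simulate_trials(lk$observer_a, stim, 5000, seed = 14)
  tb <- simulate_trials(lk$observer_b, stim, 5000, seed = 15)
  nc <- noise_corrected_correlation(ta, tb, n_partitions = 4, seed = 16)

  set.seed(99)
  relabel <- setNames(sprintf("zz_%03d", sample(seq_len(nrow(stim)))), stim$image_id)
  ta2 <- ta; ta2$image_id <- unname(relabel[ta$image_id])
  tb2 <- tb; tb2$image_id <- unname(relabel[tb$image_id])
  nc2 <- noise_corrected_correlation(ta2, tb2, n_partitions = 4, seed = 16)
  expect_equal(nc2$r_nc, nc$r_nc, tolerance = 1e-12)
  expect_equal(nc2$r_cross, nc$r_cross, tolerance = 1e-12)
})

test_that("pool-specific images are dropped with a warning", {
  stim <- small_stimuli()
  lk <- make_linked_observers(stim, rho = 0.6, sd_dprime = 0.6, lapses = c(0, 0),
                              seed = 17)
  tr_a <- simulate_trials(lk$observer_a, stim, 3000, seed = 170)
  tr_b <- simulate_trials(lk$observer_b, stim, 3000, seed = 180)
  drop_id <- stim$image_id[1]
  tr_b <- tr_b[tr_b$image_id != drop_id, ]
  expect_warning(
    nc <- noise_corrected_correlation(tr_a, tr_b, n_partitions = 3, seed = 19),
    "dropped")
  expect_equal(nc$n_images_used, nrow(stim) - 1L)
})
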