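#' Construct a synthetic observer model
#'
#' An observer model is the generative description of a subject pool in the
#' binary categorization task: a latent probability of answering correctly
#' for every image, plus a lapse process that occasionally overrides
#' perception (attention slips, motor errors). On a lapse trial, which occurs
#' with probability `lapse`, the response is correct with probability
#' `lapse_guess_correct` (0.5 = unbiased guessing, 0 = always wrong); if
#' `lapse_guess_correct` is `NA` the lapse response is instead category "A"
#' with probability `bias_A` regardless of the true category.
#'
#' Observed per-image accuracy under the model is
#' `(1 - lapse) * p_true + lapse * lapse_guess_correct`.
#'
#' @param pool_id Character label of the pool (e.g. "human", "marmoset").
#' @param p_true Named numeric vector, latent probability correct per
#'   image_id, each in `[0, 1]`.
#' @param lapse Lapse probability, in `[0, 1)` for a usable observer
#'   (exactly 1 is accepted for degenerate simulations).
#' @param lapse_guess_correct Probability a lapse trial is scored correct.
#' @param bias_A Probability a lapse response is category "A" when
#'   `lapse_guess_correct` is `NA`.
#' @return An `observer_model` object.
#' @export
observer_model <- function(pool_id, p_true, lapse = 0,
                           lapse_guess_correct = 0.5, bias_A = 0.5) {
  stopifnot(is.character(pool_id), length(pool_id) == 1L)
  if (is.null(names(p_true)) || any(!nzchar(names(p_true)))) {
    stop("`p_true` must be named by image_id", call. = FALSE)
  }
  if (any(p_true < 0 | p_true > 1)) stop("`p_true` must lie in [0, 1]", call. = FALSE)
  if (lapse < 0 || lapse > 1) stop("`lapse` must lie in [0, 1]", call. = FALSE)
  structure(list(pool_id = pool_id, p_true = p_true, lapse = lapse,
                 lapse_guess_correct = lapse_guess_correct, bias_A = bias_A),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("observer_model '%s': %d images, lapse = %.3f, mean p_true = %.3f\n",
              x$pool_id, length(x$p_true), x$lapse, mean(x$p_true)))
  invisible(x)
}

#' Map latent per-image d-prime to probability correct
#'
#' Uses the symmetric-criterion convention `p_true = pnorm(dprime / 2)`:
#' hits and correct rejections are equally likely, so the image-level
#' d-prime estimator applied to simulated trials recovers the latent values
#' (up to the shared false-alarm pooling of the estimator).
#'
#' @param dprime Numeric vector of latent sensitivities.
#' @return Probabilities correct in `(0, 1)`.
#' @export
dprime_to_ptrue <- function(dprime) stats::pnorm(dprime / 2)

#' Simulate a table of 2AFC trials from an observer model
#'
#' Each trial samples an image (uniformly, or by `weights`), flips a lapse
#' coin with probability `observer$lapse`, and responds: non-lapse trials are
#' correct with probability `p_true[image]`; lapse trials follow the
#' observer's lapse response rule (see [observer_model()]). Responses are
#' recorded as the chosen category, giving one row per trial.
#'
#' @param observer An [observer_model()]. Every sampled image must have an
#'   entry in `observer$p_true`.
#' @param stimuli A `stimulus_set` (only `image_id` and `category` are used).
#' @param n_trials Number of trials to simulate.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param weights Optional non-negative per-image sampling weights (recycled
#'   against `nrow(stimuli)`); images with zero weight are never shown.
#' @param subject_id Subject label stored in the table (default the pool id).
#' @param session Session label (default `"sim"`).
#' @return A trial table: data.frame with columns `subject_id`, `pool_id`,
#'   `image_id`, `true_category`, `response_category`, `session`.
#' @export
simulate_trials <- function(observer, stimuli, n_trials, seed,
                            weights = NULL, subject_id = observer$pool_id,
                            session = "sim") {
  stopifnot(inherits(observer, "observer_model"))
  if (n_trials < 1) stop("`n_trials` must be positive", call. = FALSE)
  missing_ids <- setdiff(stimuli$image_id, names(observer$p_true))
  if (length(missing_ids)) {
    stop("no p_true entry for image(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ..." else "", call. = FALSE)
  }
  with_seed(seed, {
    idx <- if (is.null(weights)) {
      sample.int(nrow(stimuli), n_trials, replace = TRUE)
    } else {
      sample.int(nrow(stimuli), n_trials, replace = TRUE, prob = weights)
    }
    img <- stimuli$image_id[idx]
    truth <- stimuli$category[idx]
    p <- unname(observer$p_true[img])
    is_lapse <- stats::runif(n_trials) < observer$lapse
    correct <- stats::runif(n_trials) < p
    other <- ifelse(truth == "A", "B", "A")
    response <- ifelse(correct, truth, other)
    if (any(is_lapse)) {
      nl <- sum(is_lapse)
      if (is.na(observer$lapse_guess_correct)) {
        lapse_resp <- ifelse(stats::runif(nl) < observer$bias_A, "A", "B")
      } else {
        lapse_correct <- stats::runif(nl) < observer$lapse_guess_correct
        lapse_resp <- ifelse(lapse_correct, truth[is_lapse], other[is_lapse])
      }
      response[is_lapse] <- lapse_resp
    }
    data.frame(subject_id = subject_id, pool_id = observer$pool_id,
               image_id = img, true_category = truth,
               response_category = response, session = session,
               stringsAsFactors = FALSE)
  })
}

# Draw a latent per-image d-prime vector and turn it into an observer model.
# `shifts` is a named vector of additive d-prime offsets keyed by context
# label ("orientation_lighting"), the mechanism used to inject inversion /
# contrast-reversal deficits.
latent_to_observer <- function(stimuli, dprime, pool_id, lapse,
                               lapse_guess_correct, shifts = NULL) {
  if (!is.null(shifts)) {
    ctx <- context_label(stimuli)
    hit <- ctx %in% names(shifts)
    dprime[hit] <- dprime[hit] + unname(shifts[ctx[hit]])
  }
  p_true <- dprime_to_ptrue(dprime)
  names(p_true) <- stimuli$image_id
  obs <- observer_model(pool_id, p_true, lapse = lapse,
                        lapse_guess_correct = lapse_guess_correct)
  obs$dprime_latent <- stats::setNames(dprime, stimuli$image_id)
  obs
}

#' Generate a single synthetic observer pool
#'
#' Latent per-image d-prime values are drawn i.i.d. normal with the given
#' mean and sd, optional additive context shifts are applied (e.g. an
#' inversion deficit), and the result is converted to per-image probability
#' correct via [dprime_to_ptrue()].
#'
#' @param stimuli A `stimulus_set`.
#' @param mean_dprime,sd_dprime Mean and sd of the latent d-prime draw.
#' @param lapse Lapse rate of the pool.
#' @param seed Integer seed.
#' @param shifts Named numeric vector of d-prime offsets keyed by context
#'   label, e.g. `c(inverted_below = -0.9, upright_reversed = -0.4)`.
#' @param pool_id Pool label.
#' @param lapse_guess_correct Lapse response rule (see [observer_model()]).
#' @return An `observer_model` carrying the latent d-prime vector in
#'   `$dprime_latent`.
#' @export
make_observer <- function(stimuli, mean_dprime = 1.5, sd_dprime = 0.4,
                          lapse = 0.02, seed = 1, shifts = NULL,
                          pool_id = "pool", lapse_guess_correct = 0) {
  stopifnot(sd_dprime >= 0)
  with_seed(seed, {
    d <- stats::rnorm(nrow(stimuli), mean_dprime, sd_dprime)
    latent_to_observer(stimuli, d, pool_id, lapse, lapse_guess_correct, shifts)
  })
}

#' Generate two observer pools with correlated image-level difficulty
#'
#' Draws two latent per-image d-prime vectors from a bivariate normal,
#' applies optional per-pool context shifts, and converts each to an
#' observer model. This is the generative null/alternative for cross-pool
#' image-level consistency analyses: the noise-corrected i1n correlation
#' between the two simulated pools should recover `rho`.
#'
#' `rho` is the target correlation of the pools' *final* latent difficulty
#' vectors. Context shifts shared by both pools (e.g. both having an
#' inversion deficit) are themselves a source of image-level correlation,
#' so when shifts are supplied the correlation of the underlying bivariate
#' draw is solved for internally such that the shift-inclusive vectors have
#' population correlation `rho`; an unreachable combination (e.g. `rho` too
#' low for strongly shared shifts) is an error.
#'
#' @param stimuli A `stimulus_set`.
#' @param rho Target latent image-level correlation between the two pools,
#'   in `[-1, 1]`, inclusive of any context-shift structure.
#' @param mean_dprime Marginal mean(s) of the latent draws: a single value
#'   shared by both pools, or a length-2 vector giving each pool its own
#'   baseline sensitivity.
#' @param sd_dprime Marginal sd of the latent draws (shared).
#' @param lapses Length-2 numeric, lapse rate of each pool.
#' @param seed Integer seed.
#' @param shifts_a,shifts_b Optional named context-shift vectors per pool
#'   (see [make_observer()]), applied after the correlated draw.
#' @param pool_ids Length-2 character, pool labels.
#' @param lapse_guess_correct Lapse response rule shared by both pools.
#' @return List with `observer_a`, `observer_b`, `realized_rho` (Pearson
#'   correlation of the two shift-inclusive latent vectors), `base_rho`
#'   (the correlation used for the underlying bivariate draw), and `latent`
#'   (data.frame of both final latent d-prime vectors).
#' @export
make_linked_observers <- function(stimuli, rho, mean_dprime = 1.5,
                                  sd_dprime = 0.4, lapses = c(0.02, 0.02),
                                  seed = 1, shifts_a = NULL, shifts_b = NULL,
                                  pool_ids = c("pool_a", "pool_b"),
                                  lapse_guess_correct = 0) {
  if (length(rho) != 1L || is.na(rho) || abs(rho) > 1) {
    stop("`rho` must be a single value in [-1, 1]", call. = FALSE)
  }
  stopifnot(sd_dprime >= 0, length(lapses) == 2L)
  mean_dprime <- rep_len(mean_dprime, 2L)
  n <- nrow(stimuli)
  shift_vec <- function(shifts) {
    s <- numeric(n)
    if (!is.null(shifts)) {
      ctx <- context_label(stimuli)
      hit <- ctx %in% names(shifts)
      s[hit] <- unname(shifts[ctx[hit]])
    }
    s
  }
  s_a <- shift_vec(shifts_a)
  s_b <- shift_vec(shifts_b)
  pvar <- function(x) mean((x - mean(x))^2)
  pcov <- mean((s_a - mean(s_a)) * (s_b - mean(s_b)))
  var_a <- sd_dprime^2 + pvar(s_a)
  var_b <- sd_dprime^2 + pvar(s_b)
  # solve for the base correlation so the shift-inclusive vectors have
  # population correlation rho
  if (sd_dprime > 0) {
    base_rho <- (rho * sqrt(var_a * var_b) - pcov) / sd_dprime^2
    if (abs(base_rho) > 1 + 1e-12) {
      stop(sprintf(paste0("target rho = %.3f is unreachable with these context ",
                          "shifts (required base correlation %.3f)"),
                   rho, base_rho), call. = FALSE)
    }
    base_rho <- max(-1, min(1, base_rho))
  } else {
    base_rho <- NA_real_
  }
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    br <- if (is.na(base_rho)) 0 else base_rho
    d_a <- mean_dprime[1] + sd_dprime * z1 + s_a
    d_b <- mean_dprime[2] + sd_dprime * (br * z1 + sqrt(1 - br^2) * z2) + s_b
    realized <- if (stats::sd(d_a) > 0 && stats::sd(d_b) > 0) {
      stats::cor(d_a, d_b)
    } else NA_real_
    obs_a <- latent_to_observer(stimuli, d_a, pool_ids[1], lapses[1],
                                lapse_guess_correct)
    obs_b <- latent_to_observer(stimuli, d_b, pool_ids[2], lapses[2],
                                lapse_guess_correct)
    list(observer_a = obs_a, observer_b = obs_b, realized_rho = realized,
         base_rho = base_rho,
         latent = data.frame(image_id = stimuli$image_id, dprime_a = d_a,
                             dprime_b = d_b, stringsAsFactors = FALSE))
  })
}
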