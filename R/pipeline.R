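#' Subject-level validation and exclusion
#'
#' Applies the standard subject-exclusion rules before pooling: a subject is
#' removed if they completed fewer than `min_trials` trials, or performed
#' near chance. "Near chance" defaults to a one-sided binomial test of
#' accuracy > 0.5 at level `alpha` (a subject is excluded when the test does
#' not reject); a fixed accuracy threshold is available with
#' `chance_rule = "fixed"`.
#'
#' @param trials A trial table.
#' @param min_trials Minimum trial count per subject (default 20).
#' @param chance_rule `"binomial"` (default) or `"fixed"`.
#' @param alpha Level of the binomial test.
#' @param threshold Accuracy cut-off for the fixed rule (default 0.55).
#' @return List with `trials` (filtered), `exclusions` (data.frame:
#'   subject_id, pool_id, n_trials, accuracy, reason) and `subjects`
#'   (per-subject summary with a `kept` flag).
#' @export
validate_and_filter_subjects <- function(trials, min_trials = 20,
                                         chance_rule = c("binomial", "fixed"),
                                         alpha = 0.05, threshold = 0.55) {
  chance_rule <- match.arg(chance_rule)
  key <- paste(trials$pool_id, trials$subject_id, sep = "\r")
  correct <- as.integer(trials$true_category == trials$response_category)
  k <- rowsum(correct, key); n <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(k), "\r", fixed = TRUE)
  subjects <- data.frame(
    pool_id = vapply(parts, `[`, "", 1L),
    subject_id = vapply(parts, `[`, "", 2L),
    n_trials = as.integer(n[, 1]), n_correct = as.integer(k[, 1]),
    accuracy = k[, 1] / n[, 1], stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(subjects))
  too_few <- subjects$n_trials < min_trials
  reason[too_few] <- "min_trials"
  near_chance <- if (chance_rule == "binomial") {
    vapply(seq_len(nrow(subjects)), function(i) {
      stats::binom.test(subjects$n_correct[i], subjects$n_trials[i], 0.5,
                        alternative = "greater")$p.value >= alpha
    }, logical(1))
  } else {
    subjects$accuracy < threshold
  }
  reason[is.na(reason) & near_chance] <- "near_chance"
  subjects$kept <- is.na(reason)
  subjects$reason <- reason
  if (!any(subjects$kept)) stop("all subjects excluded", call. = FALSE)
  keep_keys <- paste(subjects$pool_id[subjects$kept],
                     subjects$subject_id[subjects$kept], sep = "\r")
  list(trials = trials[key %in% keep_keys, , drop = FALSE],
       exclusions = subjects[!subjects$kept,
                             c("subject_id", "pool_id", "n_trials", "accuracy", "reason"),
                             drop = FALSE],
       subjects = subjects)
}

#' Assemble a full-pipeline configuration
#'
#' Collects every input and tunable of [run_pipeline()] into one object with
#' full provenance: all seeds and counts are recorded in the report.
#' Trial/stimulus/feature inputs may be in-memory objects or file paths
#' (read with the package readers).
#'
#' @param trials_a,trials_b Trial tables (or CSV paths) of the two pools.
#' @param stimuli A `stimulus_set` (or CSV path).
#' @param features_train,features_test Optional `feature_set`s (or paths) for
#'   the decoder stage; when absent the stage is skipped.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param min_trials,chance_rule Subject-exclusion rules
#'   (see [validate_and_filter_subjects()]).
#' @param lapse_model Lapse-correction model
#'   (see [lapse_corrected_accuracy()]).
#' @param lapse_partitions,n_boot,n_partitions,subsample_k Resampling counts
#'   for the lapse, performance-bootstrap, reliability and effect stages.
#' @param denominator_mode Reliability ceiling mode
#'   (see [noise_corrected_correlation()]).
#' @param decoder_n_train,decoder_resamples,decoder_C Decoder-stage settings.
#' @param out_dir Optional output directory for [write_report()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(trials_a, trials_b, stimuli,
                            features_train = NULL, features_test = NULL,
                            seed = 1, min_trials = 20,
                            chance_rule = "binomial",
                            lapse_model = "always_wrong",
                            lapse_partitions = 50,
                            n_boot = 1000, n_partitions = 50,
                            subsample_k = 25,
                            denominator_mode = "geometric_mean",
                            decoder_n_train = 100, decoder_resamples = 100,
                            decoder_C = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "analysis_config")
}

load_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full image-level behavioral analysis pipeline
#'
#' Executes, for two observer pools on a shared stimulus set: subject
#' validation/exclusion, lapse estimation and lapse-corrected pooled
#' performance, global i1/i1n, per-condition mean d-prime (canonical
#' upright / inverted / contrast-reversed conditions), inversion and
#' contrast-reversal effect sizes with image-subsampling bootstrap CIs,
#' cross-pool effect comparisons, the noise-corrected i1n correlation
#' between the pools (overall and within each canonical condition), and —
#' when feature sets are supplied — the linear-readout model observer.
#' Deterministic given the config; rerunning writes byte-identical reports.
#'
#' @param config An [analysis_config()].
#' @return A `pipeline_report`: list with `report` (plain, JSON-ready
#'   summary), `i1n` (per-pool i1n vectors), `effects` (full effect
#'   estimates), `reliability`, `decoder`, `log`. If `config$out_dir` is set
#'   the bundle is also written there via [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  trials_a <- run_stage("read_trials_a", load_input(config$trials_a, read_trials_csv))
  trials_b <- run_stage("read_trials_b", load_input(config$trials_b, read_trials_csv))
  stimuli <- run_stage("read_stimuli", load_input(config$stimuli, read_stimulus_set))

  pools <- list(a = trials_a, b = trials_b)
  pool_names <- vapply(pools, function(tr) tr$pool_id[1], "")
  filtered <- list(); exclusions <- list()
  for (p in names(pools)) {
    f <- run_stage(paste0("filter_subjects_", p),
                   validate_and_filter_subjects(pools[[p]],
                                                min_trials = config$min_trials,
                                                chance_rule = config$chance_rule))
    filtered[[p]] <- f$trials
    exclusions[[p]] <- f$exclusions
    note("pool %s ('%s'): %d/%d trials kept, %d subject(s) excluded", p,
         pool_names[[p]], nrow(f$trials), nrow(pools[[p]]), nrow(f$exclusions))
  }

  lapses <- list(); perf <- list(); i1n <- list()
  for (p in names(filtered)) {
    lapses[[p]] <- run_stage(paste0("lapse_", p),
                             estimate_lapse(filtered[[p]],
                                            n_partitions = config$lapse_partitions,
                                            seed = child_seed(seed, match(p, names(filtered))),
                                            correction_model = config$lapse_model))
    perf[[p]] <- run_stage(paste0("performance_", p),
                           pooled_performance(filtered[[p]], n_boot = config$n_boot,
                                              seed = child_seed(seed, 10 + match(p, names(filtered))),
                                              lapse = lapses[[p]],
                                              model = config$lapse_model))
    i1n[[p]] <- run_stage(paste0("i1n_", p), compute_i1n(filtered[[p]]))
    note("pool %s: lapse %.4f, accuracy %.4f (raw %.4f)", p,
         lapses[[p]]$lapse, perf[[p]]$accuracy, perf[[p]]$accuracy_raw)
  }

  conds <- canonical_conditions()
  cond_means <- list(); effects <- list()
  for (p in names(filtered)) {
    cm <- lapply(conds, function(sp) {
      run_stage(paste0("condition_", sp$label, "_", p),
                condition_dprime(filtered[[p]], sp, stimuli))
    })
    cond_means[[p]] <- vapply(cm, function(x) x$mean_dprime, numeric(1))
    effects[[p]] <- list(
      inversion = run_stage(paste0("inversion_effect_", p),
                            effect_size(filtered[[p]], conds$upright, conds$inverted,
                                        stimuli, n_boot = config$n_boot,
                                        subsample_k = config$subsample_k,
                                        seed = child_seed(seed, 20 + match(p, names(filtered))))),
      reversal = run_stage(paste0("reversal_effect_", p),
                           effect_size(filtered[[p]], conds$upright, conds$reversed,
                                       stimuli, n_boot = config$n_boot,
                                       subsample_k = config$subsample_k,
                                       seed = child_seed(seed, 30 + match(p, names(filtered))))))
    note("pool %s: inversion delta d' %.3f [%.3f, %.3f], reversal %.3f [%.3f, %.3f]",
         p, effects[[p]]$inversion$delta_dprime, effects[[p]]$inversion$ci_low,
         effects[[p]]$inversion$ci_high, effects[[p]]$reversal$delta_dprime,
         effects[[p]]$reversal$ci_low, effects[[p]]$reversal$ci_high)
  }
  comparisons <- run_stage("compare_effects", list(
    inversion = compare_effects(effects$a$inversion, effects$b$inversion),
    reversal = compare_effects(effects$a$reversal, effects$b$reversal)))

  reliability <- run_stage("reliability",
                           noise_corrected_correlation(filtered$a, filtered$b,
                                                       n_partitions = config$n_partitions,
                                                       seed = child_seed(seed, 40),
                                                       denominator_mode = config$denominator_mode))
  note("overall r_nc = %.3f (r_cross %.3f, ceiling %.3f)", reliability$r_nc,
       reliability$r_cross, reliability$ceiling)
  per_condition_rnc <- lapply(conds, function(sp) {
    ids <- condition_images(sp, stimuli)
    run_stage(paste0("reliability_", sp$label),
              noise_corrected_correlation(
                filtered$a[filtered$a$image_id %in% ids, , drop = FALSE],
                filtered$b[filtered$b$image_id %in% ids, , drop = FALSE],
                n_partitions = config$n_partitions,
                seed = child_seed(seed, 41),
                denominator_mode = config$denominator_mode))
  })

  decoder <- NULL
  if (!is.null(config$features_train) && !is.null(config$features_test)) {
    ftr <- run_stage("read_features_train", load_input(config$features_train, read_feature_set))
    fte <- run_stage("read_features_test", load_input(config$features_test, read_feature_set))
    decoder <- run_stage("decoder",
                         train_readout(ftr, fte, config$decoder_n_train,
                                       n_resamples = config$decoder_resamples,
                                       C = config$decoder_C,
                                       seed = child_seed(seed, 50)))
    note("decoder: accuracy %.3f +/- %.3f", decoder$accuracy_mean, decoder$accuracy_sd)
  } else {
    note("decoder stage skipped: no feature sets supplied")
  }

  effect_row <- function(e) list(label_a = e$label_a, label_b = e$label_b,
                                 delta_dprime = e$delta_dprime,
                                 ci = c(e$ci_low, e$ci_high), n_boot = e$n_boot,
                                 subsample_k = e$subsample_k, seed = e$seed)
  report <- list(
    config = list(seed = seed, min_trials = config$min_trials,
                  chance_rule = config$chance_rule,
                  lapse_model = config$lapse_model,
                  lapse_partitions = config$lapse_partitions,
                  n_boot = config$n_boot, n_partitions = config$n_partitions,
                  subsample_k = config$subsample_k,
                  denominator_mode = config$denominator_mode),
    pools = lapply(stats::setNames(names(filtered), pool_names[names(filtered)]),
                   function(p) list(
                     pool_id = unname(pool_names[[p]]),
                     n_trials = nrow(filtered[[p]]),
                     n_subjects_excluded = nrow(exclusions[[p]]),
                     exclusions = exclusions[[p]],
                     lapse = lapses[[p]]$lapse,
                     accuracy = perf[[p]]$accuracy,
                     accuracy_raw = perf[[p]]$accuracy_raw,
                     accuracy_boot_sd = perf[[p]]$boot_sd,
                     condition_mean_dprime = as.list(cond_means[[p]]),
                     inversion = effect_row(effects[[p]]$inversion),
                     reversal = effect_row(effects[[p]]$reversal))),
    comparisons = lapply(comparisons, function(x) x[c("statistic", "p_value", "method")]),
    reliability = list(
      overall = reliability[c("r_cross", "r_internal_a", "r_internal_b",
                              "ceiling", "r_nc", "r_nc_geometric",
                              "r_nc_printed_sum", "n_partitions",
                              "denominator_mode", "n_images_used")],
      per_condition = lapply(per_condition_rnc, function(x)
        x[c("r_cross", "ceiling", "r_nc", "n_images_used")])),
    decoder = if (is.null(decoder)) list(skipped = TRUE) else
      list(skipped = FALSE, n_train_per_class = decoder$n_train_per_class,
           accuracy_mean = decoder$accuracy_mean,
           accuracy_sd = decoder$accuracy_sd,
           n_resamples = decoder$n_resamples))

  bundle <- structure(list(report = report, i1n = i1n, effects = effects,
                           reliability = reliability,
                           per_condition_rnc = per_condition_rnc,
                           decoder = decoder, log = log),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits `report.json` (the machine-readable summary), per-pool i1n tables
#' (`i1n_<pool>.csv`), and `log.txt`. All writes are atomic.
#'
#' @param bundle A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atomic_write(file.path(dir, "report.json"), function(tmp) {
    jsonlite::write_json(bundle$report, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  })
  for (p in names(bundle$i1n)) {
    write_i1_csv(bundle$i1n[[p]], file.path(dir, sprintf("i1n_%s.csv", p)))
  }
  atomic_write(file.path(dir, "log.txt"), function(tmp) {
    writeLines(bundle$log, tmp)
  })
  invisible(dir)
}
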