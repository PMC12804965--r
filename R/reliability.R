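#' Split a trial table into two stratified halves
#'
#' Each image's trials are shuffled and assigned alternately (with a random
#' starting side per image), so the two halves differ by at most one trial
#' per image and their union reproduces the input exactly.
#'
#' @param trials A trial table with >= 2 rows.
#' @param seed Integer seed.
#' @return List of two trial tables.
#' @export
split_trials <- function(trials, seed = 1) {
  n <- nrow(trials)
  if (n < 2L) stop("need at least 2 trials to split", call. = FALSE)
  img <- as.character(trials$image_id)
  with_seed(seed, {
    u <- stats::runif(n)
    ord <- order(img, u)
    r <- rle(img[ord])
    lens <- r$lengths
    starts <- cumsum(c(1L, lens[-length(lens)]))
    # The random starting side of each image comes from that image's own
    # uniform draws, so the assignment depends only on per-row randomness:
    # relabeling image ids consistently leaves the partition unchanged.
    offsets <- as.integer(floor(u[ord][starts] * 1e6)) %% 2L
    half_sorted <- (sequence(lens) + rep(offsets, lens)) %% 2L
    half <- integer(n)
    half[ord] <- half_sorted
    list(trials[half == 0L, , drop = FALSE],
         trials[half == 1L, , drop = FALSE])
  })
}

# i1n values keyed by image_id; NA for unscorable images.
i1n_by_image <- function(trials) {
  v <- compute_i1n(trials)
  stats::setNames(ifelse(v$unscorable, NA_real_, v$dprime), v$image_id)
}

# Pearson r over jointly finite entries; NA if undefined.
cor_common <- function(x, y) {
  ids <- intersect(names(x), names(y))
  a <- x[ids]; b <- y[ids]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])
}

#' Internal consistency of image-level performance
#'
#' The split-half reliability of the i1n vector within one observer pool:
#' trials are split into stratified halves, i1n is computed on each half, and
#' the Pearson correlation between the two half-vectors is averaged over
#' `n_partitions` random partitions. This is the ceiling a cross-pool
#' correlation could reach given trial-by-trial noise.
#'
#' @param trials A trial table.
#' @param n_partitions Number of random partitions to average over.
#' @param seed Integer seed.
#' @return Mean within-pool split-half correlation (NA if undefined, e.g. a
#'   single trial per image everywhere).
#' @export
internal_consistency <- function(trials, n_partitions = 100, seed = 1) {
  rs <- vapply(seq_len(n_partitions), function(p) {
    halves <- split_trials(trials, seed = child_seed(seed, p))
    cor_common(i1n_by_image(halves[[1]]), i1n_by_image(halves[[2]]))
  }, numeric(1))
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}

#' Noise-corrected correlation between two pools' image-level performance
#'
#' Measures how similar two observer pools' image-by-image performance
#' patterns (i1n vectors) are, corrected for the ceiling imposed by
#' trial-by-trial noise. Per random partition, each pool's trials are split
#' into stratified halves and i1n is computed on every half; the cross-pool
#' correlation is the mean of the two cross-half correlations
#' `r(Va0, Vb1)` and `r(Va1, Vb0)`, and each pool's internal consistency is
#' its within-pool half correlation. Averaged over `n_partitions`
#' partitions, the noise-corrected value is
#' `r_nc = r_cross / ceiling`, with the ceiling either the geometric mean
#' `sqrt(r_a * r_b)` (default; the standard split-half ceiling) or the
#' literal sum-under-the-radical form `sqrt(r_a + r_b)`
#' (`denominator_mode = "printed_sum"`). Both are reported.
#'
#' @param trials_a,trials_b Trial tables of the two pools. Only images scored
#'   in both tables are used; a warning is raised if that is a proper subset
#'   of either.
#' @param n_partitions Number of random partitions to average over.
#' @param seed Integer seed (the same split partitions are applied to both
#'   pools, so identical tables yield identical splits).
#' @param denominator_mode `"geometric_mean"` or `"printed_sum"`.
#' @return A `split_half_correlation`: list with `r_cross`, `r_internal_a`,
#'   `r_internal_b`, `ceiling`, `r_nc`, `r_nc_geometric`, `r_nc_printed_sum`,
#'   `per_partition` (data.frame of per-partition components),
#'   `n_partitions`, `denominator_mode`, `n_images_used`, `seed`.
#' @export
noise_corrected_correlation <- function(trials_a, trials_b,
                                        n_partitions = 100, seed = 1,
                                        denominator_mode = c("geometric_mean",
                                                             "printed_sum")) {
  denominator_mode <- match.arg(denominator_mode)
  ids_a <- unique(as.character(trials_a$image_id))
  ids_b <- unique(as.character(trials_b$image_id))
  common <- intersect(ids_a, ids_b)
  if (length(common) < 3L) stop("fewer than 3 images shared between pools", call. = FALSE)
  if (length(common) < length(ids_a) || length(common) < length(ids_b)) {
    warning(sprintf("pools share %d images; %d / %d pool-specific images dropped",
                    length(common), length(ids_a) - length(common),
                    length(ids_b) - length(common)), call. = FALSE)
    trials_a <- trials_a[trials_a$image_id %in% common, , drop = FALSE]
    trials_b <- trials_b[trials_b$image_id %in% common, , drop = FALSE]
  }
  per <- data.frame(partition = seq_len(n_partitions), r_cross = NA_real_,
                    r_internal_a = NA_real_, r_internal_b = NA_real_)
  for (p in seq_len(n_partitions)) {
    sp <- child_seed(seed, p)
    ha <- split_trials(trials_a, seed = sp)
    hb <- split_trials(trials_b, seed = sp)
    va0 <- i1n_by_image(ha[[1]]); va1 <- i1n_by_image(ha[[2]])
    vb0 <- i1n_by_image(hb[[1]]); vb1 <- i1n_by_image(hb[[2]])
    per$r_cross[p] <- mean(c(cor_common(va0, vb1), cor_common(va1, vb0)))
    per$r_internal_a[p] <- cor_common(va0, va1)
    per$r_internal_b[p] <- cor_common(vb0, vb1)
  }
  r_cross <- mean(per$r_cross, na.rm = TRUE)
  r_a <- mean(per$r_internal_a, na.rm = TRUE)
  r_b <- mean(per$r_internal_b, na.rm = TRUE)
  ceil_geo <- if (!is.na(r_a) && !is.na(r_b) && r_a > 0 && r_b > 0) sqrt(r_a * r_b) else NA_real_
  ceil_sum <- if (!is.na(r_a) && !is.na(r_b) && (r_a + r_b) > 0) sqrt(r_a + r_b) else NA_real_
  r_nc_geo <- r_cross / ceil_geo
  r_nc_sum <- r_cross / ceil_sum
  ceiling <- if (denominator_mode == "geometric_mean") ceil_geo else ceil_sum
  r_nc <- if (denominator_mode == "geometric_mean") r_nc_geo else r_nc_sum
  if (is.na(ceiling)) {
    warning("internal-consistency ceiling is undefined or non-positive; r_nc is NA",
            call. = FALSE)
  }
  structure(list(r_cross = r_cross, r_internal_a = r_a, r_internal_b = r_b,
                 ceiling = ceiling, r_nc = r_nc, r_nc_geometric = r_nc_geo,
                 r_nc_printed_sum = r_nc_sum, per_partition = per,
                 n_partitions = n_partitions,
                 denominator_mode = denominator_mode,
                 n_images_used = length(common), seed = seed),
            class = "split_half_correlation")
}

#' @export
print.split_half_correlation <- function(x, ...) {
  cat(sprintf(paste0("split-half correlation over %d images (%d partitions)\n",
                     "  r_cross = %.3f, internal a = %.3f, b = %.3f\n",
                     "  r_nc = %.3f (%s ceiling %.3f)\n"),
              x$n_images_used, x$n_partitions, x$r_cross, x$r_internal_a,
              x$r_internal_b, x$r_nc, x$denominator_mode, x$ceiling))
  invisible(x)
}
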