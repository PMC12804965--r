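#' Generate a synthetic stimulus set
#'
#' Builds the metadata table for a two-category image set with fully crossed
#' viewing contexts: 2 in-plane orientations (upright, inverted) x 3 lighting
#' contexts (lit from above, lit from below, contrast reversed) per category,
#' `n_per_context` images in each context, plus one canonical "token" image
#' per category (upright, lit from above, frontal view, no background).
#' Latent rendering parameters are drawn i.i.d. uniform: size 4.5-9 degrees
#' visual angle, azimuth -90 to +90 degrees, elevation -45 to +45 degrees;
#' each non-token image gets one of 10 shared backgrounds.
#'
#' With the default `n_per_context = 25` this yields 151 images per category
#' (150 context images + 1 token), 302 in total.
#'
#' @param n_per_context Non-negative integer, images per (category,
#'   orientation, lighting) context.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `stimulus_set`: a data.frame with columns `image_id`, `category`
#'   ("A"/"B"), `orientation` ("upright"/"inverted"), `lighting`
#'   ("above"/"below"/"reversed"), `size_deg`, `azimuth_deg`, `elevation_deg`,
#'   `background_id` (0-9; -1 for tokens), `is_token`. Generator parameters
#'   are kept in `attr(, "params")`.
#' @examples
#' stim <- generate_stimulus_set(n_per_context = 25, seed = 1)
#' nrow(stim)            # 302
#' table(stim$category)  # 151 each
#' @export
generate_stimulus_set <- function(n_per_context = 25, seed = 1) {
  if (length(n_per_context) != 1L || is.na(n_per_context) || n_per_context < 0 ||
      n_per_context != floor(n_per_context)) {
    stop("`n_per_context` must be a single non-negative integer", call. = FALSE)
  }
  n_per_context <- as.integer(n_per_context)
  with_seed(seed, {
  categories <- c("A", "B")
  orientations <- c("upright", "inverted")
  lightings <- c("above", "below", "reversed")

  grid <- expand.grid(category = categories, orientation = orientations,
                      lighting = lightings, stringsAsFactors = FALSE)
  n_ctx_images <- nrow(grid) * n_per_context

  rows <- vector("list", nrow(grid) + 2L)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (n_per_context == 0L) next
    idx <- seq_len(n_per_context)
    rows[[i]] <- data.frame(
      image_id = sprintf("%s_%s_%s_%03d", g$category, g$orientation, g$lighting, idx),
      category = g$category,
      orientation = g$orientation,
      lighting = g$lighting,
      size_deg = runif(n_per_context, 4.5, 9.0),
      azimuth_deg = runif(n_per_context, -90, 90),
      elevation_deg = runif(n_per_context, -45, 45),
      background_id = sample.int(10L, n_per_context, replace = TRUE) - 1L,
      is_token = FALSE,
      stringsAsFactors = FALSE
    )
  }
  tokens <- data.frame(
    image_id = sprintf("%s_token", categories),
    category = categories,
    orientation = "upright",
    lighting = "above",
    size_deg = 9.0,
    azimuth_deg = 0,
    elevation_deg = 0,
    background_id = -1L,
    is_token = TRUE,
    stringsAsFactors = FALSE
  )
  out <- rbind(do.call(rbind, rows[seq_len(nrow(grid))]), tokens)
  rownames(out) <- NULL
  structure(out,
            params = list(n_per_context = n_per_context, seed = seed,
                          n_images = n_ctx_images + 2L),
            class = c("stimulus_set", "data.frame"))
  })
}

#' Context label of stimulus images
#'
#' A context is an (orientation, lighting) pair, e.g. `"upright_above"`.
#'
#' @param stimuli A `stimulus_set` (or any data.frame with `orientation` and
#'   `lighting` columns).
#' @return Character vector, one label per image.
#' @export
context_label <- function(stimuli) {
  paste(stimuli$orientation, stimuli$lighting, sep = "_")
}

#' Lighting congruency of stimulus images
#'
#' An image is lighting-congruent when its light source is overhead in world
#' coordinates: upright faces lit from above, or inverted faces lit from
#' below (the rendered "below" light is overhead once the image is flipped).
#' Contrast-reversed images are neither.
#'
#' @inheritParams context_label
#' @return Logical vector (NA for contrast-reversed images).
#' @export
lighting_congruent <- function(stimuli) {
  ifelse(stimuli$lighting == "reversed", NA,
         (stimuli$orientation == "upright" & stimuli$lighting == "above") |
           (stimuli$orientation == "inverted" & stimuli$lighting == "below"))
}

#' Write / read a stimulus set as delimited text
#'
#' The table is written as CSV with exactly the columns
#' `image_id, category, orientation, lighting, size_deg, azimuth_deg,
#' elevation_deg, background_id, is_token`, and the generator parameters to a
#' JSON sidecar `<path>.json`.
#'
#' @param stimuli A `stimulus_set`.
#' @param path Output CSV path.
#' @return `write_stimulus_set` returns `path` invisibly; `read_stimulus_set`
#'   returns the `stimulus_set`.
#' @export
write_stimulus_set <- function(stimuli, path) {
  cols <- c("image_id", "category", "orientation", "lighting", "size_deg",
            "azimuth_deg", "elevation_deg", "background_id", "is_token")
  utils::write.csv(as.data.frame(stimuli)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  params <- attr(stimuli, "params")
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("image_id", "category", "orientation", "lighting", "size_deg",
            "azimuth_deg", "elevation_deg", "background_id", "is_token")
  missing <- setdiff(cols, names(out))
  if (length(missing)) {
    stop("stimulus table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$is_token <- as.logical(out$is_token)
  sidecar <- paste0(path, ".json")
  params <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  structure(out, params = params, class = c("stimulus_set", "data.frame"))
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state after.
# All randomized operations take explicit seeds and route through this, so no
# function mutates the user-visible random stream.
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed)) stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, kept inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(k)) %% 2147483647)
}
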