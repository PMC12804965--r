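TRIAL_COLUMNS <- c("subject_id", "pool_id", "image_id", "true_category",
                   "response_category", "session")

#' Read / write a trial table as delimited text
#'
#' The file must carry the header
#' `subject_id,pool_id,image_id,true_category,response_category,session`.
#' Unknown extra columns are preserved (with a warning on read); a missing
#' required column is an error naming it; malformed category tokens are
#' errors citing the offending file line. Writes are atomic (temp file +
#' rename).
#'
#' @param path CSV path.
#' @return `read_trials_csv()` returns the trial table (data.frame);
#'   `write_trials_csv()` returns `path` invisibly.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing)) {
    stop("trial file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(out), TRIAL_COLUMNS)
  if (length(extra)) {
    warning("extra column(s) preserved but ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(out$true_category %in% c("A", "B")) |
                 !(out$response_category %in% c("A", "B")))
  if (length(bad)) {
    stop("malformed category token at file line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         " (expected 'A' or 'B')", call. = FALSE)
  }
  out[, c(TRIAL_COLUMNS, extra), drop = FALSE]
}

#' @rdname read_trials_csv
#' @param trials A trial table.
#' @export
write_trials_csv <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(trials), TRIAL_COLUMNS)
  atomic_write(path, function(tmp) {
    utils::write.csv(trials[, c(TRIAL_COLUMNS, extra), drop = FALSE], tmp,
                     row.names = FALSE, quote = FALSE)
  })
  invisible(path)
}

#' Export an i1 / i1n vector as a delimited table
#'
#' @param i1 An `i1_vector` or `i1n_vector`.
#' @param path Output CSV path.
#' @export
write_i1_csv <- function(i1, path) {
  stopifnot(inherits(i1, "i1_vector"))
  atomic_write(path, function(tmp) {
    utils::write.csv(as.data.frame(i1), tmp, row.names = FALSE, quote = FALSE)
  })
  invisible(path)
}

# Write via a temp file in the destination directory, then rename.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}
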