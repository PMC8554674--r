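#' Read epoch-level activity counts from CSV
#'
#' Reads the package's epoch CSV dialect: a UTF-8 file with a header row
#' and columns `subject_id`, `day_index`, `epoch_index`, `count`.
#' `epoch_index` is 0-based, running `0 .. epochs_per_day - 1` within each
#' day. Each subject's rows must describe complete days: a day with a
#' number of rows different from `epochs_per_day` (including a partial
#' trailing day) is rejected.
#'
#' @param path Path to the CSV file.
#' @param epoch_seconds Epoch length in seconds (default 60).
#' @return A list of [epoch_series()] objects, one per subject, in order of
#'   first appearance in the file.
#' @seealso [write_epoch_csv()]
#' @export
read_epoch_csv <- function(path, epoch_seconds = 60L) {
  if (!file.exists(path))
    stop_format(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, colClasses = list(character = "subject_id"),
                          showProgress = FALSE)
  required <- c("subject_id", "day_index", "epoch_index", "count")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop_format(sprintf("epoch CSV is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  if (!is.numeric(dt$count))
    stop_format("column 'count' is not numeric")
  if (anyNA(dt$count) || any(dt$count < 0))
    stop_validation("column 'count' contains NA or negative values")
  epoch_seconds <- as.integer(epoch_seconds)
  epd <- 86400L %/% epoch_seconds

  data.table::setorderv(dt, c("day_index", "epoch_index"))
  subjects <- unique(dt$subject_id)
  out <- vector("list", length(subjects))
  names(out) <- subjects
  for (sid in subjects) {
    sub <- dt[dt$subject_id == sid, ]
    per_day <- table(sub$day_index)
    bad <- which(per_day != epd)
    if (length(bad))
      stop_validation(sprintf(
        "subject %s, day %s: %d row(s); expected %d epochs per day",
        sid, names(per_day)[bad[1L]], as.integer(per_day[bad[1L]]), epd))
    expected_idx <- rep(0:(epd - 1L), times = length(per_day))
    if (!all(sub$epoch_index == expected_idx))
      stop_validation(sprintf(
        "subject %s: epoch_index must run 0..%d within each day", sid, epd - 1L))
    out[[sid]] <- epoch_series(sid, sub$count, epoch_seconds = epoch_seconds)
  }
  out
}

#' Write epoch-level activity counts to CSV
#'
#' Inverse of [read_epoch_csv()]. Integer-valued counts are written as
#' integers; fractional counts are written with `%.17g` so that the
#' round-trip `read_epoch_csv(write_epoch_csv(x))` reproduces counts
#' exactly (and output is byte-stable across runs).
#'
#' @param cohort A single [epoch_series()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(cohort, path) {
  if (inherits(cohort, "epoch_series")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1L, all(vapply(cohort, inherits, TRUE, "epoch_series")))
  tabs <- lapply(cohort, function(s) {
    nd <- n_days(s)
    epd <- s$epochs_per_day
    data.table::data.table(
      subject_id = s$subject_id,
      day_index = rep(s$day_map, each = epd),
      epoch_index = rep(0:(epd - 1L), times = nd),
      count = fmt_num(s$counts))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, quote = FALSE)
  invisible(path)
}

# Exact, byte-stable numeric formatting: integers plainly, others %.17g.
fmt_num <- function(x) {
  out <- character(length(x))
  int <- !is.na(x) & x == round(x) & abs(x) < 2^53
  out[int] <- sprintf("%.0f", x[int])
  out[!int] <- sprintf("%.17g", x[!int])
  out
}
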