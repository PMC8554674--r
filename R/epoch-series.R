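#' Epoch-level activity-count series for one subject
#'
#' Container for a single subject's actigraphy record: one nonnegative
#' activity count per fixed epoch (default one minute), stored as complete
#' recording days. `day_flags` marks, over the *original* recording days,
#' which days are retained (wear days); `counts` holds only the retained
#' days, concatenated in original order.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param counts Numeric vector of nonnegative activity counts; its length
#'   must be a whole number of days (`epochs_per_day = 86400/epoch_seconds`).
#' @param epoch_seconds Epoch length in seconds; must divide 86400 evenly.
#'   The default 60 matches the usual one-minute actigraphy export.
#' @param day_flags Logical vector over the original recording days, `TRUE`
#'   for retained days. Defaults to all `TRUE` (nothing removed yet). The
#'   number of `TRUE` entries must equal `length(counts)/epochs_per_day`.
#'
#' @return An object of class `"epoch_series"`: a list with elements
#'   `subject_id`, `epoch_seconds`, `epochs_per_day`, `counts`, `day_flags`
#'   and `day_map` (original index of each retained day).
#' @seealso [clean_nonwear_days()], [daily_profile()], [read_epoch_csv()]
#' @export
#' @examples
#' s <- epoch_series("s1", rep(5, 2880))
#' n_days(s)
epoch_series <- function(subject_id, counts, epoch_seconds = 60L,
                         day_flags = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id))
    stop_validation("subject_id must be a single non-NA string")
  epoch_seconds <- as.integer(epoch_seconds)
  if (is.na(epoch_seconds) || epoch_seconds <= 0L || 86400L %% epoch_seconds != 0L)
    stop_validation("epoch_seconds must be a positive integer dividing 86400")
  epochs_per_day <- 86400L %/% epoch_seconds
  counts <- as.numeric(counts)
  if (anyNA(counts))
    stop_validation(sprintf("subject %s: counts contain NA", subject_id))
  if (any(counts < 0))
    stop_validation(sprintf("subject %s: negative activity counts", subject_id))
  if (length(counts) == 0L || length(counts) %% epochs_per_day != 0L)
    stop_validation(sprintf(
      "subject %s: length(counts) = %d is not a positive multiple of %d epochs/day",
      subject_id, length(counts), epochs_per_day))
  nd <- length(counts) %/% epochs_per_day
  if (is.null(day_flags)) day_flags <- rep(TRUE, nd)
  if (!is.logical(day_flags) || anyNA(day_flags))
    stop_validation("day_flags must be logical without NA")
  if (sum(day_flags) != nd)
    stop_validation(sprintf(
      "subject %s: day_flags retains %d days but counts span %d days",
      subject_id, sum(day_flags), nd))
  structure(
    list(subject_id = subject_id,
         epoch_seconds = epoch_seconds,
         epochs_per_day = epochs_per_day,
         counts = counts,
         day_flags = day_flags,
         day_map = which(day_flags)),
    class = "epoch_series")
}

#' Number of retained days in an epoch series
#'
#' @param series An [epoch_series()] object.
#' @return Integer count of retained (wear) days.
#' @export
n_days <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  length(series$counts) %/% series$epochs_per_day
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> subject %s: %d retained day(s) of %d original, %d-s epochs (%d epochs/day)\n",
    x$subject_id, n_days(x), length(x$day_flags), x$epoch_seconds,
    x$epochs_per_day))
  invisible(x)
}

# counts as an epochs_per_day x n_days matrix (one column per retained day)
day_matrix <- function(series) {
  matrix(series$counts, nrow = series$epochs_per_day)
}

#' Remove nonwear days from an epoch series
#'
#' A recording day is flagged as nonwear and removed when the fraction of
#' its epochs with zero counts is at least `zero_fraction_threshold`. This
#' operationalizes the usual visual criterion -- long straight stretches of
#' zero counts -- as a reproducible per-day rule: sedentary or sleep periods
#' still produce occasional nonzero counts, whereas a device left on the
#' table produces (almost) all zeros. Retained days are concatenated in
#' their original order; the returned series' `day_flags`/`day_map` map the
#' new day indices back to the original recording days.
#'
#' Cleaning is idempotent and never alters counts within retained days.
#'
#' @param series An [epoch_series()] object.
#' @param zero_fraction_threshold Number in \[0, 1\]: a day whose zero-count
#'   fraction is `>=` this value is removed. Default 0.95.
#' @return A cleaned [epoch_series()].
#' @export
#' @examples
#' x <- epoch_series("s1", c(rep(3, 1440), rep(0, 1440), rep(2, 1440)))
#' clean_nonwear_days(x)$day_map # days 1 and 3 survive
clean_nonwear_days <- function(series, zero_fraction_threshold = 0.95) {
  stopifnot(inherits(series, "epoch_series"))
  if (!is.numeric(zero_fraction_threshold) || length(zero_fraction_threshold) != 1L ||
      is.na(zero_fraction_threshold) || zero_fraction_threshold < 0 ||
      zero_fraction_threshold > 1)
    stop_validation("zero_fraction_threshold must be a number in [0, 1]")
  m <- day_matrix(series)
  zero_frac <- colMeans(m == 0)
  keep <- zero_frac < zero_fraction_threshold
  if (!any(keep))
    stop_validation(sprintf(
      "subject %s: all %d day(s) flagged nonwear; subject must be excluded",
      series$subject_id, ncol(m)))
  flags <- series$day_flags
  flags[series$day_map[!keep]] <- FALSE
  epoch_series(series$subject_id,
               as.numeric(m[, keep, drop = FALSE]),
               epoch_seconds = series$epoch_seconds,
               day_flags = flags)
}

#' Day-averaged activity profile
#'
#' Averages the counts at each within-day epoch over all retained days,
#' giving the subject's mean 24-hour activity profile.
#'
#' @param series An [epoch_series()] object with at least one retained day.
#' @return Numeric vector of length `epochs_per_day`.
#' @export
daily_profile <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  if (n_days(series) < 1L)
    stop_validation("daily_profile requires at least one retained day")
  rowMeans(day_matrix(series))
}
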