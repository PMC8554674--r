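#' Fourier period grid for a fixed record length
#'
#' For a record of `record_days` whole days sampled at `epochs_per_day`
#' epochs per day, the one-sided discrete Fourier frequencies are
#' `k = 1 .. floor(L/2)` cycles per record, `L = record_days *
#' epochs_per_day`. Bin `k` corresponds to a period of
#' `record_days * 1440 / k` minutes, so the day harmonics (1440, 720, 480,
#' 360, ... minutes) sit exactly on the grid whenever `k` is a multiple of
#' `record_days`.
#'
#' @param record_days Number of whole recording days (D >= 1).
#' @param epochs_per_day Epochs per day (default 1440, i.e. 1-minute epochs).
#' @return Strictly decreasing numeric vector of periods in minutes,
#'   one per one-sided frequency bin.
#' @export
#' @examples
#' head(period_grid(7)) # 10080, 5040, 3360, 2520, 2016, 1680
#' period_grid(7)[7]    # 1440: the one-day harmonic
period_grid <- function(record_days, epochs_per_day = 1440L) {
  record_days <- as.integer(record_days)
  if (is.na(record_days) || record_days < 1L)
    stop_validation("record_days must be a positive integer")
  L <- record_days * as.integer(epochs_per_day)
  k <- seq_len(L %/% 2L)
  (record_days * 1440) / k
}

#' Cohort periodicity-signal matrix from the discrete Fourier transform
#'
#' Builds the n x p matrix X of "FFT signals": entry (i, j) is the
#' amplitude-scaled modulus `(2/L) * |c_k|` of subject i's DFT coefficient
#' at bin `k_j`, computed from the subject's first `target_days` retained
#' days after mean-centering. With this normalization a pure cosine of
#' amplitude `a` at a grid frequency yields a signal of exactly `a`, which
#' is what makes the signals interchangeable with least-squares cosinor
#' amplitudes (see [cosinor_amplitudes()]). Mean-centering removes only the
#' zero-frequency bin; the series itself is otherwise analyzed as recorded,
#' so non-24-hour structure is preserved.
#'
#' All subjects are truncated to a common `target_days` so every row shares
#' one period grid. Note that at the Nyquist bin (`k = L/2`, even `L`) the
#' 2/L scaling doubles the cosine amplitude; that bin is rarely of interest
#' and can be dropped with `min_period`.
#'
#' @param cohort A single [epoch_series()] or list of them (already cleaned
#'   of nonwear days).
#' @param target_days Number of retained days to analyze per subject.
#'   Default: the minimum retained-day count across the cohort. Subjects
#'   with fewer retained days than `target_days` trigger an error naming
#'   them.
#' @param min_period,max_period Optional period filter (minutes): columns
#'   with periods outside `[min_period, max_period]` are dropped after the
#'   transform.
#' @return An object of class `"spectrum_matrix"`: list with
#'   `subject_ids`, `periods` (minutes, strictly decreasing), `magnitudes`
#'   (n x p matrix), `record_days`, `epoch_seconds`, `epochs_per_day`.
#' @export
compute_spectrum <- function(cohort, target_days = NULL,
                             min_period = NULL, max_period = NULL) {
  if (inherits(cohort, "epoch_series")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1L, all(vapply(cohort, inherits, TRUE, "epoch_series")))
  es <- vapply(cohort, `[[`, 1L, "epoch_seconds")
  if (length(unique(es)) != 1L)
    stop_validation("all subjects must share one epoch length")
  epd <- cohort[[1L]]$epochs_per_day
  days <- vapply(cohort, n_days, 1L)
  if (is.null(target_days)) target_days <- min(days)
  target_days <- as.integer(target_days)
  if (target_days < 1L) stop_validation("target_days must be >= 1")
  short <- days < target_days
  if (any(short))
    stop_validation(sprintf(
      "subject(s) with fewer than %d retained days: %s",
      target_days,
      paste(vapply(cohort[short], `[[`, "", "subject_id"), collapse = ", ")))

  L <- target_days * epd
  p <- L %/% 2L
  n <- length(cohort)
  mags <- matrix(0, n, p)
  for (i in seq_len(n)) {
    x <- cohort[[i]]$counts[seq_len(L)]
    x <- x - mean(x)
    ft <- stats::fft(x)
    mags[i, ] <- (2 / L) * Mod(ft[2:(p + 1L)])
  }
  periods <- period_grid(target_days, epd)
  keep <- rep(TRUE, p)
  if (!is.null(min_period)) keep <- keep & periods >= min_period
  if (!is.null(max_period)) keep <- keep & periods <= max_period
  if (!any(keep)) stop_validation("period filter removed every frequency bin")
  structure(
    list(subject_ids = vapply(cohort, `[[`, "", "subject_id"),
         periods = periods[keep],
         magnitudes = mags[, keep, drop = FALSE],
         record_days = target_days,
         epoch_seconds = cohort[[1L]]$epoch_seconds,
         epochs_per_day = epd),
    class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectrum_matrix> %d subject(s) x %d periodicities, %d-day records (%d-s epochs)\n",
    nrow(x$magnitudes), ncol(x$magnitudes), x$record_days, x$epoch_seconds))
  invisible(x)
}

#' Proportion of spectral variance per periodicity
#'
#' Normalizes squared periodicity signals so they sum to one:
#' `fraction_j = m_j^2 / sum_l m_l^2`. Applied to a subject's row of the
#' spectrum matrix this is the proportion of (mean-centered) variance
#' attributable to each periodicity, the usual way dominance of, say, the
#' one-day band is quantified.
#'
#' @param x Numeric vector of nonnegative magnitudes, or a matrix /
#'   [compute_spectrum()] result (applied row-wise).
#' @return Vector (or matrix) of fractions summing to 1 per row.
#' @export
variance_fractions <- function(x) {
  if (inherits(x, "spectrum_matrix")) x <- x$magnitudes
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, variance_fractions))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (any(x < 0)) stop_validation("magnitudes must be nonnegative")
  total <- sum(x^2)
  if (total == 0)
    stop_validation("variance fractions undefined for an all-zero row")
  x^2 / total
}

#' Least-squares cosinor amplitudes at one grid period
#'
#' Fits, per subject, the single-component cosinor model
#' `counts_t ~ m + A cos(2 pi t / T) + B sin(2 pi t / T)` by least squares
#' over the first `target_days` retained days and returns the amplitude
#' `sqrt(A^2 + B^2)`. At a Fourier grid period the cosine/sine regressors
#' are orthogonal to each other and to the intercept, so this amplitude
#' equals the `(2/L)`-scaled DFT modulus of [compute_spectrum()] exactly:
#' the two routes to a "periodicity signal" coincide (Pearson correlation 1
#' across subjects). Off-grid periods are rejected because the equivalence
#' (and the orthogonality that linearizes the fit) holds only at Fourier
#' frequencies.
#'
#' @inheritParams compute_spectrum
#' @param period_minutes Period of the fitted cosine, in minutes; must equal
#'   `target_days * 1440 / k` for an integer bin `1 <= k < L/2`.
#' @return Numeric vector of amplitudes, one per subject.
#' @export
cosinor_amplitudes <- function(cohort, period_minutes, target_days = NULL) {
  if (inherits(cohort, "epoch_series")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1L, all(vapply(cohort, inherits, TRUE, "epoch_series")))
  epd <- cohort[[1L]]$epochs_per_day
  days <- vapply(cohort, n_days, 1L)
  if (is.null(target_days)) target_days <- min(days)
  target_days <- as.integer(target_days)
  if (any(days < target_days))
    stop_validation("every subject needs at least target_days retained days")
  L <- target_days * epd
  total_min <- target_days * 1440
  k <- total_min / period_minutes
  if (abs(k - round(k)) > .grid_tol || round(k) < 1 || round(k) >= L / 2)
    stop_validation(sprintf(
      "period %.6g min is not a (non-Nyquist) Fourier grid period of a %d-day record",
      period_minutes, target_days))
  epoch_min <- cohort[[1L]]$epoch_seconds / 60
  t_min <- (0:(L - 1L)) * epoch_min
  design <- cbind(1, cos(2 * pi * t_min / period_minutes),
                  sin(2 * pi * t_min / period_minutes))
  qrd <- qr(design)
  y <- vapply(cohort, function(s) s$counts[seq_len(L)], numeric(L))
  coefs <- qr.coef(qrd, y) # 3 x n
  sqrt(coefs[2L, ]^2 + coefs[3L, ]^2)
}

#' Reconstruct a series from its top periodicity bins
#'
#' Keeps the `n_bins` one-sided frequency bins with the largest DFT
#' modulus (phases taken from the DFT itself), zeroes the rest, and
#' inverts the transform. For a noiseless sum of `K` grid cosines the
#' top-`K` reconstruction reproduces the mean-centered series; on real
#' data it visualizes the activity pattern implied by the dominant
#' periodicities (e.g. a two-peak, one-nap day from the combined half-day
#' and one-third-day bands).
#'
#' @param series An [epoch_series()] object.
#' @param n_bins Number of one-sided bins to retain.
#' @param target_days Days to analyze (default: all retained days).
#' @return Numeric vector of length `L`: the mean-centered reconstruction.
#' @export
reconstruct_top_bins <- function(series, n_bins, target_days = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(target_days)) target_days <- n_days(series)
  L <- as.integer(target_days) * series$epochs_per_day
  if (n_days(series) < target_days)
    stop_validation("series has fewer retained days than target_days")
  n_bins <- as.integer(n_bins)
  p <- L %/% 2L
  if (n_bins < 1L || n_bins > p)
    stop_validation("n_bins must be between 1 and floor(L/2)")
  x <- series$counts[seq_len(L)]
  x <- x - mean(x)
  ft <- stats::fft(x)
  mag <- Mod(ft[2:(p + 1L)])
  top <- order(mag, decreasing = TRUE)[seq_len(n_bins)]
  keep <- rep(FALSE, L)
  keep[1L + top] <- TRUE                 # one-sided bins k
  mirror <- L + 1L - top                 # conjugate bins L - k
  keep[mirror[mirror >= 1L & mirror <= L]] <- TRUE
  ft[!keep] <- 0
  Re(stats::fft(ft, inverse = TRUE)) / L
}

#' Write / read a spectrum matrix as CSV
#'
#' First column `subject_id`, remaining columns named by period in minutes
#' to three decimals. Magnitudes are written with `%.17g` (exact
#' round-trip).
#'
#' @param X A [compute_spectrum()] result.
#' @param path File path.
#' @return `path` (write) / a `"spectrum_matrix"` (read), invisibly for write.
#' @export
write_spectrum_csv <- function(X, path) {
  stopifnot(inherits(X, "spectrum_matrix"))
  mags <- X$magnitudes
  vals <- lapply(seq_len(ncol(mags)), function(j) fmt_num(mags[, j]))
  names(vals) <- sprintf("%.3f", X$periods)
  dt <- data.table::as.data.table(c(list(subject_id = X$subject_ids), vals))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param epoch_seconds Epoch length of the original records (metadata only).
#' @export
read_spectrum_csv <- function(path, epoch_seconds = 60L) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, showProgress = FALSE,
                          colClasses = list(character = "subject_id"))
  if (!"subject_id" %in% names(dt))
    stop_format("spectrum CSV is missing column 'subject_id'")
  periods <- suppressWarnings(as.numeric(setdiff(names(dt), "subject_id")))
  if (anyNA(periods) || is.unsorted(rev(periods), strictly = TRUE))
    stop_format("spectrum CSV columns must be strictly decreasing periods in minutes")
  mags <- as.matrix(dt[, setdiff(names(dt), "subject_id"), with = FALSE])
  dimnames(mags) <- NULL
  record_days <- periods[1L] / 1440
  structure(
    list(subject_ids = dt$subject_id,
         periods = periods,
         magnitudes = mags,
         record_days = if (abs(record_days - round(record_days)) < .grid_tol)
           as.integer(round(record_days)) else NA_integer_,
         epoch_seconds = as.integer(epoch_seconds),
         epochs_per_day = 86400L %/% as.integer(epoch_seconds)),
    class = "spectrum_matrix")
}
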