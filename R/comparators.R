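#' Exact p-value of Fisher's g-test in harmonic analysis
#'
#' Fisher's g statistic is the largest periodogram ordinate divided by the
#' ordinate sum. Under the Gaussian white-noise null the N one-sided
#' (non-Nyquist) ordinates are iid exponential and the exact tail
#' probability is the alternating inclusion-exclusion series
#' \deqn{P(G > g) = \sum_{j=1}^{\lfloor 1/g \rfloor} (-1)^{j-1}
#'   \binom{N}{j} (1 - jg)^{N-1}.}
#' Terms are evaluated in log space; the summation is numerically exact
#' whenever the largest term is moderate, which covers the whole region
#' where the p-value is small enough to matter. The series only becomes
#' ill-conditioned for g far below the detection range, where the union
#' bound structure gives `P = 1 - exp(-mu)` with `mu >> 1`; the function
#' then returns 1 (correct to well below double precision).
#'
#' @param g Observed g statistic, in `[1/n_ordinates, 1]`.
#' @param n_ordinates Number of periodogram ordinates N (>= 2).
#' @return The p-value, clipped to \[0, 1\].
#' @export
#' @examples
#' fisher_g_pvalue(0.5, 5) # 5 * 0.5^4 = 0.3125
fisher_g_pvalue <- function(g, n_ordinates) {
  N <- as.integer(n_ordinates)
  if (is.na(N) || N < 2L) stop_validation("n_ordinates must be an integer >= 2")
  if (!is.numeric(g) || length(g) != 1L || is.na(g))
    stop_validation("g must be a single number")
  if (g < 1 / N - 1e-12 || g > 1 + 1e-12)
    stop_validation(sprintf("g = %.6g outside [1/N, 1] for N = %d", g, N))
  g <- min(max(g, 1 / N), 1)
  if (g == 1) return(0)
  jmax <- min(N, floor(1 / g + 1e-12))
  j <- seq_len(jmax)
  log_terms <- lchoose(N, j) + (N - 1) * log1p(-pmin(j * g, 1))
  if (max(log_terms) > log(1e15)) return(1) # degenerate regime, p = 1 - O(1e-13)
  s <- sum((-1)^(j - 1) * exp(log_terms))
  min(max(s, 0), 1)
}

#' Sequential Fisher g-test with Bonferroni correction
#'
#' Tests periodogram ordinates for significance in decreasing order. At
#' step s the g statistic is the largest remaining ordinate over the sum
#' of the remaining ordinates, with `N_s = p - s + 1` ordinates left; the
#' critical value therefore changes at every step. A step is significant
#' when its exact p-value is at most `alpha / correction_p` (Bonferroni).
#' On significance the ordinate is removed and the next one is tested;
#' the first nonsignificant step stops the procedure and is returned as
#' the final row.
#'
#' The remove-and-renormalize recursion is the classical extension of
#' Fisher's test to ordered ordinates; each step conditions on the
#' removal of the previously declared periodicities.
#'
#' @param ordinates Positive periodogram ordinates (squared magnitudes;
#'   e.g. [pool_ordinates()] for a cohort-level test).
#' @param period_labels Periods (minutes) labelling the ordinates; default
#'   the ordinate index.
#' @param alpha Nominal significance level (default 0.05).
#' @param correction_p Bonferroni divisor; defaults to the number of
#'   ordinates tested. Set to 1 for an uncorrected test.
#' @param max_steps Cap on the number of steps (default `length(ordinates)
#'   - 1`).
#' @return A `data.frame` of class `"fisher_steps"` with columns `rank`,
#'   `period_minutes`, `g_statistic`, `n_remaining`, `p_value`,
#'   `threshold`, `significant`.
#' @export
sequential_fisher <- function(ordinates, period_labels = seq_along(ordinates),
                              alpha = 0.05, correction_p = length(ordinates),
                              max_steps = length(ordinates) - 1L) {
  ordinates <- as.numeric(ordinates)
  if (length(ordinates) < 2L)
    stop_validation("need at least two ordinates")
  if (anyNA(ordinates) || any(ordinates <= 0))
    stop_validation("ordinates must be positive")
  if (length(period_labels) != length(ordinates))
    stop_validation("period_labels must match ordinates in length")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be in (0, 1)")
  if (correction_p < 1) stop_validation("correction_p must be >= 1")
  threshold <- alpha / correction_p

  remaining <- rep(TRUE, length(ordinates))
  rows <- list()
  step <- 0L
  while (sum(remaining) >= 2L && step < max_steps) {
    step <- step + 1L
    idx <- which(remaining)
    o <- ordinates[idx]
    top <- idx[which.max(o)] # stable: first max = longest period on ties
    g <- ordinates[top] / sum(o)
    N <- length(idx)
    p_val <- fisher_g_pvalue(g, N)
    sig <- p_val <= threshold
    rows[[step]] <- data.frame(
      rank = step, period_minutes = period_labels[top], g_statistic = g,
      n_remaining = N, p_value = p_val, threshold = threshold,
      significant = sig)
    if (!sig) break
    remaining[top] <- FALSE
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fisher_steps", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "correction_p") <- correction_p
  out
}

#' Cohort-pooled periodogram ordinates
#'
#' `ordinate_j = sum_i X[i, j]^2`: the total spectral energy of the cohort
#' at periodicity j. Identical, up to the monotone square, to the column
#' norms driving the penalized multiband path, so the Fisher test and the
#' penalized selection rank periodicities on the same population-level
#' quantity. (The aggregation level is a package choice: a per-subject
#' test can be run by passing one row's squared magnitudes directly to
#' [sequential_fisher()].)
#'
#' @param X A [compute_spectrum()] result or numeric matrix.
#' @return Numeric vector of length p.
#' @export
pool_ordinates <- function(X) {
  m <- as_magnitude_matrix(X)
  if (nrow(m) < 1L) stop_validation("X must have at least one row")
  colSums(m^2)
}

#' Autocorrelation profile of an activity series
#'
#' Standard biased sample autocorrelation with a single global mean:
#' `r_k = sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`,
#' for lags `k = 0 .. max_lag_epochs`. A peak near the one-day lag (1440
#' epochs at 1-minute resolution) indicates circadian rhythmicity; peaks
#' at shorter lags are unreliable in the presence of multiple
#' periodicities, which is the known limitation this profile illustrates
#' relative to spectral selection.
#'
#' @param series An [epoch_series()] object.
#' @param max_lag_epochs Largest lag, strictly less than the series length.
#' @return An object of class `"acf_profile"`: list with `lags_epochs`,
#'   `r`, `epoch_seconds`, `n`.
#' @export
autocorrelation <- function(series, max_lag_epochs) {
  stopifnot(inherits(series, "epoch_series"))
  x <- series$counts
  max_lag_epochs <- as.integer(max_lag_epochs)
  if (max_lag_epochs < 1L || max_lag_epochs >= length(x))
    stop_validation("max_lag_epochs must be in [1, length(counts) - 1]")
  if (stats::var(x) == 0)
    stop_validation(sprintf(
      "subject %s: constant series has undefined autocorrelation",
      series$subject_id))
  a <- stats::acf(x, lag.max = max_lag_epochs, plot = FALSE, demean = TRUE,
                  type = "correlation")
  structure(
    list(lags_epochs = 0:max_lag_epochs, r = as.numeric(a$acf),
         epoch_seconds = series$epoch_seconds, n = length(x)),
    class = "acf_profile")
}

#' @export
print.acf_profile <- function(x, ...) {
  cat(sprintf("<acf_profile> lags 0..%d epochs (n = %d)\n",
              max(x$lags_epochs), x$n))
  invisible(x)
}

#' Local maxima of an autocorrelation profile
#'
#' Lag `k >= window_epochs` is a local maximum when `r_k >= r_m` for every
#' lag m within `k +/- window_epochs`; lag 0 is never returned. Results
#' are ordered by descending correlation, so the first element is the
#' global (lag >= window) peak.
#'
#' @param profile An [autocorrelation()] result.
#' @param window_epochs Half-width of the dominance window (>= 1).
#' @return Integer vector of peak lags (epochs), sorted by descending `r`.
#' @export
find_local_maxima <- function(profile, window_epochs) {
  stopifnot(inherits(profile, "acf_profile"))
  w <- as.integer(window_epochs)
  if (w < 1L) stop_validation("window_epochs must be >= 1")
  r <- profile$r
  K <- length(r) - 1L # lags 0..K
  peaks <- integer(0)
  for (k in seq.int(w, K)) {
    lo <- max(0L, k - w)
    hi <- min(K, k + w)
    if (r[k + 1L] >= max(r[(lo + 1L):(hi + 1L)])) peaks <- c(peaks, k)
  }
  peaks <- setdiff(peaks, 0L)
  peaks[order(r[peaks + 1L], decreasing = TRUE)]
}

#' Write a sequential Fisher report / ACF profile as CSV
#'
#' @param steps A [sequential_fisher()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fisher_csv <- function(steps, path) {
  stopifnot(inherits(steps, "fisher_steps"))
  out <- as.data.frame(steps)
  for (nm in c("period_minutes", "g_statistic", "p_value", "threshold"))
    out[[nm]] <- fmt_num(out[[nm]])
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_fisher_csv
#' @param profile An [autocorrelation()] result.
#' @export
write_acf_csv <- function(profile, path) {
  stopifnot(inherits(profile, "acf_profile"))
  out <- data.frame(
    lag_epochs = profile$lags_epochs,
    lag_hours = fmt_num(profile$lags_epochs * profile$epoch_seconds / 3600),
    r = fmt_num(profile$r))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}
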