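# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (double loops, direct DFT sums, 1-D
# numeric minimization) so they stay independent of the implementation
# paths they check.

make_series <- function(counts, id = "s1", epoch_seconds = 60L) {
  epoch_series(id, counts, epoch_seconds = epoch_seconds)
}

# one subject: baseline + sum of cosines over `days` days of 1-min epochs
cosine_series <- function(days, baseline = 0, amps = numeric(0),
                          periods = numeric(0), phases = rep(0, length(amps)),
                          id = "s1") {
  L <- days * 1440L
  t <- 0:(L - 1L)
  x <- rep(baseline, L)
  for (m in seq_along(amps))
    x <- x + amps[m] * cos(2 * pi * t / periods[m] + phases[m])
  make_series(x, id = id)
}

# Direct O(L) DFT sum at one bin: amplitude-scaled modulus.
direct_dft_magnitude <- function(x, k) {
  L <- length(x)
  x <- x - mean(x)
  t <- 0:(L - 1L)
  re <- sum(x * cos(2 * pi * k * t / L))
  im <- -sum(x * sin(2 * pi * k * t / L))
  (2 / L) * sqrt(re^2 + im^2)
}

# 1-D convex minimization oracle for one theta coordinate: minimizes the
# penalized objective (1 - th)^2 * norm_sq + lambda * (alpha*th +
# (1-alpha)*th^2/2) over [0, 1] numerically.
theta_oracle <- function(norm_sq, lambda, alpha) {
  obj <- function(th)
    (1 - th)^2 * norm_sq + lambda * (alpha * th + (1 - alpha) * th^2 / 2)
  cand <- stats::optimize(obj, c(0, 1), tol = 1e-10)$minimum
  # optimize() never returns the exact interval ends; snap if an end wins
  ends <- c(0, 1)
  all <- c(cand, ends)
  all[which.min(vapply(all, obj, 0))]
}

# brute-force squared Frobenius norm of X - X diag(theta)
frobenius_oracle <- function(X, theta) {
  R <- X - X %*% diag(theta, nrow = length(theta))
  sum(R^2)
}

# column maxima of a matrix via row-wise pmax reduction (fast for wide M)
matrixStats_colmax <- function(M) {
  out <- M[1L, ]
  for (i in seq_len(nrow(M))[-1L]) out <- pmax(out, M[i, ])
  out
}

write_tmp_epoch_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

# raw epoch CSV data.frame for given per-day count vectors
epoch_df <- function(days_counts, id = "s1", epd = 1440L) {
  do.call(rbind, lapply(seq_along(days_counts), function(d) {
    data.frame(subject_id = id, day_index = d,
               epoch_index = 0:(epd - 1L), count = days_counts[[d]])
  }))
}
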