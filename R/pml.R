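#' Configuration for the penalized multiband estimator
#'
#' The estimator shrinks a diagonal column-selection matrix Theta
#' (`0 <= theta_j <= 1`) under the objective
#' \deqn{g(\theta) = \|X - X\Theta\|_F^2 +
#'   \lambda \sum_j [\alpha \theta_j + (1-\alpha)\theta_j^2/2],}
#' an elastic-net-style penalty in which `alpha = 1` is the pure L1 (lasso)
#' case used for selection and `alpha < 1` mixes in an L2 term. Because the
#' Frobenius term separates over columns, each coordinate has the closed
#' form of [theta_solution()] and the whole lambda path is available
#' without iterative optimization.
#'
#' @param alpha Elastic-net balance in \[0, 1\]; 1 (default) = pure L1.
#' @param lambda_grid Optional strictly decreasing nonnegative lambda values
#'   at which to evaluate the path. Default `NULL`: use the exact entry
#'   knots (see [solution_path()]).
#' @param mse_normalized Logical; if `TRUE` (default) the reconstruction
#'   criterion is the squared Frobenius norm divided by `n * p`, making it
#'   comparable across cohort sizes. The unnormalized option is the raw
#'   squared Frobenius norm; the two are monotone-equivalent for selection.
#' @return An object of class `"pml_config"`.
#' @export
pml_config <- function(alpha = 1, lambda_grid = NULL, mse_normalized = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop_validation("alpha must be a number in [0, 1]")
  if (!is.null(lambda_grid)) {
    lambda_grid <- as.numeric(lambda_grid)
    if (anyNA(lambda_grid) || any(lambda_grid < 0) ||
        is.unsorted(rev(lambda_grid), strictly = TRUE))
      stop_validation("lambda_grid must be strictly decreasing and nonnegative")
  }
  stopifnot(is.logical(mse_normalized), length(mse_normalized) == 1L)
  structure(list(alpha = alpha, lambda_grid = lambda_grid,
                 mse_normalized = mse_normalized),
            class = "pml_config")
}

as_magnitude_matrix <- function(X) {
  if (inherits(X, "spectrum_matrix")) X$magnitudes
  else if (is.matrix(X)) X
  else stop_validation("X must be a spectrum_matrix or numeric matrix")
}

#' Squared column norms of the periodicity-signal matrix
#'
#' `||x_j||^2 = sum_i X[i,j]^2`, the diagonal of `X^T X`: the total spectral
#' energy the cohort carries at periodicity j. These norms are the only
#' statistics the penalized estimator needs.
#'
#' @param X A [compute_spectrum()] result or numeric matrix.
#' @return Numeric vector of length p.
#' @export
column_norms_sq <- function(X) {
  m <- as_magnitude_matrix(X)
  if (nrow(m) < 1L) stop_validation("X must have at least one row")
  colSums(m^2)
}

#' Closed-form penalized selection weights
#'
#' Per-coordinate minimizer of the penalized Frobenius objective over
#' `[0, 1]` (see [pml_config()]): setting the subgradient
#' `-2||x_k||^2 + 2 theta ||x_k||^2 + (1-alpha) lambda theta + alpha lambda`
#' to zero and clipping,
#' \deqn{\theta_k = \mathrm{clip}\!\left(
#'   \frac{2\|x_k\|^2 - \alpha\lambda}{2\|x_k\|^2 + (1-\alpha)\lambda},
#'   0, 1\right).}
#' Columns with zero norm carry no signal and are fixed at 0.
#'
#' @param norms_sq Nonnegative squared column norms (from
#'   [column_norms_sq()]).
#' @param lambda Nonnegative penalty.
#' @param alpha Elastic-net balance in \[0, 1\].
#' @return Numeric vector of theta values in \[0, 1\].
#' @export
#' @examples
#' theta_solution(c(9, 4, 1), lambda = 4, alpha = 1) # 1 - 4/(2*norm^2), clipped
theta_solution <- function(norms_sq, lambda, alpha = 1) {
  norms_sq <- as.numeric(norms_sq)
  if (anyNA(norms_sq) || any(norms_sq < 0))
    stop_validation("norms_sq must be nonnegative")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop_validation("lambda must be a nonnegative number")
  if (alpha < 0 || alpha > 1) stop_validation("alpha must be in [0, 1]")
  th <- numeric(length(norms_sq))
  pos <- norms_sq > 0
  denom <- 2 * norms_sq[pos] + (1 - alpha) * lambda
  th[pos] <- pmin(1, pmax(0, (2 * norms_sq[pos] - alpha * lambda) / denom))
  th
}

#' Entry penalty of each periodicity
#'
#' The largest lambda at which a column's theta becomes positive:
#' `lambda*_k = 2 ||x_k||^2 / alpha`. As lambda decreases from its maximum,
#' periodicities enter the active set sequentially in descending order of
#' spectral energy; the entry knots are the breakpoints of the solution
#' path. Requires `alpha > 0` (with no L1 term every positive-norm theta is
#' positive at all finite lambda and no entry knots exist).
#'
#' @inheritParams theta_solution
#' @return Numeric vector of entry lambdas (0 for zero-norm columns).
#' @export
entry_lambda <- function(norms_sq, alpha = 1) {
  norms_sq <- as.numeric(norms_sq)
  if (anyNA(norms_sq) || any(norms_sq < 0))
    stop_validation("norms_sq must be nonnegative")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop_validation("entry lambdas require alpha in (0, 1]")
  2 * norms_sq / alpha
}

#' Reconstruction criterion (squared Frobenius norm)
#'
#' `||X - X Theta||_F^2 = sum_j (1 - theta_j)^2 ||x_j||^2`, optionally
#' divided by `n * p` ("mean squared error"). Used as the criterion for
#' choosing the penalty / number of selected periodicities and as a
#' measure of the variability left unexplained by them.
#'
#' @param X A [compute_spectrum()] result or numeric matrix.
#' @param theta Numeric vector in \[0, 1\], length p.
#' @param normalized Divide by `n * p`? Default `TRUE`.
#' @return Nonnegative scalar.
#' @export
pml_mse <- function(X, theta, normalized = TRUE) {
  m <- as_magnitude_matrix(X)
  if (length(theta) != ncol(m))
    stop_validation("theta length must equal the number of columns of X")
  if (any(theta < -.grid_tol) || any(theta > 1 + .grid_tol))
    stop_validation("theta components must lie in [0, 1]")
  val <- sum((1 - theta)^2 * colSums(m^2))
  if (normalized) val / (nrow(m) * ncol(m)) else val
}

#' Penalty solution path of the multiband estimator
#'
#' Evaluates theta, the reconstruction criterion and the active set along
#' a decreasing lambda sequence. By default the sequence consists of the
#' exact knots: `lambda_max = max_k 2||x_k||^2 / alpha` (all theta zero)
#' down through each distinct entry lambda, ending at 0 (no penalty, all
#' positive-norm theta equal 1, criterion 0). Between knots the path is
#' smooth and no new column activates, so the knots carry all the
#' selection information; a dense grid can be supplied through
#' [pml_config()] if the full curve is wanted.
#'
#' Columns tied in `||x_j||^2` enter at the same knot; the deterministic
#' tie-break lists the longer period first. The theta vectors at all knots
#' are stored when the `p x nknots` matrix is small (<= 2e6 entries);
#' otherwise use [path_theta()], which recomputes any theta vector from the
#' closed form on demand.
#'
#' @param X A [compute_spectrum()] result or numeric matrix (rows =
#'   subjects, columns = periodicities in strictly decreasing period
#'   order).
#' @param config A [pml_config()].
#' @return An object of class `"pml_path"`: list with `lambda`, `mse`,
#'   `n_active`, `entry_order` (column indices in entry order),
#'   `entry_lambda`, `column_norms_sq`, `periods`, `alpha`,
#'   `mse_normalized`, `n`, `p`, and `theta` (p x nknots matrix or `NULL`).
#' @export
solution_path <- function(X, config = pml_config()) {
  stopifnot(inherits(config, "pml_config"))
  m <- as_magnitude_matrix(X)
  if (ncol(m) < 1L || nrow(m) < 1L) stop_validation("X must be non-empty")
  norms <- colSums(m^2)
  periods <- if (inherits(X, "spectrum_matrix")) X$periods else NULL
  alpha <- config$alpha
  if (is.null(config$lambda_grid)) {
    if (alpha <= 0)
      stop_validation("the default knot path requires alpha > 0; supply lambda_grid")
    entries <- entry_lambda(norms, alpha)
    lambdas <- c(sort(unique(entries[norms > 0]), decreasing = TRUE), 0)
  } else {
    entries <- if (alpha > 0) entry_lambda(norms, alpha) else rep(Inf, length(norms))
    lambdas <- config$lambda_grid
  }
  n <- nrow(m); p <- ncol(m)
  nk <- length(lambdas)
  mse <- numeric(nk)
  n_active <- integer(nk)
  keep_theta <- p * nk <= 2e6
  theta_mat <- if (keep_theta) matrix(0, p, nk) else NULL
  for (i in seq_len(nk)) {
    th <- theta_solution(norms, lambdas[i], alpha)
    raw <- sum((1 - th)^2 * norms)
    mse[i] <- if (config$mse_normalized) raw / (n * p) else raw
    n_active[i] <- sum(th > 0)
    if (keep_theta) theta_mat[, i] <- th
  }
  # stable order() => among tied norms the smaller column index (longer
  # period, since periods decrease across columns) comes first
  entry_order <- order(norms, decreasing = TRUE)
  structure(
    list(lambda = lambdas, mse = mse, n_active = n_active,
         entry_order = entry_order, entry_lambda = entries,
         column_norms_sq = norms, periods = periods, alpha = alpha,
         mse_normalized = config$mse_normalized, n = n, p = p,
         theta = theta_mat),
    class = "pml_path")
}

#' @export
print.pml_path <- function(x, ...) {
  cat(sprintf(
    "<pml_path> alpha = %g, %d knot(s) over %d periodicities (n = %d)\n",
    x$alpha, length(x$lambda), x$p, x$n))
  cat(sprintf("  lambda_max = %.6g, final MSE = %.6g\n",
              max(x$lambda), x$mse[length(x$mse)]))
  invisible(x)
}

#' Theta vector at an arbitrary penalty value
#'
#' @param path A [solution_path()] result.
#' @param lambda Nonnegative penalty value.
#' @return Numeric vector of theta values in \[0, 1\].
#' @export
path_theta <- function(path, lambda) {
  stopifnot(inherits(path, "pml_path"))
  theta_solution(path$column_norms_sq, lambda, path$alpha)
}

#' Select dominant periodicities from a solution path
#'
#' With an integer `n_select`, returns the first `n_select` periodicities
#' in entry order (descending spectral energy for `alpha = 1`). With
#' `"elbow"`, the number selected is the `m` maximizing the drop ratio
#' `(MSE_{m-1} - MSE_m) / (MSE_m - MSE_{m+1})` along the knot sequence --
#' an explicit, documented heuristic standing in for the visual choice of
#' the kink in the MSE-versus-count plot; a zero denominator with a
#' positive numerator counts as a perfect elbow.
#'
#' @param path A [solution_path()] result.
#' @param n_select Positive integer (<= p) or `"elbow"`.
#' @return Integer vector of column indices in entry order; if the path
#'   came from a spectrum matrix, named by period in minutes.
#' @export
select_dominant <- function(path, n_select = "elbow") {
  stopifnot(inherits(path, "pml_path"))
  counts <- elbow_sequence(path)
  if (identical(n_select, "elbow")) {
    mse_seq <- counts$mse
    K <- length(mse_seq) - 1L # counts 0..K
    if (K < 2L) {
      m <- K
    } else {
      ratio <- rep(-Inf, K - 1L)
      for (mm in seq_len(K - 1L)) {
        num <- mse_seq[mm] - mse_seq[mm + 1L]
        den <- mse_seq[mm + 1L] - mse_seq[mm + 2L]
        ratio[mm] <- if (den > 0) num / den else if (num > 0) Inf else -Inf
      }
      m <- which.max(ratio)
    }
    n_select <- counts$n_active[m + 1L] # active count at that knot
  } else {
    if (!is.numeric(n_select) || length(n_select) != 1L || is.na(n_select) ||
        n_select < 1 || n_select != round(n_select))
      stop_validation("n_select must be a positive integer or \"elbow\"")
    if (n_select > path$p)
      stop_validation(sprintf("n_select = %d exceeds p = %d", n_select, path$p))
  }
  idx <- path$entry_order[seq_len(n_select)]
  if (!is.null(path$periods)) names(idx) <- sprintf("%.3f", path$periods[idx])
  idx
}

# Knot sequence restricted to knots where the active count increases,
# starting from the all-zero knot. Recomputed from the norms so it works
# for paths built on custom lambda grids too.
elbow_sequence <- function(path) {
  norms <- path$column_norms_sq
  alpha <- if (path$alpha > 0) path$alpha else 1
  entries <- entry_lambda(norms, alpha)
  lam <- c(sort(unique(entries[norms > 0]), decreasing = TRUE), 0)
  mse <- numeric(length(lam))
  n_active <- integer(length(lam))
  for (i in seq_along(lam)) {
    th <- theta_solution(norms, lam[i], alpha)
    raw <- sum((1 - th)^2 * norms)
    mse[i] <- if (path$mse_normalized) raw / (path$n * path$p) else raw
    n_active[i] <- sum(th > 0)
  }
  list(lambda = lam, mse = mse, n_active = n_active)
}

#' Selection report table
#'
#' One row per entered periodicity, in entry order: rank, period, entry
#' lambda, spectral energy, and the cumulative drop in the reconstruction
#' criterion once the periodicity (and all earlier ones) is fully included
#' (theta = 1 for selected columns, 0 for the rest).
#'
#' @param path A [solution_path()] result.
#' @param n_select Number of rows (default: all positive-energy columns).
#' @return A `data.frame`.
#' @export
selection_report <- function(path, n_select = NULL) {
  stopifnot(inherits(path, "pml_path"))
  pos <- sum(path$column_norms_sq > 0)
  if (is.null(n_select)) n_select <- pos
  idx <- path$entry_order[seq_len(min(n_select, path$p))]
  norms <- path$column_norms_sq
  total <- sum(norms)
  denom <- if (path$mse_normalized) path$n * path$p else 1
  cum_drop <- cumsum(norms[idx]) / denom
  data.frame(
    rank = seq_along(idx),
    period_minutes = if (!is.null(path$periods)) path$periods[idx] else NA_real_,
    column = idx,
    entry_lambda = path$entry_lambda[idx],
    norm_sq = norms[idx],
    cumulative_mse_drop = cum_drop,
    row.names = NULL)
}

#' Export a solution path as JSON
#'
#' Writes the knot list as JSON: for each knot, `lambda`, `mse`,
#' `n_active`, the active periods (minutes) and, when stored, the theta
#' vector.
#'
#' @param path A [solution_path()] result.
#' @param file Output file path.
#' @return `file`, invisibly.
#' @export
path_to_json <- function(path, file) {
  stopifnot(inherits(path, "pml_path"))
  knots <- lapply(seq_along(path$lambda), function(i) {
    th <- if (!is.null(path$theta)) path$theta[, i] else path_theta(path, path$lambda[i])
    act <- which(th > 0)
    k <- list(lambda = path$lambda[i], mse = path$mse[i],
              n_active = length(act))
    if (!is.null(path$periods)) k$active_periods_minutes <- path$periods[act]
    k$theta <- th
    k
  })
  jsonlite::write_json(
    list(alpha = path$alpha, mse_normalized = path$mse_normalized,
         n = path$n, p = path$p, knots = knots),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write the selection report as CSV
#'
#' @inheritParams selection_report
#' @param path_out Output CSV path.
#' @return `path_out`, invisibly.
#' @export
write_selection_csv <- function(path, path_out, n_select = NULL) {
  rep <- selection_report(path, n_select)
  num <- vapply(rep, is.numeric, TRUE) & names(rep) != "rank" & names(rep) != "column"
  for (nm in names(rep)[num]) rep[[nm]] <- fmt_num(rep[[nm]])
  data.table::fwrite(rep, path_out, quote = FALSE)
  invisible(path_out)
}
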