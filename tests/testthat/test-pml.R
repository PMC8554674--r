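test_that("column_norms_sq matches the naive double loop", {
  expect_equal(column_norms_sq(matrix(c(3, 4), 1)), c(9, 16))
  expect_equal(column_norms_sq(cbind(c(1, 2), 0))[2], 0)

  set.seed(51)
  X <- matrix(runif(200), 20, 10)
  oracle <- numeric(10)
  for (j in 1:10) for (i in 1:20) oracle[j] <- oracle[j] + X[i, j]^2
  expect_equal(column_norms_sq(X), oracle, tolerance = 1e-12)
})

test_that("theta_solution closed form: boundary identities", {
  expect_equal(theta_solution(c(9, 4, 0), 0), c(1, 1, 0)) # no penalty
  expect_equal(theta_solution(4, 4, alpha = 1), 0.5)      # 1 - lambda/(2 norm)
  expect_equal(theta_solution(4, 4, alpha = 0.5), 0.6)    # (8-2)/(8+2)
  expect_error(theta_solution(-1, 1), "nonnegative", class = "ar_validation_error")
})

test_that("theta_solution agrees with the 1-D convex-minimization oracle", {
  set.seed(52)
  for (rep in 1:20) {
    norm_sq <- runif(1, 0, 10)
    alpha <- sample(c(1, 0.5, 0.2), 1)
    lambda <- runif(1, 0, 3 * norm_sq + 1)
    expect_equal(theta_solution(norm_sq, lambda, alpha),
                 theta_oracle(norm_sq, lambda, alpha), tolerance = 1e-6)
  }
})

test_that("entry_lambda marks the activation boundary", {
  expect_equal(entry_lambda(4, 1), 8)
  expect_equal(entry_lambda(4, 0.5), 16)
  expect_equal(entry_lambda(0, 1), 0)
  expect_error(entry_lambda(4, 0), "alpha", class = "ar_validation_error")

  set.seed(53)
  for (rep in 1:20) {
    ns <- runif(1, 0.1, 50)
    al <- runif(1, 0.05, 1)
    lam <- entry_lambda(ns, al)
    eps <- 1e-9 * lam
    expect_equal(theta_solution(ns, lam + eps, al), 0)
    expect_gt(theta_solution(ns, lam - eps, al), 0)
  }
})

test_that("pml_mse equals the brute-force Frobenius computation", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 2)
  expect_equal(pml_mse(X, rep(1, 3)), 0)
  expect_equal(pml_mse(X, rep(0, 3), normalized = FALSE), sum(X^2))

  set.seed(54)
  for (rep in 1:10) {
    Xr <- matrix(runif(60), 6, 10)
    th <- runif(10)
    expect_equal(pml_mse(Xr, th, normalized = FALSE),
                 frobenius_oracle(Xr, th), tolerance = 1e-10)
    expect_equal(pml_mse(Xr, th), frobenius_oracle(Xr, th) / 60,
                 tolerance = 1e-10)
  }
  expect_error(pml_mse(X, c(1, 1)), "length", class = "ar_validation_error")
})

test_that("default knot path: entry order, nesting, MSE behavior", {
  X <- matrix(0, 1, 3)
  X[1, ] <- c(3, 2, 1) # norms 9, 4, 1
  path <- solution_path(X)
  expect_equal(path$lambda, c(18, 8, 2, 0))
  expect_equal(path$n_active, 0:3)
  expect_equal(path$entry_order, c(1L, 2L, 3L))
  expect_equal(path$mse[1], sum(c(9, 4, 1)) / 3) # all theta zero
  expect_equal(path$mse[4], 0)                   # lambda = 0
  # at lambda >= lambda_max every theta is suppressed
  expect_equal(path_theta(path, 18), c(0, 0, 0))
  expect_equal(path_theta(path, 25), c(0, 0, 0))

  # nesting of active sets along the knots (alpha = 1)
  acts <- lapply(path$lambda, function(l) which(path_theta(path, l) > 0))
  for (i in seq_len(length(acts) - 1L))
    expect_true(all(acts[[i]] %in% acts[[i + 1L]]))
})

test_that("path properties hold on random instances", {
  set.seed(55)
  for (rep in 1:25) {
    X <- matrix(runif(80), 8, 10)
    path <- solution_path(X)
    norms <- column_norms_sq(X)
    expect_equal(path$entry_order, order(norms, decreasing = TRUE))
    expect_true(all(diff(path$mse) <= 1e-12))       # nonincreasing as lambda drops
    expect_equal(path$mse[length(path$mse)], 0, tolerance = 1e-12)
    # theta componentwise nonincreasing in lambda
    l2 <- sort(runif(2, 0, max(path$lambda)))
    expect_true(all(path_theta(path, l2[2]) <= path_theta(path, l2[1]) + 1e-12))
    # theta nondecreasing in norm at fixed lambda
    lam <- runif(1, 0, max(path$lambda))
    th <- theta_solution(sort(norms), lam, 1)
    expect_true(all(diff(th) >= -1e-12))
  }
})

test_that("grid paths match the coordinate-wise numeric minimizer", {
  set.seed(56)
  for (alpha in c(1, 0.5)) {
    X <- matrix(runif(50, 0, 2), 5, 10)
    norms <- column_norms_sq(X)
    lmax <- max(2 * norms / alpha)
    grid <- seq(lmax, 0, length.out = 8)
    path <- solution_path(X, pml_config(alpha = alpha, lambda_grid = grid))
    expect_equal(path$lambda, grid)
    for (i in seq_along(grid)) {
      oracle <- vapply(norms, theta_oracle, 0, lambda = grid[i], alpha = alpha)
      expect_equal(path$theta[, i], oracle, tolerance = 1e-6)
    }
  }
})

test_that("select_dominant: counts, ordering, elbow, ties", {
  X <- matrix(0, 1, 4); X[1, ] <- c(4, 1, 6, 2)
  path <- solution_path(X)
  expect_equal(unname(select_dominant(path, 4)), c(3L, 1L, 4L, 2L))
  expect_equal(unname(select_dominant(path, 1)), 3L)
  expect_error(select_dominant(path, 5), "exceeds", class = "ar_validation_error")
  expect_error(select_dominant(path, 0), "positive", class = "ar_validation_error")

  # constructed elbow: one huge column, the rest tiny -> elbow picks 1
  Xe <- matrix(0, 1, 5); Xe[1, ] <- c(10, 0.4, 0.3, 0.2, 0.1)
  expect_equal(unname(select_dominant(solution_path(Xe), "elbow")), 1L)

  # tie in norms: longer period (earlier column) enters first
  Xt <- matrix(0, 1, 3); Xt[1, ] <- c(2, 3, 2)
  pt <- solution_path(Xt)
  expect_equal(pt$entry_order, c(2L, 1L, 3L))
})

test_that("selection report and JSON export are well-formed", {
  co <- simulate_cohort(cohort_preset("24m", n_subjects = 5, days = 2, seed = 3))
  X <- compute_spectrum(co)
  path <- solution_path(X)
  rep3 <- selection_report(path, 3)
  expect_equal(rep3$rank, 1:3)
  expect_equal(rep3$period_minutes[1], 1440)
  expect_true(all(diff(rep3$norm_sq) <= 0))
  expect_true(all(diff(rep3$cumulative_mse_drop) > 0))

  f <- tempfile(fileext = ".json")
  small <- solution_path(X$magnitudes[, 1:20])
  path_to_json(small, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$p, 20L)
  expect_equal(length(parsed$knots), length(small$lambda))
})
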