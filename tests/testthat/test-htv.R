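test_that("Noser matrix is the column-norm diagonal with a floor", {
  J <- diag(4)                       # orthonormal columns
  expect_equal(noser_matrix(J), rep(1, 4))
  J2 <- matrix(c(3, 4, 0, 0), 2, 2)
  expect_equal(noser_matrix(J2, floor_eps = 1e-8), c(5, 1e-8))
  J3 <- matrix(rnorm(12), 3, 4)
  expect_equal(noser_matrix(3 * J3), 3 * noser_matrix(J3))
  expect_error(noser_matrix(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("beta = 0 reduces to the closed-form regularized least squares", {
  sens <- get_sens()
  v <- add_noise(get_phantom_batch(1)$voltages[, 1], 45, seed = 2)
  r <- htv_solve(v, sens, htv_config(alpha = 0.01, beta = 0))
  J <- sens$J
  L2 <- noser_matrix(J)^2
  s_cf <- solve(crossprod(J) + 0.01 * diag(L2),
                crossprod(J, as.vector(v) - sens$v0))
  expect_lt(max(abs(r$delta - s_cf)) / max(abs(s_cf)), 1e-6)
  expect_true(r$converged)
})

test_that("objective trace is non-increasing on random inputs", {
  sens <- get_sens()
  b <- get_phantom_batch(6)
  for (i in 1:6) {
    v <- add_noise(b$voltages[, i], c(30, 45, 55, Inf)[(i %% 4) + 1], seed = i)
    r <- htv_solve(v, sens)
    expect_true(all(diff(r$objective_trace) <= 1e-10),
                label = paste("monotone trace, sample", i))
  }
})

test_that("increasing alpha shrinks the Noser-weighted solution norm", {
  sens <- get_sens()
  v <- add_noise(get_phantom_batch(1)$voltages[, 1], 45, seed = 3)
  L <- noser_matrix(sens$J)
  norms <- vapply(c(0.003, 0.03, 0.3), function(a) {
    r <- htv_solve(v, sens, htv_config(alpha = a, beta = 0))
    sqrt(sum((L * r$delta)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("a high-contrast inclusion is localized within 3 pixels", {
  sens <- get_sens()
  g <- sens$mesh$grid
  ph <- matrix(sens$ref, g, g)
  cy <- 28; cx <- 40
  ph[(row(ph) - cy)^2 + (col(ph) - cx)^2 <= 16] <- 1.8
  r <- htv_solve(solve_forward(sens, ph), sens)
  img <- r$sigma_hat
  pk <- which(img == max(img[sens$mask]), arr.ind = TRUE)[1, ]
  expect_lte(sqrt((pk[1] - cy)^2 + (pk[2] - cx)^2), 3)
})

test_that("batch pre-reconstruction clips to [0, 2] and is deterministic", {
  sens <- get_sens()
  b <- get_phantom_batch(3)
  out1 <- prereconstruct(b$voltages[, 1:2], sens)
  out2 <- prereconstruct(b$voltages[, 1:2], sens)
  expect_identical(out1, out2)
  expect_true(all(out1 >= 0 & out1 <= 2))
  expect_error(htv_solve(numeric(10), sens), "length")
  # the pre-reconstruction is artifact-laden: positive error against truth
  tr <- b$phantoms[[1]]$conductivity
  expect_gt(metric_rmse(out1[, , 1], tr), 0)
})
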