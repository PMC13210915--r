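test_that("RMSE matches hand-computed cases", {
  a <- matrix(0, 2, 2); b <- a; b[1, 1] <- 1
  expect_equal(metric_rmse(b, a), 0.5)
  expect_equal(metric_rmse(a, a), 0)
  expect_equal(metric_rmse(a + 0.3, a), 0.3)
  expect_error(metric_rmse(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("SSIM uses Gaussian 11/1.5 windows and range-scaled constants", {
  expect_equal(unname(ssim_constants(255)), c(6.5025, 58.5225))
  expect_equal(unname(ssim_constants(2)), c(0.0004, 0.0036))
  set.seed(31)
  x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
  expect_equal(metric_ssim(x, x), 1)
  expect_equal(metric_ssim(x, y), bruteforce_ssim(x, y), tolerance = 1e-6)
  expect_equal(metric_ssim(x, y, dynamic_range = 255),
               bruteforce_ssim(x, y, dr = 255), tolerance = 1e-6)
  expect_error(metric_ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("PSNR is 10 log10(MAX^2 / MSE) with MAX = 2", {
  a <- matrix(0, 12, 12)
  expect_equal(metric_psnr(a + 2, a), 0)          # MSE = MAX^2
  expect_equal(metric_psnr(a + 0.2, a), 20)       # MSE = 0.04
  expect_equal(metric_psnr(a, a), 99)             # sentinel for identical
})

test_that("relative change reports magnitude and direction", {
  rc <- relative_change(0.3812, 0.1523)
  expect_equal(as.numeric(rc), 60.0, tolerance = 0.01)
  expect_equal(attr(rc, "direction"), "decrease")
  ri <- relative_change(0.5347, 0.8376)
  expect_equal(attr(ri, "direction"), "increase")
  expect_equal(as.numeric(relative_change(0.4, 0.4)), 0)
  expect_error(relative_change(0, 1), "baseline")
})

test_that("metric report aggregates per-sample values", {
  set.seed(32)
  truth <- array(runif(16 * 16 * 3, 0, 2), c(16, 16, 3))
  r <- metric_report(truth, truth, "self")
  expect_equal(r$aggregate$rmse_mean, 0)
  expect_equal(r$aggregate$ssim_mean, 1)
  expect_equal(nrow(r$per_sample), 3)
})
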