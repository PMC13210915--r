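test_that("adjacent-adjacent protocol yields 208 measurements, 13 per drive", {
  pr <- build_protocol()
  expect_equal(pr$n_measurements, 208L)
  expect_equal(nrow(pr$table), 208L)
  for (k in 1:16) expect_equal(nrow(pr$measure_pairs[[k]]), 13L)
  # no measurement pair shares an electrode with its drive pair
  for (r in seq_len(nrow(pr$table)))
    expect_length(intersect(pr$table[r, 1:2], pr$table[r, 3:4]), 0)
})

test_that("FEM forward model satisfies reciprocity", {
  sens <- get_sens()
  ph <- get_phantom_batch(1)$phantoms[[1]]
  v <- fem_forward(sens, ph)
  tab <- sens$protocol$table
  Vm <- matrix(NA_real_, 16, 16)
  for (r in seq_len(nrow(tab))) Vm[tab[r, 1], tab[r, 3]] <- v[r]
  for (a in 1:16) for (b in 1:16)
    if (!is.na(Vm[a, b]) && !is.na(Vm[b, a]))
      expect_lt(abs(Vm[a, b] - Vm[b, a]) / max(abs(Vm[a, b]), 1e-300), 1e-6)
})

test_that("linearized forward model is exact at reference and superposes", {
  sens <- get_sens()
  g <- sens$mesh$grid
  homog <- matrix(sens$ref, g, g)
  expect_equal(solve_forward(sens, homog), sens$v0)

  set.seed(4)
  a <- b <- matrix(0, g, g)
  a[sample(which(sens$mask), 30)] <- 0.2
  b[sample(which(sens$mask), 30)] <- -0.1
  va <- solve_forward(sens, homog + a) - sens$v0
  vb <- solve_forward(sens, homog + b) - sens$v0
  vab <- solve_forward(sens, homog + a + b) - sens$v0
  expect_equal(vab, va + vb, tolerance = 1e-10)
  # doubling a single-pixel perturbation doubles the response
  p1 <- homog; p1[32, 40] <- homog[32, 40] + 0.1
  p2 <- homog; p2[32, 40] <- homog[32, 40] + 0.2
  expect_equal(2 * (solve_forward(sens, p1) - sens$v0),
               solve_forward(sens, p2) - sens$v0, tolerance = 1e-10)
  expect_error(solve_forward(sens, matrix(1, 10, 10)), "grid")
})

test_that("linearization tracks the nonlinear FEM for small contrasts", {
  sens <- get_sens()
  g <- sens$mesh$grid
  set.seed(9)
  ph <- matrix(sens$ref, g, g)
  ph[sample(which(sens$mask), 50)] <- sens$ref * 1.05
  dv_lin <- solve_forward(sens, ph) - sens$v0
  dv_fem <- fem_forward(sens, ph) - fem_forward(sens, matrix(sens$ref, g, g))
  rel <- sqrt(sum((dv_lin - dv_fem)^2) / sum(dv_fem^2))
  expect_lt(rel, 0.1)
})

test_that("noise injection realizes the requested SNR exactly", {
  v <- get_phantom_batch(1)$voltages[, 1]
  for (snr in c(30, 45, 55)) {
    vn <- add_noise(v, snr, seed = 8)
    n <- attr(vn, "noise")
    realized <- 10 * log10(sqrt(mean(v^2)) / sqrt(mean(n^2)))
    expect_equal(realized, snr, tolerance = 1e-10)
  }
  # power convention uses factor 20
  vp <- add_noise(v, 40, seed = 8, convention = "power")
  np <- attr(vp, "noise")
  expect_equal(20 * log10(sqrt(mean(v^2)) / sqrt(mean(np^2))), 40,
               tolerance = 1e-10)
  expect_identical(add_noise(v, Inf), v)
  expect_identical(add_noise(v, 30, seed = 5), add_noise(v, 30, seed = 5))
  expect_false(identical(add_noise(v, 30, seed = 5), add_noise(v, 30, seed = 6)))
})

test_that("noise schedule cycles clean/30/45/55 with period four", {
  expect_equal(noise_schedule(0:3), c("clean", "30", "45", "55"))
  expect_equal(noise_schedule(4), "clean")
  tags <- noise_schedule(0:4799)
  expect_equal(unname(table(tags)[c("clean", "30", "45", "55")]),
               rep(1200L, 4), ignore_attr = TRUE)
  expect_error(noise_schedule(-1), ">= 0")
  expect_equal(snr_of_tag(c("clean", "45")), c(Inf, 45))
})
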