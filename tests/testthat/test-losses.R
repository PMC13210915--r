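test_that("pixel loss combines mean L1 with half mean squared L2", {
  expect_equal(pixel_loss(matrix(0.5, 2, 2), matrix(0, 2, 2)), 0.625)
  x <- matrix(runif(64), 8, 8)
  expect_equal(pixel_loss(x, x), 0)
  expect_gt(pixel_loss(x, x + 0.01), 0)
})

test_that("edge loss responds to step edges and vanishes for constants", {
  x <- matrix(runif(144), 12, 12)
  expect_equal(edge_loss(x, x), 0)
  expect_equal(edge_loss(matrix(1, 12, 12), matrix(5, 12, 12)), 0)
  h <- 0.7
  im <- matrix(0, 12, 12); im[, 7:12] <- h
  mag <- legeit:::.sobel_mag(as4(im))$mag
  expect_equal(max(mag), 4 * h, tolerance = 1e-6)
})

test_that("layer masks partition the disc and drive the layer loss", {
  m <- layer_masks(64, 30)
  disc <- legeit:::.disc(64) <= 30
  expect_equal(m$skin + m$fat + m$muscle + m$core, disc + 0)
  expect_equal(sum(m$skin & m$fat) + sum(m$fat & m$muscle) +
                 sum(m$muscle & m$core) + sum(m$skin & m$core), 0)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(layer_loss(x, x, m), 0)
  expect_equal(layer_loss(x + 0.1, x, m), 0.4, tolerance = 1e-10)
})

test_that("total variation matches the forward-difference definition", {
  expect_equal(tv_loss(matrix(3, 5, 5)), 0)
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(tv_loss(cb), 4)
  x <- matrix(runif(64), 8, 8)
  expect_equal(tv_loss(x / 2), tv_loss(x) / 2)
})

test_that("SSIM loss matches the brute-force windowed oracle", {
  set.seed(21)
  x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
  expect_equal(ssim_loss(x, x), 0, tolerance = 1e-12)
  expect_equal(ssim_loss(x, y), 1 - bruteforce_ssim(x, y), tolerance = 1e-6)
  expect_gte(ssim_loss(x, y), 0)
  expect_lte(ssim_loss(x, y), 2)
})

test_that("histogram loss is invariant under spatial permutation", {
  set.seed(22)
  for (i in 1:5) {
    x <- matrix(runif(64), 8, 8)
    xp <- matrix(sample(as.vector(x)), 8, 8)
    expect_equal(hist_loss(xp, x), 0)
  }
  expect_equal(hist_loss(matrix(1.3, 4, 4), matrix(1, 4, 4)), 16 * 0.3)
})

test_that("paired losses are zero at truth and positive otherwise", {
  set.seed(23)
  x <- matrix(runif(256, 0, 2), 16, 16)
  y <- x + matrix(rnorm(256, 0, 0.1), 16, 16)
  m <- layer_masks(16, 7)
  expect_gt(pixel_loss(y, x), 0)
  expect_gt(edge_loss(y, x), 0)
  expect_gt(suppressWarnings(layer_loss(y, x, m)), 0)
  expect_gt(ssim_loss(y, x), 0)
  expect_gt(hist_loss(y, x), 0)
})

test_that("total loss weights, decomposition and degenerate cases", {
  w <- loss_weights()
  expect_equal(unlist(w[c("pix", "edge", "layer", "tv", "ssim", "hist", "gp")]),
               c(pix = 100, edge = 30, layer = 20, tv = 5, ssim = 10,
                 hist = 2, gp = 10))
  set.seed(24)
  x <- matrix(runif(256, 0, 2), 16, 16)
  y <- matrix(runif(256, 0, 2), 16, 16)
  m <- layer_masks(16, 7)
  tl <- suppressWarnings(total_loss(x, y, w, m))
  expect_equal(sum(c(w$pix, w$edge, w$layer, w$tv, w$ssim, w$hist) *
                     tl$components), tl$total, tolerance = 1e-9)
  # at pred = truth only the unary TV term survives
  tt <- suppressWarnings(total_loss(x, x, w, m))
  expect_equal(tt$total, w$tv * tv_loss(x, reduction = "mean"),
               tolerance = 1e-9)
  w0 <- loss_weights(0, 0, 0, 0, 0, 0, 0)
  expect_equal(suppressWarnings(total_loss(x, y, w0, m))$total, 0)
})

test_that("total loss gradient matches finite differences", {
  set.seed(25)
  x <- array(runif(16 * 16, 0, 2), c(16, 16, 1, 1))
  y <- array(runif(16 * 16, 0, 2), c(16, 16, 1, 1))
  m <- layer_masks(16, 7)
  w <- loss_weights()
  g <- suppressWarnings(legeit:::.total_loss_grad(x, y, w, m))
  eps <- 1e-6
  for (i in c(35, 120, 200)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (suppressWarnings(total_loss(xp, y, w, m))$total -
           suppressWarnings(total_loss(xm, y, w, m))$total) / (2 * eps)
    expect_equal(g$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("gradient penalty matches the linear-critic closed form", {
  set.seed(26)
  w <- matrix(rnorm(64), 8, 8)
  lin <- list(score = function(cond, t) sum(w * t),
              grad = function(cond, t) w)
  real <- matrix(runif(64), 8, 8); fake <- matrix(runif(64), 8, 8)
  gp <- gradient_penalty(lin, matrix(0, 8, 8), real, fake, seed = 4)
  expect_equal(gp, (sqrt(sum(w^2)) - 1)^2, tolerance = 1e-6)
  # zero iff the critic gradient has unit norm
  wu <- w / sqrt(sum(w^2))
  linu <- list(score = function(cond, t) sum(wu * t),
               grad = function(cond, t) wu)
  expect_equal(gradient_penalty(linu, matrix(0, 8, 8), real, fake), 0,
               tolerance = 1e-12)
})

test_that("critic and generator objectives decompose correctly", {
  set.seed(27)
  w <- matrix(rnorm(64, 0, 0.1), 8, 8)
  lin <- list(score = function(cond, t) sum(w * t),
              grad = function(cond, t) w)
  cond <- matrix(runif(64), 8, 8)
  real <- matrix(runif(64), 8, 8)
  co <- critic_objective(lin, cond, real, real, lambda_gp = 10, seed = 1)
  expect_equal(co$components[["wasserstein"]], 0, tolerance = 1e-12)
  expect_equal(co$value, 10 * co$components[["gp"]], tolerance = 1e-12)
  # a silent critic leaves only the anatomy-prior total
  zero <- list(score = function(cond, t) 0, grad = function(cond, t) 0 * w)
  w6 <- loss_weights()
  fake <- matrix(runif(256, 0, 2), 16, 16)
  truth <- matrix(runif(256, 0, 2), 16, 16)
  m <- layer_masks(16, 7)
  go <- suppressWarnings(generator_objective(zero, fake * 0 + 1, fake, truth,
                                             w6, m))
  tl <- suppressWarnings(total_loss(fake, truth, w6, m))
  expect_equal(go$value, tl$total, tolerance = 1e-9)
  expect_equal(go$value, go$components[["adversarial"]] +
                 sum(c(w6$pix, w6$edge, w6$layer, w6$tv, w6$ssim, w6$hist) *
                       go$components[-1]), tolerance = 1e-9)
})
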