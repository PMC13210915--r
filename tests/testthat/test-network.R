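cfg_small <- generator_config(base_channels = 4L, dropout = 0)

test_that("generator preserves shape and confines output to [0, 2]", {
  gen <- generator_new(cfg_small, seed = 2)
  for (s in c(32L, 48L, 64L, 96L)) {
    x <- array(runif(s * s, -3, 3), c(s, s, 1L, 1L))
    y <- generator_forward(gen, x)$y
    expect_equal(dim(y), c(s, s, 1L, 1L))
    expect_true(all(y >= 0 & y <= 2))
  }
  expect_error(generator_forward(gen, array(0, c(20, 20, 1, 1))), "multiple of 16")
  expect_error(generator_forward(gen, array(0, c(32, 48, 1, 1))), "square")
  expect_error(generator_forward(gen, array(0, c(32, 32, 2, 1))), "\\(H, W, 1, N\\)")
})

test_that("recurrence applies the first convolution exactly t times", {
  for (t in 1:3) {
    gen <- generator_new(generator_config(base_channels = 4L, t = t,
                                          dropout = 0), seed = 3)
    x <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
    r <- legeit:::.rrb_f(gen, "enc1.rrb1", x, train = FALSE)
    expect_length(r$cache$steps, t)     # one conv1 application per time step
    expect_length(r$cache$steps2, 1L)   # second conv applied once
  }
  # t = 2: the second application acts on h0 + x
  gen <- generator_new(generator_config(base_channels = 4L, t = 2L,
                                        dropout = 0), seed = 3)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  r <- legeit:::.rrb_f(gen, "enc1.rrb1", x, train = FALSE)
  h0 <- r$cache$steps[[1]]$ac$y
  expect_equal(r$cache$steps[[2]]$cv$x, h0 + x)
})

test_that("zeroing the first convolution reduces the block to its residual path", {
  gen <- generator_new(generator_config(base_channels = 4L, dropout = 0), seed = 5)
  gen$P[["enc1.rrb1.conv1.w"]][] <- 0
  gen$P[["enc1.rrb1.conv2.w"]][] <- 0
  x <- array(runif(8 * 8 * 4), c(8, 8, 4, 2))
  r <- legeit:::.rrb_f(gen, "enc1.rrb1", x, train = TRUE)
  res <- conv2d_fwd_cpp(x, gen$P[["enc1.rrb1.res.w"]],
                        gen$P[["enc1.rrb1.res.b"]], 1L, 0L, 1L, 1L)
  expect_equal(r$y, lrelu_y_cpp(res, 0.2), tolerance = 1e-10)
})

test_that("BAM degenerates to beta * x when alpha = gamma = 0", {
  gen <- generator_new(generator_config(base_channels = 4L, dropout = 0), seed = 4)
  p <- "enc1.rrb1.bam"
  gen$P[[paste0(p, ".abg")]] <- c(0, 0.3, 0)
  # identity statistics for the fusion batch norm in inference mode
  gen$S[[paste0(p, ".bn.rm")]] <- rep(0, 4)
  gen$S[[paste0(p, ".bn.rv")]] <- rep(1, 4)
  z <- array(runif(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  out <- legeit:::.bam_f(gen, p, z, train = FALSE, gen$cfg)$y
  expect_equal(out, 0.3 * z, tolerance = 1e-4)
})

test_that("BAM fusion weights start at 0.5/0.3/0.2 and are trainable", {
  gen <- generator_new(generator_config(base_channels = 4L, dropout = 0), seed = 6)
  abg_names <- grep("\\.abg$", names(gen$P), value = TRUE)
  expect_gt(length(abg_names), 0)
  for (nm in abg_names) expect_equal(gen$P[[nm]], c(0.5, 0.3, 0.2))
  # edge kernels start at the discrete Laplacian
  ek <- gen$P[["enc1.rrb1.bam.edge.w"]]
  expect_equal(ek[, , 1, 1], matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  # Laplacian response of a constant map vanishes in the interior (the
  # zero-padded border responds); at zero response the adaptive threshold
  # puts Me exactly at sigmoid(0) = 0.5
  z1 <- array(1, c(8, 8, 4, 1))
  b1 <- legeit:::.bam_f(gen, "enc1.rrb1.bam", z1, train = FALSE, gen$cfg)
  e1 <- conv2d_fwd_cpp(z1, gen$P[["enc1.rrb1.bam.edge.w"]], NULL, 1L, 1L, 1L, 4L)
  expect_equal(max(abs(e1[2:7, 2:7, , ])), 0)
  z0 <- array(0, c(8, 8, 4, 1))
  b0 <- legeit:::.bam_f(gen, "enc1.rrb1.bam", z0, train = FALSE, gen$cfg)
  expect_equal(as.vector(b0$cache$ed$Me), rep(0.5, 8 * 8 * 4), tolerance = 1e-12)
})

test_that("every trainable tensor receives gradient on a random batch", {
  set.seed(2)
  gen <- generator_new(generator_config(base_channels = 16L, dropout = 0),
                       seed = 2)
  x <- array(runif(32 * 32 * 1 * 8, 0, 2), c(32, 32, 1, 8))
  gy <- array(rnorm(32 * 32 * 8), c(32, 32, 1, 8))
  nn_zero_grads(gen)
  f <- generator_forward(gen, x, train = TRUE, keep_cache = TRUE)
  generator_backward(gen, f$cache, gy)
  zero <- names(Filter(function(g) all(g == 0), gen$G))
  expect_length(zero, 0)
})

test_that("critic emits a 3x3 patch map at 64x64 with 64..512 channels", {
  cr <- critic_new(base = 64L, seed = 2)
  cond <- array(runif(64 * 64 * 2, 0, 2), c(64, 64, 1, 2))
  targ <- array(runif(64 * 64 * 2, 0, 2), c(64, 64, 1, 2))
  s <- critic_forward(cr, cond, targ)$score
  expect_equal(dim(s), c(3L, 3L, 1L, 2L))
  expect_equal(vapply(1:5, function(l) dim(cr$P[[paste0("c", l, ".w")]])[4],
                      integer(1)), c(64L, 128L, 256L, 512L, 1L))
  # input sensitivity: swapping target with condition changes the score map
  s2 <- critic_forward(cr, targ, cond)$score
  expect_false(isTRUE(all.equal(s, s2)))
  expect_error(critic_forward(cr, cond, targ[1:32, 1:32, , , drop = FALSE]),
               "mismatch")
})

test_that("full-size generator parameter count is within 15% of 12.6 M", {
  gen <- generator_new(generator_config(base_channels = 32L), seed = 1)
  np <- n_parameters(gen)
  expect_lt(abs(np - 12.6e6) / 12.6e6, 0.15)
  # critic lands near its reported 2.8 M
  cr <- critic_new(base = 64L, seed = 1)
  expect_lt(abs(n_parameters(cr) - 2.8e6) / 2.8e6, 0.15)
})

test_that("resolution-adapted configurations grow monotonically", {
  rs <- resolution_summary(generator_config(base_channels = 8L))
  expect_true(all(diff(rs$parameters) > 0))
  expect_true(all(diff(rs$macs) > 0))
})
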