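test_that("initialization follows the stated schemes and is reproducible", {
  gen <- generator_new(generator_config(base_channels = 8L), seed = 1)
  cr <- critic_new(base = 16L, seed = 1)
  initialize_models(gen, cr, seed = 9)
  # critic: N(0, 0.02) on a large conv tensor
  w <- cr$P[["c4.w"]]
  expect_lt(abs(sd(w) - 0.02) / 0.02, 0.2)
  expect_lt(abs(mean(w)), 0.005)
  # Kaiming: weight variance scales inversely with fan-in
  w1 <- gen$P[["enc1.rrb1.conv1.w"]]    # fan-in 9 * 8
  w4 <- gen$P[["enc4.rrb1.conv1.w"]]    # fan-in 9 * 64
  ratio <- stats::var(as.vector(w1)) / stats::var(as.vector(w4))
  expect_lt(abs(ratio - 8) / 8, 0.25)
  # BAM fusion weights reset to 0.5/0.3/0.2
  expect_equal(gen$P[["enc1.rrb1.bam.abg"]], c(0.5, 0.3, 0.2))
  # same seed, bit-identical
  gen2 <- generator_new(generator_config(base_channels = 8L), seed = 1)
  cr2 <- critic_new(base = 16L, seed = 1)
  initialize_models(gen2, cr2, seed = 9)
  expect_identical(gen$P, gen2$P)
  expect_identical(cr$P, cr2$P)
})

test_that("cosine annealing starts at lr0 and ends at lr_min", {
  expect_equal(cosine_lr(1e-4, 1, 120), 1e-4)
  expect_equal(cosine_lr(1e-4, 120, 120), 1e-6)
  lrs <- vapply(1:120, function(e) cosine_lr(1e-4, e, 120), numeric(1))
  expect_true(all(diff(lrs) < 0))
})

test_that("one step trains the critic five times then the generator once", {
  set.seed(41)
  cfg <- train_config(batch = 2L, base_channels = 4L, critic_base = 8L,
                      dropout = 0, seed = 1)
  gen <- generator_new(generator_config(base_channels = 4L, dropout = 0), 1)
  cr <- critic_new(8L, 2)
  legeit:::.adam_new(gen); legeit:::.adam_new(cr)
  masks <- layer_masks(32, 16)
  x <- array(runif(32 * 32 * 2, 0, 2), c(32, 32, 1, 2))
  y <- array(runif(32 * 32 * 2, 0, 2), c(32, 32, 1, 2))
  rec <- train_step(gen, cr, x, y, cfg, 1e-4, 4e-4, masks)
  expect_equal(rec$n_critic_updates, 5L)
  expect_equal(rec$n_gen_updates, 1L)
  expect_equal(cr$opt$t, 5L)        # optimizer step counters
  expect_equal(gen$opt$t, 1L)
  # post-clip gradient norms never exceed the clip threshold
  expect_true(all(rec$gnorm_d <= cfg$grad_clip + 1e-6))
  expect_lte(rec$gnorm_g, cfg$grad_clip + 1e-6)
})

test_that("zero learning rates leave both models unchanged", {
  set.seed(42)
  cfg <- train_config(batch = 2L, base_channels = 4L, critic_base = 8L,
                      dropout = 0, seed = 1)
  gen <- generator_new(generator_config(base_channels = 4L, dropout = 0), 1)
  cr <- critic_new(8L, 2)
  legeit:::.adam_new(gen); legeit:::.adam_new(cr)
  p0 <- gen$P; c0 <- cr$P
  x <- array(runif(32 * 32 * 2, 0, 2), c(32, 32, 1, 2))
  y <- array(runif(32 * 32 * 2, 0, 2), c(32, 32, 1, 2))
  train_step(gen, cr, x, y, cfg, 0, 0, layer_masks(32, 16))
  expect_equal(gen$P, p0)
  expect_equal(cr$P, c0)
})

test_that("a smoke fit runs, records history and reproduces bit-identically", {
  sens <- get_sens()
  ds <- eit_dataset(24, base_seed = 700, sens = sens,
                    htv_config = htv_config(max_iter = 8))
  cfg <- train_config(batch = 4L, epochs = 2L, base_channels = 4L,
                      critic_base = 8L, seed = 5)
  m1 <- eitgan(ds, cfg)
  expect_s3_class(m1, "eitgan")
  expect_equal(nrow(m1$history), 2)
  expect_true(all(c("d_loss", "g_loss", "val_rmse", "val_ssim") %in%
                    names(m1$history)))
  expect_gte(m1$best$epoch, 1)
  # the retained checkpoint maximizes validation SSIM
  expect_equal(m1$best$val_ssim, max(m1$history$val_ssim))
  # full reproducibility of the loss traces under the same seed
  m2 <- eitgan(ds, cfg)
  expect_identical(m1$history, m2$history)
  # prediction interface
  pred <- predict(m1, ds)
  expect_equal(dim(pred), dim(ds$truth))
  expect_true(all(pred >= 0 & pred <= 2))
  # fitted-model methods
  expect_output(print(m1), "WGAN-GP")
  expect_true(is.matrix(coef(m1)) && ncol(coef(m1)) == 3)
  res <- residuals(m1, ds)
  expect_equal(dim(res)[3], length(m1$split$test))
  expect_error(eitgan(eit_dataset(24, base_seed = 701, sens = sens,
                                  htv = FALSE), cfg), "HTV")
})
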