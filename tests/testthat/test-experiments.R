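test_that("the BAM ablation grid enumerates all eight branch combinations", {
  g <- bam_ablation_grid()
  expect_equal(nrow(g), 8)
  expect_equal(nrow(unique(g)), 8)
  # row 1 is the no-BAM baseline, row 8 the full module
  expect_equal(unlist(g[1, ]), c(spatial = FALSE, channel = FALSE, edge = FALSE))
  expect_equal(unlist(g[8, ]), c(spatial = TRUE, channel = TRUE, edge = TRUE))
  # single branches and pairs are all present
  expect_equal(rowSums(g), c(0, 1, 1, 1, 2, 2, 2, 3), ignore_attr = TRUE)
})

test_that("branch-disabled generators drop the corresponding parameters", {
  g <- bam_ablation_grid()
  base <- generator_config(base_channels = 4L)
  for (r in c(1, 4, 8)) {
    cfg <- generator_config(base_channels = 4L, spatial = g$spatial[r],
                            channel = g$channel[r], edge = g$edge[r])
    gen <- generator_new(cfg, seed = 1)
    has_sp <- any(grepl("bam\\.s1", names(gen$P)))
    has_ch <- any(grepl("bam\\.fc1", names(gen$P)))
    has_ed <- any(grepl("bam\\.edge", names(gen$P)))
    expect_equal(has_sp, g$spatial[r])
    expect_equal(has_ch, g$channel[r])
    expect_equal(has_ed, g$edge[r])
    # the network still runs
    y <- generator_forward(gen, array(runif(32 * 32), c(32, 32, 1, 1)))$y
    expect_true(all(y >= 0 & y <= 2))
  }
})

test_that("evaluating truth against itself gives the ideal metric rows", {
  set.seed(51)
  truth <- array(runif(16 * 16 * 4, 0, 2), c(16, 16, 4))
  agg <- metric_report(truth, truth, "oracle", "clean")$aggregate
  expect_equal(agg$rmse_mean, 0)
  expect_equal(agg$ssim_mean, 1)
  expect_equal(agg$psnr_mean, 99)
})

test_that("the noise sweep evaluates HTV per condition on stored voltages", {
  sens <- get_sens()
  ds <- eit_dataset(6, base_seed = 800, sens = sens,
                    htv_config = htv_config(max_iter = 8))
  out <- run_experiment(NULL, ds, snrs = c(Inf, 30), subset = 1:6)
  expect_equal(nrow(out), 2)
  expect_setequal(out$condition, c("clean", "30"))
  # stronger noise cannot improve the pre-reconstruction on average
  expect_gt(out$rmse_mean[out$condition == "30"],
            0.8 * out$rmse_mean[out$condition == "clean"])
  expect_true(all(out$method == "HTV"))
})
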