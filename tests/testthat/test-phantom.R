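test_that("phantom generation is deterministic and respects tissue ranges", {
  p1 <- generate_phantom(42)
  p2 <- generate_phantom(42)
  expect_identical(p1$conductivity, p2$conductivity)
  expect_identical(p1$labels, p2$labels)

  cfg <- tissue_config()
  lab <- tissue_labels()
  ranges <- cfg$conductivity
  for (seed in seq(0, 120, by = 5)) {
    p <- generate_phantom(seed)
    expect_true(all(p$conductivity >= 0 & p$conductivity <= 2))
    # exhaustive label/conductivity range audit
    for (nm in names(ranges)) {
      sel <- p$labels == lab[[nm]]
      if (any(sel)) {
        expect_true(all(p$conductivity[sel] >= ranges[[nm]][1] - 1e-12),
                    label = paste(nm, "lower bound, seed", seed))
        expect_true(all(p$conductivity[sel] <= ranges[[nm]][2] + 1e-12),
                    label = paste(nm, "upper bound, seed", seed))
      }
    }
    # outside the disc: background label and reference conductivity
    expect_true(all(p$labels[!p$mask] == 0L))
    expect_true(all(p$conductivity[!p$mask] == cfg$background))
    expect_true(p$skin_thickness >= 1 && p$skin_thickness <= 3)
    expect_true(p$fat_thickness >= 5 && p$fat_thickness <= 10)
    expect_lte(length(p$anomalies), 3L)
  }
})

test_that("radial layer order holds along rays and anomalies sit in muscle", {
  lab <- tissue_labels()
  for (seed in c(3, 57, 91)) {
    p <- generate_phantom(seed)
    cx <- (p$grid + 1) / 2
    rmus <- p$radius - p$skin_thickness - p$fat_thickness
    # exact radial layer bands: skin outermost, fat inside it, interior
    # tissue beyond -- this makes the layer sequence monotone along every ray
    d <- sqrt((row(p$labels) - cx)^2 + (col(p$labels) - cx)^2)
    skin_band <- p$mask & d > p$radius - p$skin_thickness
    fat_band <- d <= p$radius - p$skin_thickness & d > rmus
    interior <- d <= rmus
    expect_true(all(p$labels[skin_band] == lab[["skin"]]))
    expect_true(all(p$labels[fat_band] == lab[["fat"]]))
    expect_true(all(!p$labels[interior] %in%
                      c(lab[["background"]], lab[["skin"]], lab[["fat"]])))
    # monotone depth along 360 rays (derived from the exact bands)
    for (th in seq(0, 2 * pi, length.out = 36)) {
      rr <- seq(0.5, p$radius - 0.25, by = 0.5)
      ii <- round(cx + rr * sin(th)); jj <- round(cx + rr * cos(th))
      dd <- sqrt((ii - cx)^2 + (jj - cx)^2)
      labs <- p$labels[cbind(ii, jj)]
      depth <- ifelse(labs == lab[["skin"]], 3,
               ifelse(labs == lab[["fat"]], 2,
               ifelse(labs == lab[["background"]], 4, 1)))
      o <- order(dd)
      expect_true(all(diff(depth[o]) >= 0),
                  label = paste("ray monotone, seed", seed))
    }
    for (a in p$anomalies) {
      d <- sqrt(sum((a$center - cx)^2))
      expect_lt(d, rmus)
    }
  }
})

test_that("anomaly probability zero yields anomaly-free phantoms", {
  for (seed in 1:10) {
    p <- generate_phantom(seed, config = tissue_config(anomaly_prob = 0))
    expect_length(p$anomalies, 0)
  }
})

test_that("tissue config validation rejects out-of-range conductivities", {
  bad <- tissue_config()
  bad$conductivity$vessel <- c(1.2, 2.5)
  expect_error(generate_phantom(1, config = bad), "\\[0, 2\\]")
})

test_that("dataset generation is deterministic and validates n", {
  expect_error(generate_dataset(0), ">= 1")
  expect_length(generate_dataset(1, base_seed = 7), 1)
  d1 <- generate_dataset(4, base_seed = 11)
  d2 <- generate_dataset(4, base_seed = 11)
  for (i in 1:4)
    expect_identical(d1[[i]]$conductivity, d2[[i]]$conductivity)
})

test_that("dataset split has exact sizes and partitions the indices", {
  s <- split_dataset(4800, seed = 3)
  expect_length(s$train, 3840)
  expect_length(s$val, 480)
  expect_length(s$test, 480)
  expect_setequal(c(s$train, s$val, s$test), 1:4800)
  expect_length(intersect(s$train, s$val), 0)
  expect_length(intersect(s$train, s$test), 0)
  expect_length(intersect(s$val, s$test), 0)

  s10 <- split_dataset(10, seed = 1)
  expect_equal(lengths(s10)[c("train", "val", "test")],
               c(train = 8L, val = 1L, test = 1L))
  expect_error(split_dataset(10, ratios = c(0.7, 0.1, 0.1)), "sum to 1")
  # determinism
  expect_identical(split_dataset(100, seed = 9), split_dataset(100, seed = 9))
})

test_that("augmentation draws right-angle rotations and is involutive at 180", {
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  for (seed in 1:20) {
    a <- augment(x, y, seed = seed)
    expect_true(a$rotation %in% c(0, 90, 180, 270))
  }
  idn <- augment(x, y, rotation = 0, flip = FALSE, noise_sd = 0)
  expect_identical(idn$input, x)
  expect_identical(idn$label, y)
  r180 <- augment(x, y, rotation = 180, flip = FALSE, noise_sd = 0)
  back <- augment(r180$input, r180$label, rotation = 180, flip = FALSE,
                  noise_sd = 0)
  expect_equal(back$input, x)
  expect_equal(back$label, y)
  expect_error(augment(matrix(0, 4, 6), matrix(0, 4, 6)), "square")
  # geometry identical on both images, noise on the input only
  a <- augment(x, y, seed = 5, noise_sd = 0.01)
  b <- augment(x, y, seed = 5, noise_sd = 0)
  expect_identical(a$label, b$label)
  expect_false(identical(a$input, b$input))
  expect_lt(max(abs(a$input - b$input)), 0.08)
})
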