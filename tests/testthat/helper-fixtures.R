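# Shared fixtures, built once per test run.

.fixtures <- new.env()

# full-geometry sensitivity model (64 x 64 grid, R = 30); ~1 s to build
get_sens <- function() {
  if (is.null(.fixtures$sens)) .fixtures$sens <- build_sensitivity()
  .fixtures$sens
}

# a small batch of phantoms with clean voltages
get_phantom_batch <- function(n = 6, seed = 400) {
  key <- paste0("ph", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    phs <- generate_dataset(n, base_seed = seed)
    v <- vapply(phs, function(p) solve_forward(get_sens(), p),
                numeric(nrow(get_sens()$J)))
    .fixtures[[key]] <- list(phantoms = phs, voltages = v)
  }
  .fixtures[[key]]
}

# brute-force SSIM oracle: direct sliding-window evaluation
bruteforce_ssim <- function(x, y, dr = 2, size = 11, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  C1 <- (0.01 * dr)^2; C2 <- (0.03 * dr)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in 1:(H - size + 1)) for (j in 1:(W - size + 1)) {
    wx <- x[i:(i + size - 1), j:(j + size - 1)]
    wy <- y[i:(i + size - 1), j:(j + size - 1)]
    ux <- sum(k * wx); uy <- sum(k * wy)
    sx <- sum(k * wx^2) - ux^2; sy <- sum(k * wy^2) - uy^2
    sxy <- sum(k * wx * wy) - ux * uy
    vals <- c(vals, (2 * ux * uy + C1) * (2 * sxy + C2) /
                ((ux^2 + uy^2 + C1) * (sx + sy + C2)))
  }
  mean(vals)
}

as4 <- function(m) array(m, c(dim(m), 1L, 1L))
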