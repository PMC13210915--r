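# Image quality metrics: RMSE, windowed SSIM, PSNR, and the relative-change
# arithmetic used to compare methods.

.gauss_kernel <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Windowed SSIM core on (H,W,1,N) tensors; valid windows only.
# Returns the per-sample mean SSIM and everything needed for its gradient.
.ssim_core <- function(x, y, dynamic_range = 2, size = 11L, sigma = 1.5) {
  k <- array(.gauss_kernel(size, sigma), c(size, size, 1L, 1L))
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  f <- function(z) conv2d_fwd_cpp(z, k, NULL, 1L, 0L, 1L, 1L)
  ux <- f(x); uy <- f(y)
  sxx <- f(x * x) - ux^2
  syy <- f(y * y) - uy^2
  sxy <- f(x * y) - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * sxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  d <- dim(S)
  mssim <- colMeans(matrix(S, ncol = d[4]))
  list(mssim = mssim, S = S, ux = ux, uy = uy, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2, k = k, xdim = dim(x))
}

# gradient of mean(S) (mean over windows and batch) w.r.t. x
.ssim_grad <- function(cs, x, y) {
  d <- dim(cs$S)
  Nw <- prod(d)                         # windows x batch
  adj <- function(z) conv2d_bwd_input_cpp(z, cs$k, cs$xdim[1], cs$xdim[2],
                                          1L, 0L, 1L, 1L)
  with(cs, {
    dS_dux <- (2 * uy * B1 - 2 * ux * A1) / B1^2 * (A2 / B2)
    dS_dsxx <- -(A1 / B1) * A2 / B2^2
    dS_dsxy <- (A1 / B1) * 2 / B2
    t1 <- (dS_dux - 2 * ux * dS_dsxx - uy * dS_dsxy) / Nw
    t2 <- dS_dsxx / Nw
    t3 <- dS_dsxy / Nw
    adj(t1) + 2 * x * adj(t2) + y * adj(t3)
  })
}

#' Root mean square error between two images
#' @param pred,truth numeric arrays of identical shape.
#' @return non-negative scalar.
#' @export
metric_rmse <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  sqrt(mean((pred - truth)^2))
}

#' Structural similarity index (Gaussian window 11, sigma 1.5)
#'
#' Mean of the windowed SSIM map over valid windows.  The stability constants
#' are `C1 = (0.01 Dr)^2`, `C2 = (0.03 Dr)^2` for dynamic range `Dr`; with
#' `dynamic_range = 255` these equal the classic 6.5025 and 58.5225, while
#' conductivity images in `[0, 2]` use `Dr = 2` (SSIM is invariant under the
#' common affine rescaling between the two readings).
#'
#' @param pred,truth images (matrices or `(H,W,1,N)` arrays), at least 11x11.
#' @param dynamic_range value range `Dr` of the data.
#' @return scalar (or per-sample vector for batched input) in `[-1, 1]`.
#' @export
metric_ssim <- function(pred, truth, dynamic_range = 2) {
  single <- is.matrix(pred)
  if (single) { pred <- tens4(pred); truth <- tens4(truth) }
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (dim(pred)[1] < 11 || dim(pred)[2] < 11) stop("image smaller than the SSIM window")
  m <- .ssim_core(pred, truth, dynamic_range)$mssim
  if (single) m[1] else m
}

#' SSIM stability constants for a dynamic range
#' @param dynamic_range data range `Dr`.
#' @return named vector with `C1 = (0.01 Dr)^2` and `C2 = (0.03 Dr)^2`.
#' @export
ssim_constants <- function(dynamic_range) {
  c(C1 = (0.01 * dynamic_range)^2, C2 = (0.03 * dynamic_range)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `PSNR = 10 log10(MAX^2 / MSE)` with `MAX = 2` for conductivity images in
#' `[0, 2]`.  Identical images return the capped sentinel.
#'
#' @param pred,truth images of identical shape.
#' @param max_value peak value `MAX`.
#' @param cap sentinel returned when MSE is zero.
#' @return scalar in dB.
#' @export
metric_psnr <- function(pred, truth, max_value = 2, cap = 99) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  mse <- mean((pred - truth)^2)
  if (mse == 0) return(cap)
  min(10 * log10(max_value^2 / mse), cap)
}

#' Relative change between two metric values, in percent
#'
#' Returns `100 * |after - before| / before`, labelled as a decrease when
#' `after < before` and an increase otherwise (the sign convention used when
#' quoting, e.g., "RMSE decreased by 60.1%").
#'
#' @param before baseline value (nonzero).
#' @param after comparison value.
#' @return numeric percentage with attribute `direction` and class
#'   `"relative_change"`.
#' @export
relative_change <- function(before, after) {
  if (before == 0) stop("zero baseline")
  pct <- 100 * (after - before) / before
  structure(abs(pct),
            direction = if (pct < 0) "decrease" else if (pct > 0) "increase" else "none",
            class = "relative_change")
}

#' @export
print.relative_change <- function(x, ...) {
  cat(sprintf("%.1f%% %s\n", unclass(x), attr(x, "direction")))
  invisible(x)
}
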