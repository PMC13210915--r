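# Leg-anatomy prior loss: pixel, Sobel edge, layered-tissue, total-variation,
# SSIM and histogram-matching terms, plus the WGAN-GP critic and generator
# objectives.  Every term has an analytic gradient used by the trainer.

#' Loss weights of the composite anatomy-prior objective
#'
#' @param lambda_pix,lambda_edge,lambda_layer,lambda_tv,lambda_ssim,lambda_hist
#'   weights of the six anatomy-prior terms.
#' @param lambda_gp gradient penalty coefficient of the critic objective.
#' @return named list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_pix = 100, lambda_edge = 30, lambda_layer = 20,
                         lambda_tv = 5, lambda_ssim = 10, lambda_hist = 2,
                         lambda_gp = 10) {
  w <- list(pix = lambda_pix, edge = lambda_edge, layer = lambda_layer,
            tv = lambda_tv, ssim = lambda_ssim, hist = lambda_hist,
            gp = lambda_gp)
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0")
  structure(w, class = "loss_weights")
}

#' Concentric layer masks of the leg cross-section
#'
#' Partition of the in-disc pixels into four rings by distance `d` from the
#' image center: skin `R-3 < d <= R`, fat `R-10 < d <= R-3`, muscle
#' `0.35R < d <= R-10`, core `d <= 0.35R`.  The masks are pairwise disjoint
#' and their union is the disc.
#'
#' @param grid image size.
#' @param radius leg radius R in pixels.
#' @return named list of four logical matrices `skin`, `fat`, `muscle`, `core`.
#' @export
layer_masks <- function(grid = 64L, radius = 30) {
  d <- .disc(grid)
  R <- radius
  list(skin = d <= R & d > R - 3,
       fat = d <= R - 3 & d > R - 10,
       muscle = d <= R - 10 & d > 0.35 * R,
       core = d <= 0.35 * R)
}

.as_batch <- function(x) if (is.matrix(x)) tens4(x) else x

.check_pair <- function(pred, truth) {
  if (!identical(dim(.as_batch(pred)), dim(.as_batch(truth))))
    stop("shape mismatch between pred and truth")
}

#' Pixel loss: L1 plus 0.5 x squared L2, mean-reduced
#' @param pred,truth images or `(H,W,1,N)` batches.
#' @return scalar.
#' @export
pixel_loss <- function(pred, truth) {
  .check_pair(pred, truth)
  d <- pred - truth
  mean(abs(d)) + 0.5 * mean(d^2)
}

.pixel_grad <- function(pred, truth) (sign(pred - truth) + (pred - truth)) / length(pred)

.sobel_k <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dx (columns)
  list(gx = array(gx, c(3, 3, 1, 1)), gy = array(t(gx), c(3, 3, 1, 1)))
}

.sobel_mag <- function(x, eps = 1e-8) {
  # valid convolution: no border padding, so constant images respond exactly 0
  k <- .sobel_k()
  gx <- conv2d_fwd_cpp(x, k$gx, NULL, 1L, 0L, 1L, 1L)
  gy <- conv2d_fwd_cpp(x, k$gy, NULL, 1L, 0L, 1L, 1L)
  list(mag = sqrt(gx^2 + gy^2 + eps), gx = gx, gy = gy)
}

#' Sobel edge loss
#'
#' L1 distance between the Sobel gradient-magnitude maps of the two images,
#' mean-reduced.
#' @inheritParams pixel_loss
#' @return scalar.
#' @export
edge_loss <- function(pred, truth) {
  .check_pair(pred, truth)
  p <- .sobel_mag(.as_batch(pred)); t <- .sobel_mag(.as_batch(truth))
  mean(abs(p$mag - t$mag))
}

.edge_grad <- function(pred, truth) {
  p <- .sobel_mag(pred); tt <- .sobel_mag(truth)
  s <- sign(p$mag - tt$mag) / length(p$mag)
  k <- .sobel_k()
  d <- dim(pred)
  dgx <- s * p$gx / p$mag
  dgy <- s * p$gy / p$mag
  conv2d_bwd_input_cpp(dgx, k$gx, d[1], d[2], 1L, 0L, 1L, 1L) +
    conv2d_bwd_input_cpp(dgy, k$gy, d[1], d[2], 1L, 0L, 1L, 1L)
}

#' Layered-tissue constraint loss
#'
#' Sum over the four concentric rings of the absolute difference between the
#' masked mean conductivities of prediction and truth (batch-averaged).
#'
#' @inheritParams pixel_loss
#' @param masks a [layer_masks()] list.
#' @return scalar.
#' @export
layer_loss <- function(pred, truth, masks = layer_masks()) {
  .check_pair(pred, truth)
  p <- .as_batch(pred); tt <- .as_batch(truth)
  N <- dim(p)[4]
  tot <- 0
  for (m in masks) {
    nm <- sum(m)
    if (nm == 0) { warning("empty layer mask skipped"); next }
    for (n in seq_len(N))
      tot <- tot + abs(mean(p[, , 1, n][m]) - mean(tt[, , 1, n][m]))
  }
  tot / N
}

.layer_grad <- function(pred, truth, masks) {
  d <- dim(pred); N <- d[4]
  g <- array(0, d)
  for (m in masks) {
    nm <- sum(m)
    if (nm == 0) next
    for (n in seq_len(N)) {
      s <- sign(mean(pred[, , 1, n][m]) - mean(truth[, , 1, n][m]))
      pl <- g[, , 1, n]; pl[m] <- pl[m] + s / nm; g[, , 1, n] <- pl
    }
  }
  g / N
}

#' Anisotropic total variation
#'
#' Sum of absolute forward differences in both directions, no wraparound.
#' @param pred image or batch.
#' @param reduction `"sum"` (the literal definition) or `"mean"`
#'   (divided by the pixel count, the convention inside [total_loss()]).
#' @return scalar.
#' @export
tv_loss <- function(pred, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  p <- .as_batch(pred)
  d <- dim(p)
  v <- sum(abs(p[-1, , , , drop = FALSE] - p[-d[1], , , , drop = FALSE])) +
       sum(abs(p[, -1, , , drop = FALSE] - p[, -d[2], , , drop = FALSE]))
  if (reduction == "mean") v / (d[1] * d[2] * d[4]) else v
}

.tv_grad <- function(pred) {
  d <- dim(pred)
  g <- array(0, d)
  dh <- sign(pred[-1, , , , drop = FALSE] - pred[-d[1], , , , drop = FALSE])
  dv <- sign(pred[, -1, , , drop = FALSE] - pred[, -d[2], , , drop = FALSE])
  g[-1, , , ] <- g[-1, , , , drop = FALSE] + dh
  g[-d[1], , , ] <- g[-d[1], , , , drop = FALSE] - dh
  g[, -1, , ] <- g[, -1, , , drop = FALSE] + dv
  g[, -d[2], , ] <- g[, -d[2], , , drop = FALSE] - dv
  g / (d[1] * d[2] * d[4])
}

#' SSIM loss: one minus the mean windowed SSIM
#' @inheritParams pixel_loss
#' @param dynamic_range data range for the stability constants.
#' @return scalar in `[0, 2]`.
#' @export
ssim_loss <- function(pred, truth, dynamic_range = 2) {
  .check_pair(pred, truth)
  1 - mean(metric_ssim(.as_batch(pred), .as_batch(truth), dynamic_range))
}

#' Histogram matching loss
#'
#' L1 distance between the ascending-sorted pixel vectors of prediction and
#' truth, per image.
#' @inheritParams pixel_loss
#' @param reduction `"sum"` (the literal definition) or `"mean"`.
#' @return scalar (batch-averaged).
#' @export
hist_loss <- function(pred, truth, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  .check_pair(pred, truth)
  p <- .as_batch(pred); tt <- .as_batch(truth)
  d <- dim(p); N <- d[4]; npx <- d[1] * d[2]
  tot <- 0
  for (n in seq_len(N))
    tot <- tot + sum(abs(sort(as.vector(p[, , 1, n])) -
                         sort(as.vector(tt[, , 1, n]))))
  tot <- tot / N
  if (reduction == "mean") tot / npx else tot
}

.hist_grad <- function(pred, truth) {
  d <- dim(pred); N <- d[4]; npx <- d[1] * d[2]
  g <- array(0, d)
  for (n in seq_len(N)) {
    pv <- as.vector(pred[, , 1, n])
    o <- order(pv)
    s <- sign(pv[o] - sort(as.vector(truth[, , 1, n])))
    gi <- numeric(npx); gi[o] <- s
    g[, , 1, n] <- gi
  }
  g / (N * npx)
}

#' Composite anatomy-prior loss
#'
#' Weighted sum of the six terms.  Inside the total every term is
#' mean-reduced per image and averaged over the batch so that the stated
#' weights stay scale-comparable across resolutions.
#'
#' @inheritParams pixel_loss
#' @param weights a [loss_weights()].
#' @param masks a [layer_masks()] list.
#' @param dynamic_range passed to the SSIM term.
#' @return list with `total` and the unweighted `components`.
#' @export
total_loss <- function(pred, truth, weights = loss_weights(),
                       masks = layer_masks(dim(.as_batch(pred))[1]),
                       dynamic_range = 2) {
  p <- .as_batch(pred); tt <- .as_batch(truth)
  comp <- c(pix = pixel_loss(p, tt),
            edge = edge_loss(p, tt),
            layer = layer_loss(p, tt, masks),
            tv = tv_loss(p, reduction = "mean"),
            ssim = ssim_loss(p, tt, dynamic_range),
            hist = hist_loss(p, tt, reduction = "mean"))
  lam <- c(weights$pix, weights$edge, weights$layer, weights$tv,
           weights$ssim, weights$hist)
  list(total = sum(lam * comp), components = comp)
}

# value + components + gradient w.r.t. pred (training path)
.total_loss_grad <- function(pred, truth, weights, masks, dynamic_range = 2) {
  p <- .as_batch(pred); tt <- .as_batch(truth)
  d <- dim(p)
  val <- total_loss(p, tt, weights, masks, dynamic_range)
  cs <- .ssim_core(p, tt, dynamic_range)
  g <- weights$pix * .pixel_grad(p, tt) +
    weights$edge * .edge_grad(p, tt) +
    weights$layer * .layer_grad(p, tt, masks) +
    weights$tv * .tv_grad(p) +
    weights$ssim * (-.ssim_grad(cs, p, tt)) +
    weights$hist * .hist_grad(p, tt)
  dim(g) <- d
  list(total = val$total, components = val$components, grad = g)
}

## ---- adversarial objectives -------------------------------------------------

.critic_score <- function(critic, cond, target) {
  if (inherits(critic, "eit_critic")) {
    s <- critic_forward(critic, cond, target)$score
    colMeans(matrix(s, ncol = dim(s)[4]))
  } else {
    vapply(seq_len(dim(.as_batch(target))[4]), function(n)
      critic$score(.as_batch(cond)[, , 1, n], .as_batch(target)[, , 1, n]),
      numeric(1))
  }
}

.critic_input_grad <- function(critic, cond, target) {
  # per-sample gradient of D(cond, target) w.r.t. target
  cond <- .as_batch(cond); target <- .as_batch(target)
  if (inherits(critic, "eit_critic")) {
    f <- critic_forward(critic, cond, target, keep_cache = TRUE)
    sdim <- f$cache$sdim
    u <- array(1 / (sdim[1] * sdim[2]), sdim)
    legeit_gchain <- .critic_gchain(critic, f$cache, u)
    legeit_gchain$g[, , 2L, , drop = FALSE]
  } else {
    d <- dim(target)
    g <- array(0, d)
    for (n in seq_len(d[4]))
      g[, , 1, n] <- critic$grad(cond[, , 1, n], target[, , 1, n])
    g
  }
}

#' Gradient penalty at random interpolates
#'
#' `mean((||grad_{y_hat} D(x, y_hat)||_2 - 1)^2)` with `y_hat` a per-sample
#' convex combination of real and fake target images.
#'
#' @param critic an `"eit_critic"` or a list with functions
#'   `score(cond, target)` and `grad(cond, target)`.
#' @param cond,real,fake image batches.
#' @param seed seed for the interpolation coefficients.
#' @return scalar penalty.
#' @export
gradient_penalty <- function(critic, cond, real, fake, seed = 1L) {
  cond <- .as_batch(cond); real <- .as_batch(real); fake <- .as_batch(fake)
  N <- dim(real)[4]
  e <- .with_seed(seed, runif(N))
  mix <- real
  for (n in seq_len(N))
    mix[, , 1, n] <- e[n] * real[, , 1, n] + (1 - e[n]) * fake[, , 1, n]
  g <- .critic_input_grad(critic, cond, mix)
  nrm <- sqrt(colSums(matrix(g, ncol = N)^2))
  mean((nrm - 1)^2)
}

#' Critic (discriminator) objective
#'
#' `E[D(x, G(x))] - E[D(x, y)] + lambda_gp * GP`.
#'
#' @inheritParams gradient_penalty
#' @param lambda_gp gradient penalty coefficient.
#' @return list with `value` and `components` (wasserstein, gp).
#' @export
critic_objective <- function(critic, cond, real, fake, lambda_gp = 10,
                             seed = 1L) {
  wass <- mean(.critic_score(critic, cond, fake)) -
    mean(.critic_score(critic, cond, real))
  gp <- gradient_penalty(critic, cond, real, fake, seed)
  list(value = wass + lambda_gp * gp,
       components = c(wasserstein = wass, gp = gp))
}

#' Generator objective
#'
#' `-E[D(x, G(x))] + L_total`.
#'
#' @inheritParams gradient_penalty
#' @param truth ground-truth conductivity batch.
#' @param weights a [loss_weights()].
#' @param masks a [layer_masks()] list.
#' @return list with `value` and `components` (adversarial plus the six
#'   anatomy-prior terms).
#' @export
generator_objective <- function(critic, cond, fake, truth,
                                weights = loss_weights(),
                                masks = layer_masks(dim(.as_batch(fake))[1])) {
  adv <- -mean(.critic_score(critic, cond, fake))
  tl <- total_loss(fake, truth, weights, masks)
  list(value = adv + tl$total,
       components = c(adversarial = adv, tl$components))
}
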