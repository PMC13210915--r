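# WGAN-GP training of the BAM-R2UNet post-processor, with the classic
# fit-object interface: eitgan() returns a classed model with print, summary,
# predict, plot, coef and residuals methods.

#' Training configuration
#'
#' Defaults follow the reference training recipe: batch 16, 120 epochs,
#' generator/critic learning rates 1e-4 / 4e-4 with cosine annealing to 1e-6,
#' Adam (0.5, 0.999), five critic updates per generator update, gradient
#' penalty 10, base channels 32, recurrence t = 2, gradient clipping at
#' global norm 1.
#'
#' @param batch batch size.
#' @param epochs training epochs (no early stopping; the best validation-SSIM
#'   checkpoint is kept).
#' @param lr_g,lr_d initial generator / critic learning rates.
#' @param beta1,beta2 Adam moment coefficients.
#' @param n_critic critic updates per generator update.
#' @param lambda_gp gradient penalty coefficient.
#' @param base_channels generator base channel count.
#' @param critic_base critic first-layer channel count.
#' @param t recurrence count.
#' @param bottleneck_blocks RecurrentBlock-BAM blocks in the bottleneck.
#' @param spatial,channel,edge BAM branch switches (ablations).
#' @param dropout bottleneck dropout.
#' @param grad_clip maximum global gradient norm.
#' @param lr_min cosine annealing endpoint.
#' @param augment apply rotation/flip/noise augmentation to training batches.
#' @param augment_noise_sd augmentation noise on the network input.
#' @param weights a [loss_weights()].
#' @param seed master seed of the run.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(batch = 16L, epochs = 120L, lr_g = 1e-4, lr_d = 4e-4,
                         beta1 = 0.5, beta2 = 0.999, n_critic = 5L,
                         lambda_gp = 10, base_channels = 32L,
                         critic_base = 64L, t = 2L, bottleneck_blocks = 1L,
                         spatial = TRUE, channel = TRUE, edge = TRUE,
                         dropout = 0.1, grad_clip = 1.0, lr_min = 1e-6,
                         augment = TRUE, augment_noise_sd = 0.01,
                         weights = loss_weights(), seed = 1L) {
  stopifnot(n_critic >= 1L, epochs >= 1L, batch >= 1L)
  structure(as.list(environment()), class = "train_config")
}

## ---- optimizer --------------------------------------------------------------

.adam_new <- function(net) {
  net$opt <- list(m = lapply(net$P, function(p) p * 0),
                  v = lapply(net$P, function(p) p * 0), t = 0L)
  invisible(net)
}

.grad_global_norm <- function(net) sqrt(sum(vapply(net$G, function(g) sum(g^2), numeric(1))))

.clip_grads <- function(net, max_norm) {
  gn <- .grad_global_norm(net)
  if (is.finite(max_norm) && gn > max_norm) {
    sc <- max_norm / (gn + 1e-12)
    net$G <- lapply(net$G, function(g) g * sc)
    gn <- max_norm
  }
  gn
}

.adam_step <- function(net, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  o <- net$opt
  o$t <- o$t + 1L
  bc1 <- 1 - beta1^o$t; bc2 <- 1 - beta2^o$t
  for (nm in names(net$P)) {
    g <- net$G[[nm]]
    o$m[[nm]] <- beta1 * o$m[[nm]] + (1 - beta1) * g
    o$v[[nm]] <- beta2 * o$v[[nm]] + (1 - beta2) * g^2
    net$P[[nm]] <- net$P[[nm]] -
      lr * (o$m[[nm]] / bc1) / (sqrt(o$v[[nm]] / bc2) + eps)
  }
  net$opt <- o
  invisible(net)
}

#' Cosine annealing learning rate
#' @param lr0 initial rate.
#' @param epoch 1-based epoch index.
#' @param epochs total epochs.
#' @param lr_min endpoint rate at the final epoch.
#' @return learning rate for the epoch.
#' @export
cosine_lr <- function(lr0, epoch, epochs, lr_min = 1e-6) {
  if (epochs == 1L) return(lr0)
  f <- (epoch - 1) / (epochs - 1)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * f))
}

#' Re-initialize generator and critic weights in place
#'
#' Generator convolution and dense weights: Kaiming (He) normal; batch-norm
#' scale/shift 1/0; BAM edge kernels: discrete Laplacian; BAM fusion scalars:
#' 0.5/0.3/0.2.  Critic weights: normal with mean 0 and sd 0.02, biases 0.
#'
#' @param gen an `"eit_generator"`.
#' @param critic an `"eit_critic"`.
#' @param seed integer seed (same seed, bit-identical initialisation).
#' @export
initialize_models <- function(gen, critic, seed = 1L) {
  .with_seed(seed, {
    for (nm in names(gen$P)) {
      p <- gen$P[[nm]]
      if (endsWith(nm, ".abg")) gen$P[[nm]] <- c(0.5, 0.3, 0.2)
      else if (grepl("\\.edge\\.w$", nm))
        gen$P[[nm]] <- array(rep(laplacian_kernel(), dim(p)[4]), dim(p))
      else if (endsWith(nm, ".w")) gen$P[[nm]] <- init_kaiming(dim(p) %||% length(p))
      else if (endsWith(nm, ".g")) gen$P[[nm]] <- rep(1, length(p))
      else gen$P[[nm]] <- p * 0
    }
    gen$S <- list()
    for (nm in names(critic$P)) {
      p <- critic$P[[nm]]
      critic$P[[nm]] <- if (endsWith(nm, ".w")) init_normal(dim(p)) else p * 0
    }
  })
  invisible(list(generator = gen, critic = critic))
}

## ---- one optimization step --------------------------------------------------

.batch_tensor <- function(arr3, idx) {
  d <- dim(arr3)
  array(arr3[, , idx], c(d[1], d[2], 1L, length(idx)))
}

.augment_batch <- function(x, y, noise_sd) {
  N <- dim(x)[4]
  for (n in seq_len(N)) {
    a <- augment(x[, , 1, n], y[, , 1, n], noise_sd = noise_sd)
    x[, , 1, n] <- a$input
    y[, , 1, n] <- a$label
  }
  list(x = x, y = y)
}

#' One WGAN-GP training step
#'
#' Performs `n_critic` critic updates followed by one generator update, with
#' gradient clipping on both.  The fake batch is generated once per step and
#' reused across the critic iterations (the fake distribution only changes
#' when the generator is updated); random interpolates for the gradient
#' penalty are redrawn at every critic iteration.  Exposed mainly for
#' auditing; [eitgan()] drives it.
#'
#' @param gen,critic the two networks.
#' @param xb,yb the step's batch: HTV inputs and truths, `(H,W,1,N)`.
#' @param config a [train_config()].
#' @param lr_g,lr_d learning rates for this step.
#' @param masks layer masks for the anatomy-prior loss.
#' @return list of loss records and post-clip gradient norms.
#' @export
train_step <- function(gen, critic, xb, yb, config, lr_g, lr_d, masks) {
  d_losses <- numeric(config$n_critic)
  gnorm_d <- numeric(config$n_critic)
  N <- dim(xb)[4]
  fake0 <- generator_forward(gen, xb, train = TRUE)$y
  for (k in seq_len(config$n_critic)) {
    nn_zero_grads(critic)
    ff <- critic_forward(critic, xb, fake0, keep_cache = TRUE)
    sdim <- ff$cache$sdim
    u <- 1 / (sdim[1] * sdim[2] * sdim[4])
    critic_backward(critic, ff$cache, array(u, sdim))
    fr <- critic_forward(critic, xb, yb, keep_cache = TRUE)
    critic_backward(critic, fr$cache, array(-u, sdim))
    e <- runif(N)
    mix <- yb
    for (n in seq_along(e))
      mix[, , 1, n] <- e[n] * yb[, , 1, n] + (1 - e[n]) * fake0[, , 1, n]
    fm <- critic_forward(critic, xb, mix, keep_cache = TRUE)
    pen <- .critic_gp_accumulate(critic, fm$cache, config$lambda_gp)
    d_losses[k] <- mean(ff$score) - mean(fr$score) + config$lambda_gp * pen
    if (!is.finite(d_losses[k])) stop("non-finite critic loss")
    gnorm_d[k] <- .clip_grads(critic, config$grad_clip)
    .adam_step(critic, lr_d, config$beta1, config$beta2)
  }
  # generator update
  nn_zero_grads(gen)
  fw <- generator_forward(gen, xb, train = TRUE, keep_cache = TRUE)
  sup <- .total_loss_grad(fw$y, yb, config$weights, masks)
  nn_zero_grads(critic)   # scratch use of critic gradients
  fc <- critic_forward(critic, xb, fw$y, keep_cache = TRUE)
  sdim <- fc$cache$sdim
  gadv_full <- critic_backward(critic, fc$cache,
                               array(-1 / (sdim[1] * sdim[2] * sdim[4]), sdim))
  nn_zero_grads(critic)
  gy <- sup$grad + gadv_full[, , 2L, , drop = FALSE]
  generator_backward(gen, fw$cache, gy)
  g_adv <- -mean(fc$score)
  g_loss <- g_adv + sup$total
  if (!is.finite(g_loss)) stop("non-finite generator loss")
  gnorm_g <- .clip_grads(gen, config$grad_clip)
  .adam_step(gen, lr_g, config$beta1, config$beta2)
  list(d_loss = mean(d_losses), g_loss = g_loss, g_adv = g_adv,
       components = sup$components, gnorm_g = gnorm_g, gnorm_d = gnorm_d,
       n_critic_updates = config$n_critic, n_gen_updates = 1L)
}

## ---- the fitting function ---------------------------------------------------

#' Fit the BAM-R2UNet EIT post-processor
#'
#' Alternating WGAN-GP optimization of the conditional PatchGAN critic and
#' the boundary-attention recurrent-residual U-Net generator under the
#' six-term anatomy-prior loss.  The dataset is split 80/10/10; per-epoch
#' validation RMSE/SSIM are recorded and the checkpoint with the best
#' validation SSIM is retained in the returned model.
#'
#' @param dataset an [eit_dataset()] with HTV inputs filled.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `"eitgan"`.
#' @export
eitgan <- function(dataset, config = train_config(), verbose = FALSE) {
  if (is.null(dataset$htv)) stop("dataset has no HTV pre-reconstructions")
  g <- dim(dataset$truth)[1]
  radius <- dataset$sens$mesh$radius
  masks <- layer_masks(g, radius)
  split <- split_dataset(dataset$n, seed = config$seed)
  if (length(split$train) < config$batch)
    stop("training split smaller than one batch")
  if (length(split$val) == 0 || length(split$test) == 0)
    stop("empty validation/test split")
  gcfg <- generator_config(base_channels = config$base_channels, t = config$t,
                           bottleneck_blocks = config$bottleneck_blocks,
                           dropout = config$dropout, spatial = config$spatial,
                           channel = config$channel, edge = config$edge)
  gen <- generator_new(gcfg, seed = config$seed)
  critic <- critic_new(config$critic_base, seed = config$seed + 1L)
  initialize_models(gen, critic, seed = config$seed)
  .adam_new(gen); .adam_new(critic)
  hist <- NULL
  best <- list(val_ssim = -Inf, epoch = 0L, P = NULL, S = NULL)
  ntr <- length(split$train)
  steps <- max(1L, ntr %/% config$batch)
  .with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      lr_g <- cosine_lr(config$lr_g, epoch, config$epochs, config$lr_min)
      lr_d <- cosine_lr(config$lr_d, epoch, config$epochs, config$lr_min)
      ord <- sample(split$train)
      recs <- vector("list", steps)
      for (st in seq_len(steps)) {
        idx <- ord[((st - 1L) * config$batch + 1L):(st * config$batch)]
        b <- list(x = .batch_tensor(dataset$htv, idx),
                  y = .batch_tensor(dataset$truth, idx))
        if (config$augment) b <- .augment_batch(b$x, b$y, config$augment_noise_sd)
        recs[[st]] <- train_step(gen, critic, b$x, b$y, config,
                                 lr_g, lr_d, masks)
      }
      vm <- .validate(gen, dataset, split$val, config$batch)
      comp <- Reduce(`+`, lapply(recs, `[[`, "components")) / steps
      row <- data.frame(epoch = epoch, lr_g = lr_g, lr_d = lr_d,
                        d_loss = mean(vapply(recs, `[[`, 0, "d_loss")),
                        g_loss = mean(vapply(recs, `[[`, 0, "g_loss")),
                        g_adv = mean(vapply(recs, `[[`, 0, "g_adv")),
                        t(comp), val_rmse = vm$rmse, val_ssim = vm$ssim)
      hist <- rbind(hist, row)
      if (vm$ssim > best$val_ssim)
        best <- list(val_ssim = vm$ssim, val_rmse = vm$rmse, epoch = epoch,
                     P = gen$P, S = gen$S)
      if (verbose)
        message(sprintf("epoch %3d lr %.2e d %8.4f g %8.4f val rmse %.4f ssim %.4f",
                        epoch, lr_g, row$d_loss, row$g_loss, vm$rmse, vm$ssim))
    }
  })
  # keep the best validation-SSIM checkpoint in the generator
  final_P <- gen$P; final_S <- gen$S
  if (!is.null(best$P)) { gen$P <- best$P; gen$S <- best$S }
  structure(list(generator = gen, critic = critic, config = config,
                 history = hist, best = best[c("epoch", "val_ssim", "val_rmse")],
                 final = list(P = final_P, S = final_S),
                 split = split, masks = masks, grid = g, radius = radius),
            class = "eitgan")
}

.validate <- function(gen, dataset, idx, batch) {
  rmse <- ssim <- numeric(0)
  for (s in split(idx, ceiling(seq_along(idx) / batch))) {
    x <- .batch_tensor(dataset$htv, s)
    y <- .batch_tensor(dataset$truth, s)
    p <- generator_forward(gen, x, train = FALSE)$y
    for (n in seq_along(s)) {
      rmse <- c(rmse, metric_rmse(p[, , 1, n], y[, , 1, n]))
      ssim <- c(ssim, metric_ssim(p[, , 1, n], y[, , 1, n]))
    }
  }
  list(rmse = mean(rmse), ssim = mean(ssim))
}

## ---- S3 methods -------------------------------------------------------------

#' @export
print.eitgan <- function(x, ...) {
  cat("BAM-R2UNet EIT post-processor (WGAN-GP)\n")
  cat(sprintf("  generator: base %d, t = %d, %s parameters\n",
              x$config$base_channels, x$config$t,
              format(n_parameters(x$generator), big.mark = ",")))
  cat(sprintf("  critic:    base %d, %s parameters\n", x$config$critic_base,
              format(n_parameters(x$critic), big.mark = ",")))
  cat(sprintf("  trained %d epochs; best epoch %d (val SSIM %.4f, RMSE %.4f)\n",
              nrow(x$history), x$best$epoch, x$best$val_ssim, x$best$val_rmse))
  invisible(x)
}

#' @export
summary.eitgan <- function(object, ...) {
  print(object)
  cat("\nBAM fusion weights (alpha, beta, gamma) per block:\n")
  print(round(coef(object), 3))
  cat("\nlast epochs:\n")
  print(utils::tail(object$history[, c("epoch", "lr_g", "d_loss", "g_loss",
                                       "val_rmse", "val_ssim")], 5))
  invisible(object)
}

#' @export
coef.eitgan <- function(object, ...) {
  nms <- grep("\\.abg$", names(object$generator$P), value = TRUE)
  m <- do.call(rbind, object$generator$P[nms])
  colnames(m) <- c("alpha", "beta", "gamma")
  rownames(m) <- sub(".bam.abg", "", nms, fixed = TRUE)
  m
}

#' Predict reconstructions from HTV inputs
#'
#' @param object an [eitgan()] model (best-checkpoint weights).
#' @param newdata an `eit_dataset`, an `(H, W, n)` array or a single matrix.
#' @param batch batch size for inference.
#' @param ... unused.
#' @return `(H, W, n)` array of reconstructed conductivity images.
#' @export
predict.eitgan <- function(object, newdata, batch = 16L, ...) {
  arr <- if (inherits(newdata, "eit_dataset")) newdata$htv
         else if (is.matrix(newdata)) array(newdata, c(dim(newdata), 1L))
         else newdata
  n <- dim(arr)[3]
  out <- array(0, dim(arr))
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    x <- .batch_tensor(arr, s)
    out[, , s] <- generator_forward(object$generator, x, train = FALSE)$y
  }
  out
}

#' @export
residuals.eitgan <- function(object, dataset, subset = NULL, ...) {
  idx <- subset %||% object$split$test
  pred <- predict(object, array(dataset$htv[, , idx], c(object$grid, object$grid,
                                                        length(idx))))
  pred - array(dataset$truth[, , idx], dim(pred))
}

#' @export
plot.eitgan <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  h <- x$history
  plot(h$epoch, h$g_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training losses")
  lines(h$epoch, h$d_loss, lty = 2)
  legend("topright", c("generator", "critic"), lty = 1:2, bty = "n")
  plot(h$epoch, h$val_ssim, type = "l", xlab = "epoch", ylab = "validation SSIM",
       main = "validation quality")
  invisible(x)
}
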