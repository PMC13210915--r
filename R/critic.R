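#' Create the conditional PatchGAN critic
#'
#' Five 4x4 convolutions with strides 2,2,2,2,1, channels
#' `base * c(1, 2, 4, 8)` then 1, affine-free instance normalisation on layers
#' 2--4 and LeakyReLU slope 0.2.  The input is the HTV condition image and the
#' target image concatenated on the channel axis; the output is an unbounded
#' patch score map (Wasserstein critic, no sigmoid).  Weights are initialised
#' from N(0, 0.02) as is conventional for this discriminator family.
#'
#' @param base first-layer channel count (64 in the full-size model).
#' @param seed integer seed.
#' @return an object of class `"eit_critic"`.
#' @export
critic_new <- function(base = 64L, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  net <- nn_new()
  cs <- c(base, 2L * base, 4L * base, 8L * base, 1L)
  cin <- 2L
  for (l in 1:5) {
    nn_param(net, paste0("c", l, ".w"), init_normal(c(4L, 4L, cin, cs[l])))
    if (l %in% c(1L, 5L)) nn_param(net, paste0("c", l, ".b"), numeric(cs[l]))
    cin <- cs[l]
  }
  net$strides <- c(2L, 2L, 2L, 2L, 1L)
  nn_zero_grads(net)
  class(net) <- c("eit_critic", "environment")
  net
}

#' Critic forward pass
#'
#' @param net an [critic_new()] object.
#' @param cond condition (HTV) image batch `(H, W, 1, N)`.
#' @param target target image batch, same shape.
#' @param keep_cache keep activations for the backward passes.
#' @return list with `score` (patch map `(h, w, 1, N)`) and optionally `cache`.
#' @export
critic_forward <- function(net, cond, target, keep_cache = FALSE) {
  if (is.matrix(cond)) cond <- tens4(cond)
  if (is.matrix(target)) target <- tens4(target)
  if (!identical(dim(cond), dim(target))) stop("condition/target shape mismatch")
  x <- .concat_f(cond, target)$y
  cache <- list(xdim = dim(x))
  h <- x
  for (l in 1:5) {
    cv <- conv_f(net, paste0("c", l), h, stride = net$strides[l], pad = 1L)
    lc <- list(cv = cv$cache)
    h <- cv$y
    if (l %in% 2:4) {
      no <- inorm_f(h)
      h <- no$y
      lc$no <- no$cache
    }
    if (l < 5L) {
      ac <- lrelu_f(h, 0.2)
      h <- ac$y
      lc$ac <- ac$cache
    }
    cache[[paste0("l", l)]] <- lc
  }
  cache$sdim <- dim(h)
  if (keep_cache) list(score = h, cache = cache) else list(score = h)
}

#' Critic backward pass (exact)
#'
#' Standard backpropagation of a gradient on the patch score map; accumulates
#' parameter gradients and returns the gradient with respect to the stacked
#' two-channel input.
#'
#' @param net the critic.
#' @param cache cache from `critic_forward(..., keep_cache = TRUE)`.
#' @param gscore gradient with respect to the score map.
#' @return gradient array `(H, W, 2, N)`.
#' @export
critic_backward <- function(net, cache, gscore) {
  g <- gscore
  for (l in 5:1) {
    lc <- cache[[paste0("l", l)]]
    if (!is.null(lc$ac)) g <- lrelu_b(lc$ac, g)
    if (!is.null(lc$no)) g <- inorm_b(lc$no, g)
    g <- conv_b(net, lc$cv, g)
  }
  g
}

# Input-gradient chain used by the gradient penalty: LeakyReLU masks and
# instance-norm statistics from the forward pass are treated as constants,
# which is exact a.e. for the masks and a frozen-statistics reading of the
# norm layers.  Returns the input gradient and the per-layer chain signals
# needed for the second (weight) backward pass.
.critic_gchain <- function(net, cache, u) {
  g <- u
  q <- vector("list", 5L)
  for (l in 5:1) {
    lc <- cache[[paste0("l", l)]]
    if (!is.null(lc$ac)) g <- lrelu_bwd_cpp(lc$ac$y, g, lc$ac$s)
    if (!is.null(lc$no)) {
      d <- lc$no$d
      g <- col_axpb_cpp(g, lc$no$istd, numeric(length(lc$no$istd)),
                        hw = d[1] * d[2])
    }
    q[[l]] <- g
    w <- net$P[[paste0("c", l, ".w")]]
    din <- dim(lc$cv$x)
    g <- conv2d_bwd_input_cpp(g, w, din[1], din[2], lc$cv$stride, 1L, 1L, 1L)
  }
  list(g = g, q = q)
}

# Accumulate lambda_gp * d(penalty)/d(weights) by back-propagating through the
# input-gradient chain (double backprop); returns the penalty value.
.critic_gp_accumulate <- function(net, cache, lambda_gp) {
  d <- cache$xdim
  sdim <- cache$sdim
  N <- d[4]
  # per-sample score is the patch-map mean, so seed the chain with 1/P per
  # sample; the 1/N of the batch mean enters through dpg below
  u <- array(1 / (sdim[1] * sdim[2]), sdim)
  ch <- .critic_gchain(net, cache, u)
  g <- ch$g
  # penalty on the gradient w.r.t. the interpolated target channel
  gt <- g[, , 2L, , drop = FALSE]
  nrm <- sqrt(colSums(matrix(gt, ncol = N)^2))
  pen <- mean((nrm - 1)^2)
  dpg <- matrix(gt, ncol = N)
  dpg <- sweep(dpg, 2L, 2 * (nrm - 1) / pmax(nrm, 1e-12) / N, `*`)
  r <- array(0, d)
  r[, , 2L, ] <- dpg
  # reverse sweep: same direction as the original forward pass
  for (l in 1:5) {
    lc <- cache[[paste0("l", l)]]
    w <- net$P[[paste0("c", l, ".w")]]
    gw <- conv2d_bwd_weight_cpp(r, ch$q[[l]], 4L, lc$cv$stride, 1L, 1L, 1L)
    nn_acc(net, paste0("c", l, ".w"), lambda_gp * gw)
    if (l < 5L) {
      r <- conv2d_fwd_cpp(r, w, NULL, lc$cv$stride, 1L, 1L, 1L)
      if (!is.null(lc$no)) {
        dd <- lc$no$d
        r <- col_axpb_cpp(r, lc$no$istd, numeric(length(lc$no$istd)),
                          hw = dd[1] * dd[2])
      }
      if (!is.null(lc$ac)) r <- lrelu_bwd_cpp(lc$ac$y, r, lc$ac$s)
    }
  }
  pen
}
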