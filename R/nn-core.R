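# Minimal dense-tensor neural network core.
#
# A "net" is an environment with named parameter arrays (P), matching gradient
# accumulators (G) and persistent state such as batch-norm running moments (S).
# Tensors are column-major R arrays with dim = (H, W, C, N); convolution weights
# are (K, K, Cin/groups, Cout).  Forward functions return list(y, cache); the
# matching backward consumes the cache, accumulates parameter gradients into G
# and returns the gradient with respect to the input.

nn_new <- function() {
  net <- new.env(parent = emptyenv())
  net$P <- list()
  net$G <- list()
  net$S <- list()
  net
}

nn_param <- function(net, name, value) {
  net$P[[name]] <- value
  invisible(net)
}

nn_zero_grads <- function(net) {
  net$G <- lapply(net$P, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p)))
  invisible(net)
}

nn_acc <- function(net, name, g) {
  net$G[[name]] <- net$G[[name]] + g
  invisible(net)
}

nn_n_params <- function(net) sum(vapply(net$P, length, integer(1)))

`%||%` <- function(a, b) if (is.null(a)) b else a

tens4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d[1], d[2], 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(d[1], d[2], d[3], 1L)
  x
}

## ---- convolution ------------------------------------------------------------

conv_f <- function(net, nm, x, stride = 1L, pad = 1L, dil = 1L, groups = 1L) {
  w <- net$P[[paste0(nm, ".w")]]
  b <- net$P[[paste0(nm, ".b")]]
  y <- conv2d_fwd_cpp(x, w, b, stride, pad, dil, groups)
  list(y = y, cache = list(nm = nm, x = x, stride = stride, pad = pad,
                           dil = dil, groups = groups))
}

conv_b <- function(net, cache, gy) {
  nm <- cache$nm
  w <- net$P[[paste0(nm, ".w")]]
  gw <- conv2d_bwd_weight_cpp(cache$x, gy, dim(w)[1], cache$stride, cache$pad,
                              cache$dil, cache$groups)
  nn_acc(net, paste0(nm, ".w"), gw)
  if (!is.null(net$P[[paste0(nm, ".b")]])) {
    d <- dim(gy)
    gb <- rowSums(matrix(colSums(matrix(gy, nrow = d[1] * d[2])), d[3], d[4]))
    nn_acc(net, paste0(nm, ".b"), gb)
  }
  d <- dim(cache$x)
  conv2d_bwd_input_cpp(gy, w, d[1], d[2], cache$stride, cache$pad,
                       cache$dil, cache$groups)
}

# Transposed 2x2 stride-2 convolution (upsampling).  Weight (2, 2, Cout, Cin):
# stored as the weight of the adjoint (downsampling) convolution.
convt_f <- function(net, nm, x) {
  w <- net$P[[paste0(nm, ".w")]]
  d <- dim(x)
  y <- conv2d_bwd_input_cpp(x, w, 2L * d[1], 2L * d[2], 2L, 0L, 1L, 1L)
  b <- net$P[[paste0(nm, ".b")]]
  if (!is.null(b)) {
    dy <- dim(y)
    y <- y + rep(rep(b, each = dy[1] * dy[2]), dy[4])
  }
  list(y = y, cache = list(nm = nm, x = x))
}

convt_b <- function(net, cache, gy) {
  nm <- cache$nm
  w <- net$P[[paste0(nm, ".w")]]
  # y = adjoint-conv of x by w, so:  gx = conv(gy, w);  gw = bwd_weight(gy, x).
  gw <- conv2d_bwd_weight_cpp(gy, cache$x, 2L, 2L, 0L, 1L, 1L)
  nn_acc(net, paste0(nm, ".w"), gw)
  if (!is.null(net$P[[paste0(nm, ".b")]])) {
    d <- dim(gy)
    gb <- rowSums(matrix(colSums(matrix(gy, nrow = d[1] * d[2])), d[3], d[4]))
    nn_acc(net, paste0(nm, ".b"), gb)
  }
  conv2d_fwd_cpp(gy, w, NULL, 2L, 0L, 1L, 1L)
}

## ---- normalisation ----------------------------------------------------------

# per-channel sums over (H,W,N) from per-column (c,n) sums
.chan_from_cols <- function(colsums, C, N) rowSums(matrix(colsums, C, N))

bn_f <- function(net, nm, x, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  g <- net$P[[paste0(nm, ".g")]]
  b <- net$P[[paste0(nm, ".b")]]
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- hw * N
  if (train) {
    ss <- col_sums2_cpp(x, NULL, hw)
    mu <- .chan_from_cols(ss[1, ], C, N) / M
    v2 <- pmax(.chan_from_cols(ss[2, ], C, N) / M - mu^2, 0)
    key_m <- paste0(nm, ".rm"); key_v <- paste0(nm, ".rv")
    net$S[[key_m]] <- (1 - momentum) * (net$S[[key_m]] %||% 0) + momentum * mu
    net$S[[key_v]] <- (1 - momentum) * (net$S[[key_v]] %||% 1) + momentum * v2
  } else {
    mu <- rep_len(net$S[[paste0(nm, ".rm")]] %||% 0, C)
    v2 <- rep_len(net$S[[paste0(nm, ".rv")]] %||% 1, C)
  }
  istd <- 1 / sqrt(v2 + eps)
  xhat <- col_axpb_cpp(x, rep(istd, N), rep(-mu * istd, N), hw = hw)
  y <- col_axpb_cpp(xhat, rep(g, N), rep(b, N), hw = hw)
  list(y = y, cache = list(nm = nm, xhat = xhat, istd = istd, d = d,
                           train = train))
}

bn_b <- function(net, cache, gy) {
  nm <- cache$nm; d <- cache$d
  g <- net$P[[paste0(nm, ".g")]]
  xhat <- cache$xhat
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  ss <- col_sums2_cpp(gy, xhat, hw)
  nn_acc(net, paste0(nm, ".g"), .chan_from_cols(ss[2, ], C, N))
  nn_acc(net, paste0(nm, ".b"), .chan_from_cols(ss[1, ], C, N))
  gxh <- col_axpb_cpp(gy, rep(g, N), numeric(C * N), hw = hw)
  if (cache$train) {
    M <- hw * N
    sh <- col_sums2_cpp(gxh, xhat, hw)
    s1 <- .chan_from_cols(sh[1, ], C, N) / M
    s2 <- .chan_from_cols(sh[2, ], C, N) / M
    bn_bwd_fuse_cpp(gxh, xhat, rep(cache$istd, N), rep(s1, N), rep(s2, N),
                    hw = hw)
  } else {
    col_axpb_cpp(gxh, rep(cache$istd, N), numeric(C * N), hw = hw)
  }
}

# Affine-free instance normalisation (per sample, per channel).
inorm_f <- function(x, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  ss <- col_sums2_cpp(x, NULL, hw)
  mu <- ss[1, ] / hw
  v2 <- pmax(ss[2, ] / hw - mu^2, 0)
  istd <- 1 / sqrt(v2 + eps)
  xhat <- col_axpb_cpp(x, istd, -mu * istd, hw = hw)
  list(y = xhat, cache = list(xhat = xhat, istd = istd, d = d))
}

inorm_b <- function(cache, gy) {
  d <- cache$d; hw <- d[1] * d[2]
  ss <- col_sums2_cpp(gy, cache$xhat, hw)
  bn_bwd_fuse_cpp(gy, cache$xhat, cache$istd, ss[1, ] / hw, ss[2, ] / hw,
                  hw = hw)
}

## ---- activations ------------------------------------------------------------

lrelu_f <- function(x, slope = 0.2) {
  y <- lrelu_y_cpp(x, slope)
  list(y = y, cache = list(y = y, s = slope))
}
lrelu_b <- function(cache, gy) lrelu_bwd_cpp(cache$y, gy, cache$s)

relu_f <- function(x) lrelu_f(x, 0)
relu_b <- lrelu_b

sigm <- function(x) 1 / (1 + exp(-x))

## ---- dense / pooling --------------------------------------------------------

# x: (Cin, N) matrix
linear_f <- function(net, nm, x) {
  w <- net$P[[paste0(nm, ".w")]]
  b <- net$P[[paste0(nm, ".b")]]
  list(y = w %*% x + b, cache = list(nm = nm, x = x))
}

linear_b <- function(net, cache, gy) {
  nm <- cache$nm
  nn_acc(net, paste0(nm, ".w"), gy %*% t(cache$x))
  nn_acc(net, paste0(nm, ".b"), rowSums(gy))
  t(net$P[[paste0(nm, ".w")]]) %*% gy
}

gap_f <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- matrix(col_sums2_cpp(x, NULL, hw)[1, ] / hw, d[3], d[4])
  list(y = y, cache = d)
}

gap_b <- function(cache, gy) {
  d <- cache
  gx <- rep(as.vector(gy), each = d[1] * d[2]) / (d[1] * d[2])
  dim(gx) <- d
  gx
}

pool_f <- function(x) {
  r <- maxpool2_fwd_cpp(x)
  list(y = r$y, cache = list(argmax = r$argmax, H = dim(x)[1], W = dim(x)[2]))
}
pool_b <- function(cache, gy) maxpool2_bwd_cpp(gy, cache$argmax, cache$H, cache$W)

## ---- initialisers -----------------------------------------------------------

# Kaiming (He) normal for LeakyReLU fan-in
init_kaiming <- function(dimw, slope = 0.2) {
  # conv weight (K, K, Cin/g, Cout): fan_in = K*K*Cin/g; dense (Cout, Cin): Cin
  fan_in <- if (length(dimw) == 2L) dimw[2] else prod(dimw[-length(dimw)])
  array(rnorm(prod(dimw), 0, sqrt(2 / ((1 + slope^2) * fan_in))), dim = dimw)
}

init_normal <- function(dimw, sd = 0.02) array(rnorm(prod(dimw), 0, sd), dim = dimw)

laplacian_kernel <- function() matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
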