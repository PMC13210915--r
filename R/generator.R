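#' Generator architecture configuration
#'
#' Describes the boundary-attention recurrent-residual U-Net generator: a
#' symmetric encoder--bottleneck--decoder where every stage projects channels
#' with a 1x1 convolution and stacks RecurrentBlock-BAM blocks.  Each
#' RecurrentBlock applies its first 3x3 convolution `t` times with re-injection
#' of the block input, a second 3x3 convolution once, the boundary attention
#' module (BAM), and a 1x1-projected residual connection.  BAM fuses a spatial
#' attention map, a channel attention vector and a learnable Laplacian edge map
#' with trainable scalar weights initialised at 0.5/0.3/0.2.
#'
#' @param base_channels first-stage channel count; stages use
#'   `base_channels * c(1, 2, 4, 8)` and the bottleneck 16x.
#' @param t recurrence count of the first convolution in each block.
#' @param bottleneck_blocks number of RecurrentBlock-BAM blocks in the
#'   bottleneck.  The default 1 matches the reported ~12.6 M trainable
#'   parameters of the full-size generator.
#' @param dropout dropout probability applied after the bottleneck.
#' @param reduction channel reduction factor inside both BAM attention branches.
#' @param spatial,channel,edge logical switches for the three BAM branches
#'   (all `FALSE` gives the plain recurrent-residual backbone without BAM).
#' @param classic_r2u if `TRUE`, the second convolution of each block is also
#'   applied recurrently (the classical R2U variant); the default applies the
#'   recurrence to the first convolution only.
#' @return a list of class `"gen_config"`.
#' @export
generator_config <- function(base_channels = 32L, t = 2L, bottleneck_blocks = 1L,
                             dropout = 0.1, reduction = 8L,
                             spatial = TRUE, channel = TRUE, edge = TRUE,
                             classic_r2u = FALSE) {
  stopifnot(t >= 1L, base_channels >= 1L, bottleneck_blocks >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(base = as.integer(base_channels), t = as.integer(t),
                 nbott = as.integer(bottleneck_blocks), dropout = dropout,
                 red = as.integer(reduction),
                 branches = c(spatial = spatial, channel = channel, edge = edge),
                 classic_r2u = classic_r2u, slope = 0.2),
            class = "gen_config")
}

.reg_conv <- function(net, nm, K, cin, cout, groups = 1L, bias = FALSE,
                      init = c("kaiming", "zero")) {
  init <- match.arg(init)
  dimw <- c(K, K, cin %/% groups, cout)
  w <- if (init == "kaiming") init_kaiming(dimw) else array(0, dimw)
  nn_param(net, paste0(nm, ".w"), w)
  if (bias) nn_param(net, paste0(nm, ".b"), numeric(cout))
  invisible(net)
}

.reg_bn <- function(net, nm, c) {
  nn_param(net, paste0(nm, ".g"), rep(1, c))
  nn_param(net, paste0(nm, ".b"), numeric(c))
  invisible(net)
}

.rrb_register <- function(net, p, c, cfg) {
  .reg_conv(net, paste0(p, ".conv1"), 3L, c, c)
  .reg_bn(net, paste0(p, ".bn1"), c)
  .reg_conv(net, paste0(p, ".conv2"), 3L, c, c)
  .reg_bn(net, paste0(p, ".bn2"), c)
  br <- cfg$branches
  if (any(br)) {
    cr <- max(1L, c %/% cfg$red)
    if (br[["spatial"]]) {
      .reg_conv(net, paste0(p, ".bam.s1"), 1L, c, cr)
      .reg_bn(net, paste0(p, ".bam.sbn1"), cr)
      .reg_conv(net, paste0(p, ".bam.sdw"), 3L, cr, cr, groups = cr)
      .reg_bn(net, paste0(p, ".bam.sbn2"), cr)
      .reg_conv(net, paste0(p, ".bam.sdil"), 3L, cr, cr)
      .reg_bn(net, paste0(p, ".bam.sbn3"), cr)
      .reg_conv(net, paste0(p, ".bam.sout"), 1L, cr, 1L, bias = TRUE)
    }
    if (br[["channel"]]) {
      cr2 <- max(1L, c %/% cfg$red)
      nn_param(net, paste0(p, ".bam.fc1.w"), init_kaiming(c(cr2, c)))
      nn_param(net, paste0(p, ".bam.fc1.b"), numeric(cr2))
      nn_param(net, paste0(p, ".bam.fc2.w"), init_kaiming(c(c, cr2)))
      nn_param(net, paste0(p, ".bam.fc2.b"), numeric(c))
    }
    if (br[["edge"]]) {
      lap <- laplacian_kernel()
      nn_param(net, paste0(p, ".bam.edge.w"),
               array(rep(lap, c), dim = c(3, 3, 1, c)))
    }
    nn_param(net, paste0(p, ".bam.abg"), c(0.5, 0.3, 0.2))
    .reg_bn(net, paste0(p, ".bam.bn"), c)
  }
  .reg_conv(net, paste0(p, ".res"), 1L, c, c, bias = TRUE)
  invisible(net)
}

#' Create a BAM-R2UNet generator
#'
#' Builds the parameter set of the generator.  Convolution and dense weights
#' use Kaiming (He) initialisation for the LeakyReLU slope 0.2; the edge-branch
#' kernels start at the discrete Laplacian; BAM fusion weights start at
#' 0.5/0.3/0.2.
#'
#' @param config a [generator_config()].
#' @param seed integer seed making the initialisation reproducible.
#' @return an object of class `"eit_generator"`.
#' @export
generator_new <- function(config = generator_config(), seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  net <- nn_new()
  net$cfg <- config
  b <- config$base
  cs <- b * c(1L, 2L, 4L, 8L)
  cin <- 1L
  for (i in 1:4) {
    p <- paste0("enc", i)
    .reg_conv(net, paste0(p, ".proj"), 1L, cin, cs[i], bias = TRUE)
    .rrb_register(net, paste0(p, ".rrb1"), cs[i], config)
    .rrb_register(net, paste0(p, ".rrb2"), cs[i], config)
    cin <- cs[i]
  }
  cb <- b * 16L
  .reg_conv(net, "bott.proj", 1L, cs[4], cb, bias = TRUE)
  for (j in seq_len(config$nbott))
    .rrb_register(net, paste0("bott.rrb", j), cb, config)
  cup <- cb
  for (i in 4:1) {
    p <- paste0("dec", i)
    # transposed conv weight stored as the adjoint convolution's (2,2,Cout,Cin)
    nn_param(net, paste0(p, ".up.w"), init_kaiming(c(2L, 2L, cs[i], cup)))
    nn_param(net, paste0(p, ".up.b"), numeric(cs[i]))
    .reg_conv(net, paste0(p, ".proj"), 1L, 2L * cs[i], cs[i], bias = TRUE)
    .rrb_register(net, paste0(p, ".rrb1"), cs[i], config)
    .rrb_register(net, paste0(p, ".rrb2"), cs[i], config)
    cup <- cs[i]
  }
  .reg_conv(net, "head.conv3", 3L, b, b)
  .reg_bn(net, "head.bn", b)
  .reg_conv(net, "head.out", 1L, b, 1L, bias = TRUE)
  nn_zero_grads(net)
  class(net) <- c("eit_generator", "environment")
  net
}

## ---- RecurrentBlock-BAM forward/backward ------------------------------------

.red_hw <- function(g) {
  d <- dim(g)
  array(red_hw_cpp(g, d[1] * d[2], d[3], d[4]), c(d[1], d[2], 1L, d[4]))
}

.red_ch <- function(g) {
  d <- dim(g)
  matrix(col_sums2_cpp(g, NULL, d[1] * d[2])[1, ], d[3], d[4])
}

# alpha * z * ms1p * mc + beta * z with ms1p broadcast over channels and mc
# over space; NULL branch maps are treated as 1
.fuse3 <- function(z, ms1p, mc, alpha, beta, d) {
  bam_fuse_cpp(z, if (is.null(ms1p)) numeric(0) else ms1p,
               if (is.null(mc)) numeric(0) else mc,
               alpha, beta, d[1] * d[2], d[3], d[4],
               !is.null(ms1p), !is.null(mc))
}

.bam_f <- function(net, p, z, train, cfg) {
  br <- cfg$branches
  d <- dim(z)
  cache <- list(p = p, d = d, z = z)
  if (!any(br)) { cache$off <- TRUE; return(list(y = z, cache = cache)) }
  abg <- net$P[[paste0(p, ".abg")]]
  if (br[["spatial"]]) {
    c1 <- conv_f(net, paste0(p, ".s1"), z, pad = 0L)
    b1 <- bn_f(net, paste0(p, ".sbn1"), c1$y, train)
    r1 <- relu_f(b1$y)
    cr <- dim(r1$y)[3]
    c2 <- conv_f(net, paste0(p, ".sdw"), r1$y, pad = 1L, groups = cr)
    b2 <- bn_f(net, paste0(p, ".sbn2"), c2$y, train)
    r2 <- relu_f(b2$y)
    c3 <- conv_f(net, paste0(p, ".sdil"), r2$y, pad = 2L, dil = 2L)
    b3 <- bn_f(net, paste0(p, ".sbn3"), c3$y, train)
    r3 <- relu_f(b3$y)
    c4 <- conv_f(net, paste0(p, ".sout"), r3$y, pad = 0L)
    Ms <- sigm(c4$y)
    cache$sp <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                     c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                     c3 = c3$cache, b3 = b3$cache, r3 = r3$cache,
                     c4 = c4$cache, Ms = Ms)
  } else Ms <- NULL
  if (br[["channel"]]) {
    gp <- gap_f(z)
    f1 <- linear_f(net, paste0(p, ".fc1"), gp$y)
    a1 <- relu_f(f1$y)
    f2 <- linear_f(net, paste0(p, ".fc2"), a1$y)
    Mc <- sigm(f2$y)
    cache$ch <- list(gp = gp$cache, f1 = f1$cache, a1 = a1$cache,
                     f2 = f2$cache, Mc = Mc)
  } else Mc <- NULL
  if (br[["edge"]]) {
    ce <- conv_f(net, paste0(p, ".edge"), z, pad = 1L, groups = d[3])
    a <- abs(ce$y)
    hw <- d[1] * d[2]
    thr <- col_sums2_cpp(a, NULL, hw)[1, ] / hw
    Me <- sigm(col_axpb_cpp(a, rep(1, d[3] * d[4]), -thr, hw = hw))
    cache$ed <- list(ce = ce$cache, sgn = sign(ce$y), Me = Me)
  } else Me <- NULL
  ms1p <- if (is.null(Ms)) NULL else as.vector(1 + Ms)
  T1 <- .fuse3(z, ms1p, Mc, 1, 0, d)
  fuse <- abg[1] * T1 + abg[2] * z
  if (!is.null(Me)) fuse <- fuse + abg[3] * Me * z
  bnf <- bn_f(net, paste0(p, ".bn"), fuse, train)
  cache$T1 <- T1; cache$ms1p <- ms1p; cache$Mc <- Mc
  cache$bnf <- bnf$cache
  list(y = bnf$y, cache = cache)
}

.bam_b <- function(net, cache, gy) {
  if (isTRUE(cache$off)) return(gy)
  p <- cache$p; d <- cache$d; z <- cache$z
  abg <- net$P[[paste0(p, ".abg")]]
  gf <- bn_b(net, cache$bnf, gy)
  Me <- if (!is.null(cache$ed)) cache$ed$Me else NULL
  gabg <- c(sum(gf * cache$T1), sum(gf * z),
            if (!is.null(Me)) sum(gf * Me * z) else 0)
  nn_acc(net, paste0(p, ".abg"), gabg)
  gz <- .fuse3(gf, cache$ms1p, cache$Mc, abg[1], abg[2], d)
  if (!is.null(Me)) gz <- gz + abg[3] * gf * Me
  gfz <- if (!is.null(cache$sp) || !is.null(cache$ch)) gf * z else NULL
  # spatial branch
  if (!is.null(cache$sp)) {
    sp <- cache$sp
    gMs <- .red_hw(.fuse3(gfz, NULL, cache$Mc, abg[1], 0, d))
    gc4 <- gMs * sp$Ms * (1 - sp$Ms)
    g3 <- conv_b(net, sp$c4, gc4)
    g3 <- relu_b(sp$r3, g3)
    g3 <- bn_b(net, sp$b3, g3)
    g2 <- conv_b(net, sp$c3, g3)
    g2 <- relu_b(sp$r2, g2)
    g2 <- bn_b(net, sp$b2, g2)
    g1 <- conv_b(net, sp$c2, g2)
    g1 <- relu_b(sp$r1, g1)
    g1 <- bn_b(net, sp$b1, g1)
    gz <- gz + conv_b(net, sp$c1, g1)
  }
  # channel branch
  if (!is.null(cache$ch)) {
    ch <- cache$ch
    gMc <- .red_ch(.fuse3(gfz, cache$ms1p, NULL, abg[1], 0, d))
    gf2 <- gMc * ch$Mc * (1 - ch$Mc)
    ga1 <- linear_b(net, ch$f2, gf2)
    ga1 <- relu_b(ch$a1, ga1)
    ggp <- linear_b(net, ch$f1, ga1)
    gz <- gz + gap_b(ch$gp, ggp)
  }
  # edge branch
  if (!is.null(cache$ed)) {
    ed <- cache$ed
    gMe <- abg[3] * gf * z
    gA <- gMe * Me * (1 - Me)
    hw <- d[1] * d[2]
    mA <- col_sums2_cpp(gA, NULL, hw)[1, ] / hw
    ga <- col_axpb_cpp(gA, rep(1, d[3] * d[4]), -mA, hw = hw)
    ge <- ga * ed$sgn
    gz <- gz + conv_b(net, ed$ce, ge)
  }
  gz
}

.rrb_f <- function(net, p, x, train) {
  cfg <- net$cfg
  tloop <- cfg$t
  app <- function(nm_conv, nm_bn, inp) {
    cv <- conv_f(net, nm_conv, inp)
    bn <- bn_f(net, nm_bn, cv$y, train)
    ac <- lrelu_f(bn$y, cfg$slope)
    list(y = ac$y, cache = list(cv = cv$cache, bn = bn$cache, ac = ac$cache))
  }
  c1 <- paste0(p, ".conv1"); n1 <- paste0(p, ".bn1")
  steps <- vector("list", tloop)
  h <- NULL
  for (i in seq_len(tloop)) {
    inp <- if (i == 1L) x else h + x
    a <- app(c1, n1, inp)
    steps[[i]] <- a$cache
    h <- a$y
  }
  c2 <- paste0(p, ".conv2"); n2 <- paste0(p, ".bn2")
  if (isTRUE(cfg$classic_r2u)) {
    steps2 <- vector("list", tloop)
    z <- NULL
    for (i in seq_len(tloop)) {
      inp <- if (i == 1L) h else z + h
      a <- app(c2, n2, inp)
      steps2[[i]] <- a$cache
      z <- a$y
    }
  } else {
    a2 <- app(c2, n2, h)
    steps2 <- list(a2$cache)
    z <- a2$y
  }
  bam <- .bam_f(net, paste0(p, ".bam"), z, train, cfg)
  rs <- conv_f(net, paste0(p, ".res"), x, pad = 0L)
  outa <- lrelu_f(bam$y + rs$y, cfg$slope)
  list(y = outa$y,
       cache = list(p = p, steps = steps, steps2 = steps2, bam = bam$cache,
                    rs = rs$cache, outa = outa$cache))
}

.rrb_b <- function(net, cache, gy) {
  cfg <- net$cfg
  app_b <- function(cc, g) {
    g <- lrelu_b(cc$ac, g)
    g <- bn_b(net, cc$bn, g)
    conv_b(net, cc$cv, g)
  }
  # backward through h_1 = A(xin); h_i = A(h_{i-1} + xin): every iteration's
  # input gradient flows both to the previous h and to the re-injected xin.
  rec_b <- function(caches, g_top) {
    gxin <- 0; gh <- g_top
    for (i in length(caches):1) {
      gi <- app_b(caches[[i]], gh)
      gxin <- gxin + gi
      gh <- gi
    }
    gxin
  }
  g <- lrelu_b(cache$outa, gy)
  gx <- conv_b(net, cache$rs, g)      # residual path
  gz <- .bam_b(net, cache$bam, g)
  ght <- if (length(cache$steps2) > 1L) rec_b(cache$steps2, gz)
         else app_b(cache$steps2[[1]], gz)
  gx + rec_b(cache$steps, ght)
}

.concat_f <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  list(y = y, c1 = da[3], c2 = db[3])
}

#' Generator forward pass
#'
#' Maps HTV pre-reconstructed conductivity images to restored conductivity
#' images in `[0, 2]`.  The spatial size must be a multiple of 16 (the four
#' pooling stages); internal feature-map sizes adapt to the input resolution.
#'
#' @param net an [generator_new()] object.
#' @param x input array `(H, W, 1, N)` (a single `(H, W)` matrix is promoted).
#' @param train logical; use batch statistics and dropout when `TRUE`.
#' @param keep_cache keep the activation cache needed for [generator_backward()].
#' @return list with `y` (same shape as `x`, values in `[0, 2]`) and, when
#'   requested, `cache`.
#' @export
generator_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  if (is.matrix(x)) x <- tens4(x)
  d <- dim(x)
  if (length(d) != 4L || d[3] != 1L)
    stop("generator input must be (H, W, 1, N)")
  if (d[1] != d[2]) stop("generator input must be square")
  if (d[1] %% 16L != 0L) stop("input size must be a multiple of 16")
  cfg <- net$cfg
  cache <- list()
  skips <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    p <- paste0("enc", i)
    pr <- conv_f(net, paste0(p, ".proj"), h, pad = 0L)
    r1 <- .rrb_f(net, paste0(p, ".rrb1"), pr$y, train)
    r2 <- .rrb_f(net, paste0(p, ".rrb2"), r1$y, train)
    pl <- pool_f(r2$y)
    skips[[i]] <- r2$y
    cache[[p]] <- list(pr = pr$cache, r1 = r1$cache, r2 = r2$cache, pl = pl$cache)
    h <- pl$y
  }
  pr <- conv_f(net, "bott.proj", h, pad = 0L)
  h <- pr$y
  bott <- list(pr = pr$cache, rrb = list())
  for (j in seq_len(cfg$nbott)) {
    rb <- .rrb_f(net, paste0("bott.rrb", j), h, train)
    bott$rrb[[j]] <- rb$cache
    h <- rb$y
  }
  if (train && cfg$dropout > 0) {
    keep <- (array(runif(length(h)), dim(h)) >= cfg$dropout) / (1 - cfg$dropout)
    h <- h * keep
    bott$drop <- keep
  }
  cache$bott <- bott
  for (i in 4:1) {
    p <- paste0("dec", i)
    up <- convt_f(net, paste0(p, ".up"), h)
    cc <- .concat_f(up$y, skips[[i]])
    pr <- conv_f(net, paste0(p, ".proj"), cc$y, pad = 0L)
    r1 <- .rrb_f(net, paste0(p, ".rrb1"), pr$y, train)
    r2 <- .rrb_f(net, paste0(p, ".rrb2"), r1$y, train)
    cache[[p]] <- list(up = up$cache, cc = cc, pr = pr$cache,
                       r1 = r1$cache, r2 = r2$cache)
    h <- r2$y
  }
  hc <- conv_f(net, "head.conv3", h)
  hb <- bn_f(net, "head.bn", hc$y, train)
  ha <- lrelu_f(hb$y, cfg$slope)
  ho <- conv_f(net, "head.out", ha$y, pad = 0L)
  s <- sigm(ho$y)
  y <- 2 * s
  cache$head <- list(hc = hc$cache, hb = hb$cache, ha = ha$cache,
                     ho = ho$cache, s = s)
  if (keep_cache) list(y = y, cache = cache) else list(y = y)
}

#' Generator backward pass
#'
#' Accumulates parameter gradients for a loss gradient `gy` with respect to the
#' generator output, and returns the gradient with respect to the input.
#'
#' @param net the generator.
#' @param cache cache from `generator_forward(..., keep_cache = TRUE)`.
#' @param gy gradient array shaped like the output.
#' @return gradient with respect to the input image batch.
#' @export
generator_backward <- function(net, cache, gy) {
  hd <- cache$head
  gho <- 2 * hd$s * (1 - hd$s) * gy
  g <- conv_b(net, hd$ho, gho)
  g <- lrelu_b(hd$ha, g)
  g <- bn_b(net, hd$hb, g)
  g <- conv_b(net, hd$hc, g)
  gskip <- vector("list", 4L)
  for (i in 1:4) {
    p <- paste0("dec", i)
    cc <- cache[[p]]
    g <- .rrb_b(net, cc$r2, g)
    g <- .rrb_b(net, cc$r1, g)
    g <- conv_b(net, cc$pr, g)
    c1 <- cc$cc$c1
    gup <- g[, , seq_len(c1), , drop = FALSE]
    gskip[[i]] <- g[, , c1 + seq_len(cc$cc$c2), , drop = FALSE]
    g <- convt_b(net, cc$up, gup)
  }
  bott <- cache$bott
  if (!is.null(bott$drop)) g <- g * bott$drop
  for (j in length(bott$rrb):1) g <- .rrb_b(net, bott$rrb[[j]], g)
  g <- conv_b(net, bott$pr, g)
  for (i in 4:1) {
    p <- paste0("enc", i)
    cc <- cache[[p]]
    g <- pool_b(cc$pl, g)
    g <- g + gskip[[i]]
    g <- .rrb_b(net, cc$r2, g)
    g <- .rrb_b(net, cc$r1, g)
    g <- conv_b(net, cc$pr, g)
  }
  g
}

#' Number of trainable parameters
#' @param net a generator or critic object.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) nn_n_params(net)

#' Multiply--accumulate count of one generator forward pass
#'
#' Analytic count of convolution/dense MACs for a single image at the given
#' resolution (activation and normalisation costs excluded).
#'
#' @param config a [generator_config()].
#' @param size input resolution (multiple of 16).
#' @return numeric MAC count.
#' @export
generator_macs <- function(config = generator_config(), size = 64L) {
  b <- config$base
  cs <- b * c(1L, 2L, 4L, 8L)
  br <- config$branches
  conv_m <- function(K, cin, cout, hw, groups = 1L) K * K * (cin / groups) * cout * hw
  rrb_m <- function(c, hw) {
    m <- config$t * conv_m(3, c, c, hw) + conv_m(3, c, c, hw) * (if (config$classic_r2u) config$t else 1)
    if (any(br)) {
      cr <- max(1, c %/% config$red)
      if (br[["spatial"]])
        m <- m + conv_m(1, c, cr, hw) + conv_m(3, cr, cr, hw, cr) +
          conv_m(3, cr, cr, hw) + conv_m(1, cr, 1, hw)
      if (br[["channel"]]) m <- m + 2 * c * cr
      if (br[["edge"]]) m <- m + conv_m(3, c, c, hw, c)
    }
    m + conv_m(1, c, c, hw)
  }
  total <- 0
  hw <- size^2
  cin <- 1L
  for (i in 1:4) {
    total <- total + conv_m(1, cin, cs[i], hw) + 2 * rrb_m(cs[i], hw)
    cin <- cs[i]
    hw <- hw / 4
  }
  cb <- 16L * b
  total <- total + conv_m(1, cs[4], cb, hw) + config$nbott * rrb_m(cb, hw)
  cup <- cb
  for (i in 4:1) {
    hw <- hw * 4
    total <- total + conv_m(2, cup, cs[i], hw) / 4 +   # transposed conv
      conv_m(1, 2 * cs[i], cs[i], hw) + 2 * rrb_m(cs[i], hw)
    cup <- cs[i]
  }
  total + conv_m(3, b, b, size^2) + conv_m(1, b, 1, size^2)
}
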