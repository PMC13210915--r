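# Parametric leg cross-section conductivity phantoms on a 64x64 grid.
#
# Anatomy, outermost to innermost: skin ring (1-3 px), subcutaneous fat ring
# (5-10 px), muscle bulk; inside the muscle an eccentric tibia (cortical shell
# + cancellous core), a lateral fibula (cortical), vessels and nerve bundles,
# and 0-3 pathological anomalies (edema / tumor / hematoma / foreign body).
# Conductivities are drawn per structure from 1 kHz literature ranges, all
# within [0, 2] S/m.  Outside the leg disc the medium is the homogeneous
# reference (1 S/m) that the linearized forward model is built around.

#' Tissue label codes
#' @return named integer vector mapping tissue names to label ids.
#' @export
tissue_labels <- function() {
  c(background = 0L, skin = 1L, fat = 2L, muscle = 3L,
    tibia_cortical = 4L, tibia_cancellous = 5L, fibula_cortical = 6L,
    vessel = 7L, nerve = 8L, edema = 9L, tumor = 10L, hematoma = 11L,
    foreign_body = 12L)
}

#' Default tissue specification
#'
#' Conductivity ranges (S/m, at 1 kHz) and geometry parameter ranges (pixels
#' on the 64x64 grid, or fractions of the leg radius R) for every tissue
#' class.  All ranges must lie in `[0, 2]` S/m.
#'
#' @param anomaly_prob probability that each drawn anomaly is kept
#'   (0 disables anomalies entirely).
#' @return a list of class `"tissue_config"`.
#' @export
tissue_config <- function(anomaly_prob = 1) {
  stopifnot(anomaly_prob >= 0, anomaly_prob <= 1)
  structure(list(
    conductivity = list(
      skin = c(0.30, 0.60), fat = c(0.30, 0.55), muscle = c(0.80, 1.20),
      tibia_cortical = c(0.05, 0.15), tibia_cancellous = c(0.10, 0.25),
      fibula_cortical = c(0.05, 0.15), vessel = c(1.20, 1.60),
      nerve = c(0.08, 0.20), edema = c(0.75, 0.85), tumor = c(0.25, 0.35),
      hematoma = c(0.10, 0.20), foreign_body = c(0.005, 0.02)),
    geometry = list(
      skin_thickness = c(1, 3), fat_thickness = c(5, 10),
      tibia_offset = c(0.15, 0.35),        # fraction of R
      tibia_radius = c(5, 8), tibia_cortical_thickness = c(1.5, 2.5),
      fibula_offset = c(0.55, 0.75),       # fraction of R
      fibula_radius = c(2.5, 4),
      vessel_radius = c(1, 3), nerve_radius = c(1, 3),
      n_vessels = c(1L, 3L), n_nerves = c(1L, 2L),
      anomaly_radius = c(2, 6), max_anomalies = 3L),
    anomaly_prob = anomaly_prob,
    background = 1.0), class = "tissue_config")
}

.validate_tissue_config <- function(config) {
  for (nm in names(config$conductivity)) {
    r <- config$conductivity[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < 0 || r[2] > 2)
      stop("conductivity range for '", nm, "' must lie within [0, 2] S/m")
  }
  invisible(config)
}

.with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.runifr <- function(r) runif(1, r[1], r[2])

.disc <- function(grid) {
  cx <- (grid + 1) / 2
  ix <- matrix(rep(seq_len(grid), grid), grid, grid)
  jx <- t(ix)
  sqrt((ix - cx)^2 + (jx - cx)^2)
}

#' Generate one leg cross-section phantom
#'
#' Deterministic given `seed` and `config`: the same pair always reproduces a
#' bit-identical phantom.
#'
#' @param seed non-negative integer seed.
#' @param config a [tissue_config()].
#' @param grid image size in pixels (square).
#' @param radius leg disc radius in pixels.
#' @return object of class `"eit_phantom"` with elements `conductivity`
#'   (grid x grid, S/m), `labels` (integer tissue ids), `mask` (in-disc
#'   logical), `anomalies` (metadata list), `skin_thickness`,
#'   `fat_thickness`, `seed`.
#' @export
generate_phantom <- function(seed, config = tissue_config(), grid = 64L,
                             radius = 30) {
  stopifnot(seed >= 0)
  .validate_tissue_config(config)
  .with_seed(seed, {
    R <- radius
    lab <- tissue_labels()
    cx <- (grid + 1) / 2
    d <- .disc(grid)
    mask <- d <= R
    labels <- matrix(0L, grid, grid)
    sigma <- matrix(config$background, grid, grid)
    cr <- config$conductivity
    ge <- config$geometry

    ts <- .runifr(ge$skin_thickness)
    tf <- .runifr(ge$fat_thickness)
    rmus <- R - ts - tf
    vals <- vapply(cr, .runifr, numeric(1))

    paint <- function(region, tissue) {
      labels[region] <<- lab[[tissue]]
      sigma[region] <<- vals[[tissue]]
    }
    paint(mask & d > R - ts, "skin")
    paint(d <= R - ts & d > rmus, "fat")
    paint(d <= rmus, "muscle")

    circle <- function(c0, r0) (col(d) - c0[1])^2 + (row(d) - c0[2])^2 <= r0^2

    # tibia: eccentric cortical shell with cancellous core
    phi <- runif(1, 0, 2 * pi)
    rt <- .runifr(ge$tibia_radius)
    off <- .runifr(ge$tibia_offset) * R
    off <- min(off, rmus - rt - 1)
    tib_c <- cx + off * c(cos(phi), sin(phi))
    ct <- .runifr(ge$tibia_cortical_thickness)
    paint(circle(tib_c, rt) & labels == lab[["muscle"]], "tibia_cortical")
    paint(circle(tib_c, rt - ct) & labels == lab[["tibia_cortical"]],
          "tibia_cancellous")

    # fibula: lateral cortical rod
    rf <- .runifr(ge$fibula_radius)
    phif <- phi + sample(c(-1, 1), 1) * runif(1, 0.6, 1.2)
    offf <- min(.runifr(ge$fibula_offset) * R, rmus - rf - 1)
    fib_c <- cx + offf * c(cos(phif), sin(phif))
    paint(circle(fib_c, rf) & labels == lab[["muscle"]], "fibula_cortical")

    muscle_centers <- which(labels == lab[["muscle"]] & d <= rmus - 2,
                            arr.ind = TRUE)
    place <- function(rad, tissue, value = NULL) {
      for (try in 1:50) {
        k <- muscle_centers[sample(nrow(muscle_centers), 1), ]
        ctr <- c(k[2], k[1])                     # (x=col, y=row)
        if (labels[k[1], k[2]] != lab[["muscle"]]) next
        reg <- circle(ctr, rad) & labels == lab[["muscle"]]
        if (!reg[k[1], k[2]]) next
        labels[reg] <<- lab[[tissue]]
        sigma[reg] <<- if (is.null(value)) vals[[tissue]] else value
        return(list(center = ctr, radius = rad))
      }
      NULL
    }
    nv <- sample(ge$n_vessels[1]:ge$n_vessels[2], 1)
    for (v in seq_len(nv)) place(.runifr(ge$vessel_radius), "vessel",
                                 .runifr(cr$vessel))
    nn <- sample(ge$n_nerves[1]:ge$n_nerves[2], 1)
    for (v in seq_len(nn)) place(.runifr(ge$nerve_radius), "nerve",
                                 .runifr(cr$nerve))

    anomalies <- list()
    na <- sample(0:ge$max_anomalies, 1)
    if (na > 0 && config$anomaly_prob > 0)
      na <- rbinom(1, na, config$anomaly_prob)
    else if (config$anomaly_prob == 0) na <- 0L
    types <- c("edema", "tumor", "hematoma", "foreign_body")
    for (a in seq_len(na)) {
      ty <- sample(types, 1)
      va <- .runifr(cr[[ty]])
      pl <- place(.runifr(ge$anomaly_radius), ty, va)
      if (!is.null(pl))
        anomalies[[length(anomalies) + 1L]] <-
          list(type = ty, center = pl$center, size = pl$radius,
               conductivity = va)
    }
    structure(list(conductivity = sigma, labels = labels, mask = mask,
                   anomalies = anomalies, skin_thickness = ts,
                   fat_thickness = tf, seed = seed, grid = grid,
                   radius = radius),
              class = "eit_phantom")
  })
}

#' Generate a list of phantoms
#'
#' @param n number of phantoms (>= 1).
#' @param base_seed phantom `i` uses seed `base_seed + i - 1`.
#' @param ... passed to [generate_phantom()].
#' @return list of `"eit_phantom"` objects.
#' @export
generate_dataset <- function(n, base_seed = 1L, ...) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) generate_phantom(base_seed + i - 1L, ...))
}

#' Random train/validation/test split
#'
#' @param n number of samples.
#' @param ratios length-3 proportions summing to 1; sizes are
#'   `floor(r1*n)`, `floor(r2*n)` and the remainder.
#' @param seed permutation seed.
#' @return list of class `"eit_split"` with disjoint index vectors
#'   `train`, `val`, `test` covering `1:n`.
#' @export
split_dataset <- function(n, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  .with_seed(seed, {
    perm <- sample.int(n)
    n1 <- floor(ratios[1] * n)
    n2 <- floor(ratios[2] * n)
    structure(list(train = sort(perm[seq_len(n1)]),
                   val = sort(perm[n1 + seq_len(n2)]),
                   test = sort(perm[(n1 + n2 + 1):n])),
              class = "eit_split")
  })
}

.rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Training-time augmentation of an input/label image pair
#'
#' Applies the same random right-angle rotation and optional horizontal flip
#' to both images, plus a small additive Gaussian perturbation to the network
#' input only.
#'
#' @param input,label square matrices (the HTV image and the ground truth).
#' @param seed optional seed for the random draws.
#' @param rotation force a rotation in `c(0, 90, 180, 270)` degrees.
#' @param flip force the horizontal flip on/off.
#' @param noise_sd standard deviation of the input perturbation.
#' @return list with transformed `input`, `label`, and the applied
#'   `rotation` and `flip`.
#' @export
augment <- function(input, label, seed = NULL, rotation = NULL, flip = NULL,
                    noise_sd = 0.01) {
  if (nrow(input) != ncol(input) || !identical(dim(input), dim(label)))
    stop("augment expects a pair of square images of equal size")
  do_it <- function() {
    if (is.null(rotation)) rotation <- sample(c(0, 90, 180, 270), 1)
    if (is.null(flip)) flip <- runif(1) < 0.5
    if (!rotation %in% c(0, 90, 180, 270)) stop("rotation must be a right angle")
    k <- rotation / 90
    for (i in seq_len(k)) { input <- .rot90cw(input); label <- .rot90cw(label) }
    if (flip) { input <- input[, ncol(input):1]; label <- label[, ncol(label):1] }
    if (noise_sd > 0)
      input <- input + matrix(rnorm(length(input), 0, noise_sd), nrow(input))
    list(input = input, label = label, rotation = rotation, flip = flip)
  }
  if (is.null(seed)) do_it() else .with_seed(seed, do_it())
}

#' @export
print.eit_phantom <- function(x, ...) {
  cat("Leg phantom", x$grid, "x", x$grid, " (seed", x$seed, ")\n")
  cat("  conductivity range:", sprintf("%.3f..%.3f S/m", min(x$conductivity),
                                       max(x$conductivity)), "\n")
  cat("  anomalies:", length(x$anomalies),
      if (length(x$anomalies))
        paste0("(", paste(vapply(x$anomalies, `[[`, "", "type"),
                          collapse = ", "), ")") else "", "\n")
  invisible(x)
}

#' Export phantom images to PNG for visual inspection
#'
#' Writes a grey-scale panel of conductivity maps (0..2 S/m mapped to black..
#' white).  Requires the `png` package.
#'
#' @param phantoms list of phantoms (or matrices in `[0, 2]`).
#' @param file output path.
#' @param ncol panel columns.
#' @export
export_png <- function(phantoms, file, ncol = 4L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  mats <- lapply(phantoms, function(p)
    if (inherits(p, "eit_phantom")) p$conductivity else p)
  g <- nrow(mats[[1]])
  nr <- ceiling(length(mats) / ncol)
  panel <- matrix(0, nr * g, ncol * g)
  for (i in seq_along(mats)) {
    r0 <- ((i - 1) %/% ncol) * g
    c0 <- ((i - 1) %% ncol) * g
    panel[r0 + seq_len(g), c0 + seq_len(g)] <- pmin(pmax(mats[[i]] / 2, 0), 1)
  }
  png::writePNG(panel, file)
  invisible(file)
}
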