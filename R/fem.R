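# Finite-element forward model on the pixelated leg disc.
#
# The disc of radius R inside the square pixel grid is meshed by splitting
# every in-disc pixel into two linear triangles whose nodes are the pixel
# corners.  Point electrodes sit on the 16 boundary nodes closest to uniform
# angles.  The sensitivity (Jacobian) matrix is assembled by the adjoint
# method from the drive and measurement fields at the homogeneous reference
# conductivity; the full nonlinear solve is also available and serves as an
# oracle for the linearization.

.build_mesh <- function(grid = 64L, radius = 30) {
  cx <- (grid + 1) / 2
  d <- .disc(grid)
  inpix <- which(d <= radius, arr.ind = TRUE)      # (row=i, col=j)
  # node key for pixel corner (i +/- .5, j +/- .5): use half-integer lattice
  nodekey <- function(i, j) paste(i, j, sep = ",")
  keys <- character(0)
  corner <- function(i, j) rbind(c(i - 0.5, j - 0.5), c(i + 0.5, j - 0.5),
                                 c(i - 0.5, j + 0.5), c(i + 0.5, j + 0.5))
  allc <- unique(do.call(rbind, lapply(seq_len(nrow(inpix)), function(r)
    corner(inpix[r, 1], inpix[r, 2]))))
  keys <- nodekey(allc[, 1], allc[, 2])
  nid <- seq_along(keys)
  names(nid) <- keys
  # node coordinates in (x=col, y=row)
  nodes <- cbind(x = allc[, 2], y = allc[, 1])
  tris <- list(); tpix <- integer(0)
  for (r in seq_len(nrow(inpix))) {
    i <- inpix[r, 1]; j <- inpix[r, 2]
    bl <- nid[[nodekey(i + 0.5, j - 0.5)]]
    br <- nid[[nodekey(i + 0.5, j + 0.5)]]
    tl <- nid[[nodekey(i - 0.5, j - 0.5)]]
    tr <- nid[[nodekey(i - 0.5, j + 0.5)]]
    tris[[length(tris) + 1L]] <- c(bl, br, tr)
    tris[[length(tris) + 1L]] <- c(bl, tr, tl)
    tpix <- c(tpix, r, r)
  }
  tri <- do.call(rbind, tris)
  # boundary nodes: nodes of edges used by exactly one triangle
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  bnd_edges <- ed[ekey %in% names(which(table(ekey) == 1L)), , drop = FALSE]
  bnd_nodes <- sort(unique(as.vector(bnd_edges)))
  list(nodes = nodes, tri = tri, tri_pixel = tpix, pixels = inpix,
       boundary_nodes = bnd_nodes, grid = grid, radius = radius, center = cx)
}

.electrode_nodes <- function(mesh, n_electrodes = 16L) {
  ang <- atan2(mesh$nodes[mesh$boundary_nodes, "y"] - mesh$center,
               mesh$nodes[mesh$boundary_nodes, "x"] - mesh$center)
  rad <- sqrt((mesh$nodes[mesh$boundary_nodes, "x"] - mesh$center)^2 +
              (mesh$nodes[mesh$boundary_nodes, "y"] - mesh$center)^2)
  target <- 2 * pi * (seq_len(n_electrodes) - 1) / n_electrodes
  target[target > pi] <- target[target > pi] - 2 * pi
  vapply(target, function(th) {
    dd <- abs(atan2(sin(ang - th), cos(ang - th)))
    cand <- which(dd == min(dd))
    mesh$boundary_nodes[cand[which.max(rad[cand])]]
  }, integer(1))
}

.tri_geom <- function(mesh) {
  n <- mesh$nodes
  t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  x <- cbind(n[t1, "x"], n[t2, "x"], n[t3, "x"])
  y <- cbind(n[t1, "y"], n[t2, "y"], n[t3, "y"])
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  area <- 0.5 * abs(b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  list(b = b, c = cc, area = area)
}

.assemble <- function(mesh, geom, sigma_el) {
  ne <- nrow(mesh$tri)
  ii <- jj <- integer(9 * ne); vv <- numeric(9 * ne)
  pos <- 1L
  idx <- rep(1:3, each = 3); jdx <- rep(1:3, 3)
  # vectorized triplet assembly
  coef <- sigma_el / (4 * geom$area)
  for (a in 1:3) for (bb in 1:3) {
    k <- ((a - 1) * 3 + bb - 1) * ne + seq_len(ne)
    ii[k] <- mesh$tri[, a]
    jj[k] <- mesh$tri[, bb]
    vv[k] <- coef * (geom$b[, a] * geom$b[, bb] + geom$c[, a] * geom$c[, bb])
  }
  nn <- nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nn, nn))
}

.fem_solve_fields <- function(K, rhs, ground) {
  free <- setdiff(seq_len(nrow(K)), ground)
  U <- matrix(0, nrow(K), ncol(rhs))
  sol <- Matrix::solve(K[free, free], rhs[free, , drop = FALSE])
  U[free, ] <- as.matrix(sol)
  U
}

#' Build the linearized EIT sensitivity model
#'
#' Meshes the disc, solves the drive and measurement fields at the homogeneous
#' reference conductivity, and assembles the 208 x P pixel Jacobian `J`
#' (volts per S/m) together with the baseline voltages `v0`.  The forward
#' model is `v = v0 + J (sigma - sigma_ref)` on in-disc pixels.
#'
#' @param grid image size in pixels.
#' @param radius disc radius in pixels.
#' @param protocol an [build_protocol()] object.
#' @param ref_conductivity homogeneous reference (S/m), must be positive.
#' @param current drive current amplitude in amperes (1 mA nominal).
#' @return object of class `"eit_sensitivity"`.
#' @export
build_sensitivity <- function(grid = 64L, radius = 30,
                              protocol = build_protocol(),
                              ref_conductivity = 1.0, current = 1e-3) {
  if (ref_conductivity <= 0) stop("reference conductivity must be positive")
  mesh <- .build_mesh(grid, radius)
  geom <- .tri_geom(mesh)
  el <- .electrode_nodes(mesh, protocol$n_electrodes)
  nn <- nrow(mesh$nodes)
  K <- .assemble(mesh, geom, rep(ref_conductivity, nrow(mesh$tri)))
  ground <- which.min(abs(mesh$nodes[, "x"] - mesh$center) +
                      abs(mesh$nodes[, "y"] - mesh$center))
  L <- protocol$n_electrodes
  rhs_d <- matrix(0, nn, L)
  rhs_m <- matrix(0, nn, L)
  for (k in seq_len(L)) {
    rhs_d[el[protocol$drive_pairs[k, 1]], k] <- current
    rhs_d[el[protocol$drive_pairs[k, 2]], k] <- -current
    # measurement patterns: unit current through adjacent pair (k, k+1)
    rhs_m[el[k], k] <- 1
    rhs_m[el[(k %% L) + 1L], k] <- -1
  }
  Ud <- .fem_solve_fields(K, rhs_d, ground)
  Um <- .fem_solve_fields(K, rhs_m, ground)
  # per-element gradients of all fields
  gx_d <- gy_d <- matrix(0, nrow(mesh$tri), L)
  gx_m <- gy_m <- matrix(0, nrow(mesh$tri), L)
  for (a in 1:3) {
    gx_d <- gx_d + geom$b[, a] * Ud[mesh$tri[, a], ] / (2 * geom$area)
    gy_d <- gy_d + geom$c[, a] * Ud[mesh$tri[, a], ] / (2 * geom$area)
    gx_m <- gx_m + geom$b[, a] * Um[mesh$tri[, a], ] / (2 * geom$area)
    gy_m <- gy_m + geom$c[, a] * Um[mesh$tri[, a], ] / (2 * geom$area)
  }
  tab <- protocol$table
  nM <- nrow(tab)
  Jel <- matrix(0, nM, nrow(mesh$tri))
  v0 <- numeric(nM)
  for (r in seq_len(nM)) {
    dpair <- tab[r, 1]                 # drive index = drive_a
    mpair <- tab[r, 3]                 # measurement pattern index = meas_a
    Jel[r, ] <- -geom$area * (gx_d[, dpair] * gx_m[, mpair] +
                              gy_d[, dpair] * gy_m[, mpair])
    v0[r] <- Ud[el[tab[r, 3]], dpair] - Ud[el[tab[r, 4]], dpair]
  }
  # aggregate elements into their pixels
  J <- t(rowsum(t(Jel), group = mesh$tri_pixel, reorder = TRUE))
  pixel_index <- mesh$pixels[, 1] + (mesh$pixels[, 2] - 1L) * grid
  mask <- matrix(FALSE, grid, grid)
  mask[pixel_index] <- TRUE
  structure(list(J = J, v0 = v0, pixel_index = pixel_index, mask = mask,
                 mesh = mesh, geom = geom, electrodes = el,
                 protocol = protocol, ref = ref_conductivity,
                 current = current, ground = ground),
            class = "eit_sensitivity")
}

#' @export
print.eit_sensitivity <- function(x, ...) {
  cat("EIT sensitivity model:", nrow(x$J), "measurements x", ncol(x$J),
      "pixels (grid", x$mesh$grid, ", R =", x$mesh$radius, ")\n")
  invisible(x)
}

#' Linearized forward solve
#'
#' `v = v0 + J (sigma - sigma_ref)` over in-disc pixels.
#'
#' @param sens an [build_sensitivity()] object.
#' @param phantom an `"eit_phantom"` or a conductivity matrix of matching size.
#' @return numeric voltage vector (length 208 for the default protocol).
#' @export
solve_forward <- function(sens, phantom) {
  sigma <- if (inherits(phantom, "eit_phantom")) phantom$conductivity else phantom
  if (!identical(dim(sigma), c(sens$mesh$grid, sens$mesh$grid)))
    stop("phantom grid does not match the sensitivity geometry")
  as.vector(sens$v0 + sens$J %*% (sigma[sens$pixel_index] - sens$ref))
}

#' Full nonlinear FEM forward solve (linearization oracle)
#'
#' Re-assembles the stiffness matrix with the element conductivities taken
#' from the pixel image and solves the drive fields exactly.  Slower than
#' [solve_forward()]; used to audit the linearized model.
#'
#' @inheritParams solve_forward
#' @return numeric voltage vector.
#' @export
fem_forward <- function(sens, phantom) {
  sigma <- if (inherits(phantom, "eit_phantom")) phantom$conductivity else phantom
  mesh <- sens$mesh
  sig_el <- sigma[sens$pixel_index][mesh$tri_pixel]
  K <- .assemble(mesh, sens$geom, sig_el)
  L <- sens$protocol$n_electrodes
  nn <- nrow(mesh$nodes)
  rhs <- matrix(0, nn, L)
  for (k in seq_len(L)) {
    rhs[sens$electrodes[sens$protocol$drive_pairs[k, 1]], k] <- sens$current
    rhs[sens$electrodes[sens$protocol$drive_pairs[k, 2]], k] <- -sens$current
  }
  Ud <- .fem_solve_fields(K, rhs, sens$ground)
  tab <- sens$protocol$table
  vapply(seq_len(nrow(tab)), function(r)
    Ud[sens$electrodes[tab[r, 3]], tab[r, 1]] -
      Ud[sens$electrodes[tab[r, 4]], tab[r, 1]], numeric(1))
}
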