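#' @useDynLib celldistr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Cell support: the 3D binary domain of one cell
#'
#' Wraps a 3D binary mask (voxel grid indexed \code{[x, y, z]}) together with
#' its voxel sizes.  The mask defines the spatial domain \code{Omega} of a
#' cell; its surface (foreground voxels 6-adjacent to background or to the
#' grid edge) is the reference against which the per-event boundary distances
#' are measured.
#'
#' On construction the mask is validated: it must contain at least one
#' foreground voxel, and every z-plane with foreground must be 2D-connected
#' after a single 3x3 morphological closing (a guard against fragmented
#' segmentations, for which radial boundary distances are ill-defined).
#'
#' @param mask logical (or 0/1 numeric) matrix or 3D array, indexed
#'   \code{[x, y]} or \code{[x, y, z]}; nonzero values are foreground.
#' @param voxel_size numeric length 3: micrometres per voxel along x, y
#'   (equal) and per z-step.
#' @param name identifier used in messages and reports.
#' @param check validate connectivity (set \code{FALSE} for very large masks).
#' @return an object of class \code{cell_support} with elements \code{mask},
#'   \code{voxel_size}, \code{name}, \code{dim}.
#' @export
cell_support <- function(mask, voxel_size = c(1, 1, 1), name = "cell",
                         check = TRUE) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  stopifnot(length(dim(mask)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  mask <- array(as.logical(mask != 0), dim = dim(mask))
  if (!any(mask)) stop("cell mask has no foreground voxel")
  if (check) {
    for (z in seq_len(dim(mask)[3])) {
      pl <- mask[, , z]
      if (!any(pl)) next
      ncomp <- cpp_n_components(binary_close(pl))
      if (ncomp > 1L)
        stop("z-plane ", z - 1L, " of mask '", name, "' has ", ncomp,
             " components after closing; expected a single connected cell")
    }
  }
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size),
                 name = name, dim = dim(mask)),
            class = "cell_support")
}

#' @export
print.cell_support <- function(x, ...) {
  cat("<cell_support> '", x$name, "': ", paste(x$dim, collapse = " x "),
      " voxels, ", sum(x$mask), " foreground, voxel size ",
      paste(signif(x$voxel_size, 4), collapse = " x "), " um\n", sep = "")
  invisible(x)
}

# one 3x3 binary closing (dilation then erosion), used only by the
# connectivity guard
binary_close <- function(pl) {
  shift2 <- function(m, dx, dy) {
    nx <- nrow(m); ny <- ncol(m)
    out <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    out[okx, oky] <- m[xs[okx], ys[oky]]
    out
  }
  acc <- pl
  for (dx in -1:1) for (dy in -1:1)
    if (dx != 0 || dy != 0) acc <- acc | shift2(pl, dx, dy)
  ero <- acc
  for (dx in -1:1) for (dy in -1:1)
    if (dx != 0 || dy != 0) ero <- ero & shift2(acc, dx, dy)
  ero
}

#' Surface voxels of a cell support
#'
#' Foreground voxels 6-adjacent to background or to the grid edge, i.e. the
#' discrete cell surface.
#'
#' @param cell a \code{\link{cell_support}}.
#' @return integer matrix with columns \code{x, y, z} (0-based voxel coords).
#' @export
boundary_voxels <- function(cell) {
  m <- cell$mask
  d <- dim(m)
  shift3 <- function(a, dx, dy, dz) {
    out <- array(FALSE, dim = d)
    xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy; zs <- seq_len(d[3]) - dz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    out[okx, oky, okz] <- a[xs[okx], ys[oky], zs[okz]]
    out
  }
  nb_all <- array(TRUE, dim = d)
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    nb_all <- nb_all & shift3(m, s[1], s[2], s[3])
  idx <- which(m & !nb_all, arr.ind = TRUE)
  colnames(idx) <- c("x", "y", "z")
  idx - 1L
}

# nearest-voxel membership test, continuous 0-based voxel-centre coordinates
inside_mask <- function(cell, x, y, z) {
  ix <- round(x) + 1; iy <- round(y) + 1; iz <- round(z) + 1
  d <- cell$dim
  ok <- ix >= 1 & iy >= 1 & iz >= 1 & ix <= d[1] & iy <= d[2] & iz <= d[3]
  res <- logical(length(x))
  res[ok] <- cell$mask[cbind(ix[ok], iy[ok], iz[ok])]
  res
}

# ratio converting z-plane index differences to xy-pixel units
z_scale <- function(cell) cell$voxel_size[3] / cell$voxel_size[1]

#' Reference frame: origin and zero-angle direction
#'
#' The cylindrical coordinate system is anchored at a reference point
#' \code{origin} (typically the event emitter or attractor, e.g. the Golgi or
#' ERC centroid) and a reference direction in the xy-plane that defines
#' \code{theta = 0}, so that angular densities are comparable across cells.
#'
#' @param origin numeric length 3, continuous 0-based voxel coordinates
#'   \code{(x, y, z)}.
#' @param direction numeric length 2 \code{(dx, dy)}; normalized internally.
#' @return an object of class \code{reference_frame}.
#' @export
reference_frame <- function(origin, direction = c(1, 0)) {
  stopifnot(length(origin) == 3L, length(direction) == 2L)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("reference direction has zero length")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm),
            class = "reference_frame")
}

#' Default reference frame from mask geometry
#'
#' Fallback when no biological reference point is available: the origin is the
#' foreground centroid and the direction the principal axis of the xy
#' foreground distribution.  Prefer a biologically meaningful reference
#' (e.g. the Golgi-to-cell-center axis) whenever one can be annotated.
#'
#' @param cell a \code{\link{cell_support}}.
#' @return a \code{\link{reference_frame}}.
#' @export
default_frame <- function(cell) {
  idx <- which(cell$mask, arr.ind = TRUE) - 1
  ctr <- colMeans(idx)
  xy <- sweep(idx[, 1:2, drop = FALSE], 2, ctr[1:2])
  ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)$vectors[, 1]
  # snap the origin to the nearest foreground voxel of its plane
  org <- ctr
  if (!inside_mask(cell, org[1], org[2], org[3])) {
    pl <- idx[round(idx[, 3]) == round(org[3]), , drop = FALSE]
    if (nrow(pl) == 0) pl <- idx
    k <- which.min((pl[, 1] - org[1])^2 + (pl[, 2] - org[2])^2)
    org <- pl[k, ]
  }
  reference_frame(org, ev)
}

frame_angle <- function(frame) atan2(frame$direction[2], frame$direction[1])

#' Angular boundary distance
#'
#' Distance from the origin, projected on plane \code{z}, to the first
#' background crossing of the cell mask along direction \code{theta}
#' (measured from the reference direction).  The ray is marched in 0.25-voxel
#' steps and the crossing is placed at the midpoint of the last-inside /
#' first-outside pair.  This per-event distance normalizes the radial
#' coordinate and weights the radial and angular densities, making them
#' independent of the cell shape.
#'
#' @param cell a \code{\link{cell_support}}.
#' @param frame a \code{\link{reference_frame}}.
#' @param theta angle(s) in radians from the reference direction.
#' @param z plane index (0-based); defaults to the origin's plane.
#' @return numeric vector of distances in xy-pixel units (strictly positive).
#' @export
boundary_distance_angular <- function(cell, frame, theta,
                                      z = round(frame$origin[3])) {
  z <- round(z)
  if (z < 0 || z >= cell$dim[3]) stop("plane ", z, " outside the mask grid")
  pl <- cell$mask[, , z + 1]
  ox <- frame$origin[1]; oy <- frame$origin[2]
  if (!inside_mask(cell, ox, oy, z))
    stop("origin projection (", round(ox, 2), ", ", round(oy, 2),
         ") lies outside the foreground of plane ", z)
  cpp_ray_cast(pl, ox, oy, theta + frame_angle(frame), 0.25)
}

# foreground z-extent (0-based bottom and top plane index) of the z-column at
# a continuous lateral position; NULL when the column is empty
column_extent <- function(cell, x, y) {
  ix <- round(x) + 1; iy <- round(y) + 1
  if (ix < 1 || iy < 1 || ix > cell$dim[1] || iy > cell$dim[2]) return(NULL)
  zz <- which(cell$mask[ix, iy, ])
  if (length(zz) == 0) return(NULL)
  c(min(zz), max(zz)) - 1L
}

#' Axial boundary distance
#'
#' Euclidean distance (z scaled by the voxel-size ratio) from the origin
#' \code{O} to the surface point of the z-column at lateral position
#' \code{(r, theta)}: the topmost foreground voxel of that column, the natural
#' "in-depth" reference for flat adherent cells.  Used as the per-event weight
#' of the depth density.
#'
#' @inheritParams boundary_distance_angular
#' @param r radial distance(s) in xy-pixel units.
#' @param theta angle(s) from the reference direction (recycled with \code{r}).
#' @return numeric vector of distances in xy-pixel units.
#' @export
boundary_distance_axial <- function(cell, frame, r, theta) {
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  a0 <- frame_angle(frame)
  ox <- frame$origin[1]; oy <- frame$origin[2]; oz <- frame$origin[3]
  zs <- z_scale(cell)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- ox + r[i] * cos(theta[i] + a0)
    y <- oy + r[i] * sin(theta[i] + a0)
    ext <- column_extent(cell, x, y)
    if (is.null(ext))
      stop("lateral position (r = ", round(r[i], 2), ", theta = ",
           round(theta[i], 3), ") is outside the xy-projection of the mask")
    dz2 <- ((ext[2] - oz) * zs)^2
    out[i] <- sqrt((x - ox)^2 + (y - oy)^2 + dz2)
  }
  pmax(out, 0.5)   # floor guards the degenerate origin-on-surface case
}

#' Cylindrical, shape-normalized event coordinates
#'
#' Converts event positions to cylindrical coordinates \code{(r, theta, z)}
#' about the reference frame, computes the per-event boundary distances
#' \code{d_theta} (lateral, along the event's angle in its plane) and
#' \code{d_z} (to the top surface of the event's z-column), and the
#' normalized coordinates \code{r_norm = r / d_theta} in [0, 1] and
#' \code{z_norm} = relative height within the event's foreground z-column.
#' The normalized coordinates are what make densities comparable across cells
#' of different shape and size.
#'
#' @param points data.frame with columns \code{x, y, z} (continuous 0-based
#'   voxel coordinates) and optionally \code{w} (nonnegative weights,
#'   default 1).
#' @param frame a \code{\link{reference_frame}}; its origin must lie inside
#'   the mask.
#' @param cell a \code{\link{cell_support}}; every point must lie inside.
#' @return a data.frame of class \code{cylindrical_events} with columns
#'   \code{r, theta, z, w, d_theta, d_z, r_norm, z_norm}.
#' @export
to_cylindrical <- function(points, frame, cell) {
  stopifnot(is.data.frame(points), all(c("x", "y", "z") %in% names(points)),
            nrow(points) >= 1)
  w <- if ("w" %in% names(points)) as.numeric(points$w) else rep(1, nrow(points))
  if (any(w < 0)) stop("negative event weights")
  if (sum(w) <= 0) stop("total event weight is zero")
  if (!inside_mask(cell, frame$origin[1], frame$origin[2], frame$origin[3]))
    stop("frame origin lies outside the cell mask")
  ok <- inside_mask(cell, points$x, points$y, points$z)
  if (!all(ok))
    stop("events outside the cell mask at rows: ",
         paste(utils::head(which(!ok), 10), collapse = ", "))
  dx <- points$x - frame$origin[1]
  dy <- points$y - frame$origin[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) - frame_angle(frame)) %% (2 * pi)
  theta[r < 1e-12] <- 0          # angle undefined at the origin: convention
  z <- points$z
  # d_theta per event, ray-cast grouped by plane
  d_theta <- numeric(nrow(points))
  for (zp in unique(round(z))) {
    sel <- round(z) == zp
    d_theta[sel] <- boundary_distance_angular(cell, frame, theta[sel], zp)
  }
  d_z <- boundary_distance_axial(cell, frame, r, theta)
  r_norm <- pmin(pmax(r / d_theta, 0), 1)
  z_norm <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    ext <- column_extent(cell, points$x[i], points$y[i])
    h <- ext[2] - ext[1]
    z_norm[i] <- if (h <= 0) 0 else min(max((z[i] - ext[1]) / h, 0), 1)
  }
  structure(data.frame(r = r, theta = theta, z = z, w = w,
                       d_theta = d_theta, d_z = d_z,
                       r_norm = r_norm, z_norm = z_norm),
            class = c("cylindrical_events", "data.frame"))
}
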