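#' Entropy of the angular event distribution about a candidate origin
#'
#' Recomputes the event angles for a candidate reference point, estimates the
#' angular density with a von Mises kernel (concentration from the circular
#' rule of thumb, events weighted by their \code{w}), and returns the
#' differential entropy \code{-sum_g f(theta_g) log f(theta_g) dtheta} over a
#' K-point angular grid.  The entropy is maximal for the uniform angular
#' density, so the candidate maximizing it is the point about which the
#' events are most uniformly distributed — the putative organizing center
#' (emitter or attractor) of the events.
#'
#' Two variants are available.  \code{entropy_of = "events"} replaces the
#' grid integral by the sum over the N event angles; that sample sum
#' estimates \code{-int f^2 log f}, which is not maximized by the uniform
#' density, so it is provided for comparison only and the grid form is the
#' default.  \code{weighting = "boundary"} additionally multiplies each
#' event's weight by its angular boundary distance, as the comparison-layer
#' densities do; within a single cell that geometric factor tilts the
#' angular density wherever the candidate is off-center, biasing the search,
#' so the default weights by \code{w} alone.
#'
#' @param points data.frame with columns \code{x, y} (continuous voxel
#'   coordinates) and optionally \code{w}; at least 2 events not all at the
#'   candidate origin.
#' @param origin candidate origin, numeric length 2 (x, y) on the analysis
#'   plane.
#' @param cell a \code{\link{cell_support}}.
#' @param z plane index of the analysis.
#' @param entropy_of \code{"grid"} (default) or \code{"events"}.
#' @param weighting \code{"event"} (default) or \code{"boundary"}.
#' @param K angular grid size for the entropy integral.
#' @return the entropy (finite; a 1e-12 floor inside the log guards
#'   underflow).
#' @export
angular_entropy <- function(points, origin, cell, z = 0,
                            entropy_of = c("grid", "events"),
                            weighting = c("event", "boundary"), K = 360L) {
  entropy_of <- match.arg(entropy_of)
  weighting <- match.arg(weighting)
  stopifnot(nrow(points) >= 2)
  w <- if ("w" %in% names(points)) as.numeric(points$w) else rep(1, nrow(points))
  dx <- points$x - origin[1]
  dy <- points$y - origin[2]
  r <- sqrt(dx^2 + dy^2)
  if (all(r < 1e-9)) stop("all events lie at the candidate origin")
  theta <- atan2(dy, dx) %% (2 * pi)
  theta[r < 1e-12] <- 0
  wt <- w
  if (weighting == "boundary") {
    pl <- cell$mask[, , round(z) + 1]
    wt <- w * cpp_ray_cast(pl, origin[1], origin[2], theta, 0.25)
  }
  kappa <- suppressWarnings(vonmises_concentration(theta, wt))
  cw <- wt / sum(wt)
  if (entropy_of == "grid") {
    grid <- seq(0, 2 * pi, length.out = K + 1)[seq_len(K)]
    f <- as.vector(vonmises_kernel(outer(grid, theta, "-"), kappa) %*% cw)
    f <- pmax(f, 1e-12)
    -sum(f * log(f)) * 2 * pi / K
  } else {
    f <- as.vector(vonmises_kernel(outer(theta, theta, "-"), kappa) %*% cw)
    f <- pmax(f, 1e-12)
    -sum(f * log(f))
  }
}

#' Entropy map over candidate origins
#'
#' Evaluates \code{\link{angular_entropy}} on every lattice point of the
#' analysis plane lying inside the mask, at the given stride.  The argmax is
#' the candidate giving the most uniform angular distribution of the events.
#'
#' @inheritParams angular_entropy
#' @param step lattice spacing in voxels (>= 1).
#' @param ... passed on to \code{\link{angular_entropy}}.
#' @return an object of class \code{entropy_map}: data.frame of candidates
#'   (\code{x, y, entropy}) with attributes \code{argmax} (the best
#'   candidate), \code{max_entropy}, \code{n_eval}, \code{step},
#'   \code{plane}.
#' @export
entropy_map <- function(points, cell, step = 2, z = 0, ...) {
  stopifnot(step >= 1)
  pl <- cell$mask[, , round(z) + 1]
  xs <- seq(1, nrow(pl), by = step)
  ys <- seq(1, ncol(pl), by = step)
  cand <- expand.grid(x = xs, y = ys)
  keep <- pl[as.matrix(cand)]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) stop("no lattice point inside the mask")
  ent <- vapply(seq_len(nrow(cand)), function(i)
    angular_entropy(points, c(cand$x[i] - 1, cand$y[i] - 1), cell, z = z, ...),
    numeric(1))
  best <- which.max(ent)
  structure(data.frame(x = cand$x - 1, y = cand$y - 1, entropy = ent),
            class = c("entropy_map", "data.frame"),
            argmax = c(cand$x[best] - 1, cand$y[best] - 1),
            max_entropy = ent[best], n_eval = nrow(cand),
            step = step, plane = z)
}

#' Locate the point of most uniform angular distribution
#'
#' Finds the candidate origin maximizing the angular entropy, either by the
#' exhaustive \code{\link{entropy_map}} at stride 1 (\code{method = "map"})
#' or by an accelerated hierarchical refinement (\code{method =
#' "bisection"}): a coarse lattice at one eighth of the mask bounding box is
#' evaluated, the search recenters on the best cell, the stride is halved and
#' a local 5x5 lattice evaluated, until the stride drops below 1 voxel.  The
#' refinement is deterministic and evaluates far fewer candidates than the
#' exhaustive map while attaining (on unimodal entropy surfaces) essentially
#' the same maximum.
#'
#' @inheritParams entropy_map
#' @param method \code{"bisection"} (the default) or \code{"map"}.
#' @return list with \code{origin} (x, y, plane), \code{entropy},
#'   \code{n_eval} and \code{method}.
#' @export
find_uniform_center <- function(points, cell, method = c("bisection", "map"),
                                z = 0, ...) {
  method <- match.arg(method)
  if (method == "map") {
    em <- entropy_map(points, cell, step = 1, z = z, ...)
    return(list(origin = c(attr(em, "argmax"), z),
                entropy = attr(em, "max_entropy"),
                n_eval = attr(em, "n_eval"), method = "map"))
  }
  pl <- cell$mask[, , round(z) + 1]
  fg <- which(pl, arr.ind = TRUE) - 1
  bb <- c(diff(range(fg[, 1])), diff(range(fg[, 2])))
  stride <- max(bb) / 8
  cache <- new.env(hash = TRUE)
  n_eval <- 0L
  ev <- function(x, y) {
    key <- paste0(round(x, 3), "_", round(y, 3))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- angular_entropy(points, c(x, y), cell, z = z, ...)
    cache[[key]] <- val
    n_eval <<- n_eval + 1L
    val
  }
  in_plane <- function(x, y) {
    ix <- round(x) + 1; iy <- round(y) + 1
    ix >= 1 && iy >= 1 && ix <= nrow(pl) && iy <= ncol(pl) && pl[ix, iy]
  }
  # coarse pass over the full bounding box
  xs <- seq(min(fg[, 1]), max(fg[, 1]), by = stride)
  ys <- seq(min(fg[, 2]), max(fg[, 2]), by = stride)
  best <- NULL
  for (x in xs) for (y in ys) {
    if (!in_plane(x, y)) next
    e <- ev(x, y)
    if (is.null(best) || e > best$e) best <- list(x = x, y = y, e = e)
  }
  if (is.null(best)) stop("no coarse lattice point inside the mask")
  # local refinement with halving stride
  while (stride >= 1) {
    stride <- stride / 2
    for (dx in -2:2) for (dy in -2:2) {
      x <- best$x + dx * stride; y <- best$y + dy * stride
      if (!in_plane(x, y)) next
      e <- ev(x, y)
      if (e > best$e) best <- list(x = x, y = y, e = e)
    }
  }
  list(origin = c(best$x, best$y, z), entropy = best$e,
       n_eval = n_eval, method = "bisection")
}

#' Track the uniform-distribution center over time
#'
#' Runs \code{\link{find_uniform_center}} on the event set of every frame
#' and reports the Euclidean distance (micrometres, voxel sizes applied)
#' between the center at frame t and the center at the first frame.  A
#' stationary series indicates a stable organizing center; a growing series
#' indicates that the center is being displaced (e.g. on cytoskeleton
#' disruption).  Frames with fewer than 2 events yield \code{NA} and the
#' series continues.
#'
#' @param events_by_frame list of per-frame event data.frames
#'   (\code{x, y[, w]}), at least 2 frames.
#' @inheritParams find_uniform_center
#' @return data.frame with columns \code{frame, x, y, entropy, dist_um};
#'   \code{dist_um} is 0 at the first frame by definition.
#' @export
track_center_over_time <- function(events_by_frame, cell,
                                   method = "bisection", z = 0, ...) {
  stopifnot(length(events_by_frame) >= 2)
  res <- data.frame(frame = seq_along(events_by_frame) - 1L,
                    x = NA_real_, y = NA_real_, entropy = NA_real_,
                    dist_um = NA_real_)
  for (k in seq_along(events_by_frame)) {
    ev <- events_by_frame[[k]]
    if (is.null(ev) || nrow(ev) < 2) next
    ctr <- find_uniform_center(ev, cell, method = method, z = z, ...)
    res$x[k] <- ctr$origin[1]; res$y[k] <- ctr$origin[2]
    res$entropy[k] <- ctr$entropy
  }
  ref <- which(!is.na(res$x))[1]
  if (is.na(ref)) stop("no frame with enough events")
  px <- cell$voxel_size[1]
  res$dist_um <- sqrt((res$x - res$x[ref])^2 + (res$y - res$y[ref])^2) * px
  res
}
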