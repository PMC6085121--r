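#' Trajectory of one tracked particle
#'
#' Time-ordered 3D positions of a single tracked object, in continuous voxel
#' coordinates, with the acquisition interval \code{dt} (seconds per frame).
#'
#' @param t integer frame indices, strictly increasing.
#' @param x,y,z continuous voxel coordinates (z defaults to 0 for 2D data).
#' @param id track identifier.
#' @param dt seconds per frame.
#' @return a data.frame of class \code{trajectory} with attributes \code{id}
#'   and \code{dt}.
#' @export
trajectory <- function(t, x, y, z = 0, id = "track", dt = 1) {
  n <- length(t)
  stopifnot(n >= 1, length(x) == n, length(y) == n)
  z <- rep_len(z, n)
  if (n > 1 && any(diff(t) <= 0)) stop("frame indices must be strictly increasing")
  structure(data.frame(t = t, x = x, y = y, z = z),
            class = c("trajectory", "data.frame"), id = id, dt = dt)
}

traj_id <- function(traj) attr(traj, "id")

#' Gated distance between two trajectories
#'
#' Frame-wise distance with per-frame discrepancies capped at the gate
#' \code{epsilon}: \code{sum_t min(||a(t) - b(t)||, epsilon)} over the union
#' of frame indices.  Frames covered by only one of the two tracks contribute
#' the gate, penalizing length mismatch.  The cap makes tracker-to-tracker
#' comparison robust to outliers.
#'
#' @param a,b \code{\link{trajectory}} objects.
#' @param epsilon gate in pixels (> 0).
#' @return nonnegative distance, bounded by \code{|frame union| * epsilon}.
#' @export
gated_distance <- function(a, b, epsilon) {
  stopifnot(epsilon > 0)
  frames <- union(a$t, b$t)
  ia <- match(frames, a$t)
  ib <- match(frames, b$t)
  both <- !is.na(ia) & !is.na(ib)
  d <- rep(epsilon, length(frames))
  if (any(both)) {
    dd <- sqrt((a$x[ia[both]] - b$x[ib[both]])^2 +
               (a$y[ia[both]] - b$y[ib[both]])^2 +
               (a$z[ia[both]] - b$z[ib[both]])^2)
    d[both] <- pmin(dd, epsilon)
  }
  sum(d)
}

#' Consensus filter across particle trackers
#'
#' Retains a trajectory of the reference tracker (the first-listed set) iff
#' its gated distance to a matched trajectory is below \code{threshold} in at
#' least two trackers (the reference itself counts as one).  Matching within
#' each other tracker is greedy one-to-one in ascending gated distance, so a
#' single reported track cannot support several reference tracks.
#'
#' @param tracks_by_method named list of at least 2 track sets (each a list
#'   of \code{\link{trajectory}} objects); the first set is the reference.
#' @param epsilon gate in pixels for the gated distance (default 5).
#' @param threshold maximal gated distance for a match (default 2).
#' @return the retained subset of the reference track set.
#' @export
consensus_filter <- function(tracks_by_method, epsilon = 5, threshold = 2) {
  if (length(tracks_by_method) < 2) stop("need at least 2 track sets")
  ref <- tracks_by_method[[1]]
  support <- rep(1L, length(ref))   # the reference method supports its own tracks
  for (m in seq_along(tracks_by_method)[-1]) {
    other <- tracks_by_method[[m]]
    if (length(other) == 0) next
    dm <- matrix(NA_real_, length(ref), length(other))
    for (i in seq_along(ref)) for (j in seq_along(other))
      dm[i, j] <- gated_distance(ref[[i]], other[[j]], epsilon)
    ord <- order(dm)
    used_i <- logical(length(ref)); used_j <- logical(length(other))
    for (k in ord) {
      if (dm[k] >= threshold) break
      i <- (k - 1) %% length(ref) + 1
      j <- (k - 1) %/% length(ref) + 1
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      support[i] <- support[i] + 1L
    }
  }
  ref[support >= 2L]
}

#' Trajectory dynamic features
#'
#' \code{confinement_ratio}: net displacement divided by total path length,
#' in [0, 1]; 1 for perfectly direct motion, near 0 for confined or looping
#' motion.  A stationary track (zero path length) is assigned ratio 1 with a
#' warning, a point that never moves being maximally "direct".
#' \code{total_path_length}: sum of step lengths in micrometres (voxel sizes
#' applied).  \code{lifetime}: \code{(t_last - t_first) * dt} seconds.
#'
#' @param traj a \code{\link{trajectory}} with at least 2 points.
#' @param voxel_size micrometres per voxel along x, y, z.
#' @return a single numeric value.
#' @export
confinement_ratio <- function(traj, voxel_size = c(1, 1, 1)) {
  stopifnot(nrow(traj) >= 2)
  p <- scale_xyz(traj, voxel_size)
  disp <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  path <- sum(sqrt(rowSums(diff(as.matrix(p))^2)))
  if (path <= 0) {
    warning("stationary trajectory; confinement ratio set to 1")
    return(1)
  }
  disp / path
}

scale_xyz <- function(traj, voxel_size) {
  data.frame(x = traj$x * voxel_size[1], y = traj$y * voxel_size[2],
             z = traj$z * voxel_size[3])
}

#' @rdname confinement_ratio
#' @export
total_path_length <- function(traj, voxel_size = c(1, 1, 1)) {
  stopifnot(nrow(traj) >= 2)
  p <- scale_xyz(traj, voxel_size)
  sum(sqrt(rowSums(diff(as.matrix(p))^2)))
}

#' @rdname confinement_ratio
#' @export
lifetime <- function(traj) {
  stopifnot(nrow(traj) >= 2)
  (traj$t[nrow(traj)] - traj$t[1]) * attr(traj, "dt")
}

#' Classify a trajectory as periphery- or center-directed
#'
#' A track is \code{toward_periphery} when the normalized radius of its last
#' point exceeds that of its first point (net outward displacement in the
#' shape-normalized frame), \code{toward_center} otherwise.  Ties (net change
#' below 1e-9, e.g. purely tangential tracks) fall in the center class and
#' are flagged in the \code{tie} attribute so they can be reported.
#'
#' @param traj a \code{\link{trajectory}} with at least 2 points inside the
#'   mask.
#' @param frame a \code{\link{reference_frame}}.
#' @param cell a \code{\link{cell_support}}.
#' @return \code{"toward_periphery"} or \code{"toward_center"}, with
#'   attribute \code{tie}.
#' @export
classify_direction <- function(traj, frame, cell) {
  stopifnot(nrow(traj) >= 2)
  ends <- data.frame(x = traj$x[c(1, nrow(traj))],
                     y = traj$y[c(1, nrow(traj))],
                     z = traj$z[c(1, nrow(traj))])
  S <- to_cylindrical(ends, frame, cell)
  dr <- S$r_norm[2] - S$r_norm[1]
  tie <- abs(dr) < 1e-9
  structure(if (dr > 1e-9) "toward_periphery" else "toward_center", tie = tie)
}

#' Spatially binned average of a trajectory dynamic feature
#'
#' Localizes each track by the cylindrical coordinates of its median point
#' (the frame with index \code{floor((n - 1) / 2)} of the time-ordered
#' track), bins the chosen normalized axis into \code{B} bins, and averages
#' the feature within each bin.  Empty bins carry \code{NA}, never 0.
#'
#' @param tracks list of \code{\link{trajectory}} objects.
#' @param feature \code{"confinement_ratio"}, \code{"total_path_length"} or
#'   \code{"lifetime"}.
#' @param axis \code{"radius"}, \code{"angle"} or \code{"depth"}.
#' @param B number of bins (>= 2).
#' @param frame a \code{\link{reference_frame}}.
#' @param cell a \code{\link{cell_support}}.
#' @return an object of class \code{feature_histogram} with bin edges,
#'   per-bin mean feature and per-bin counts.
#' @export
feature_histogram <- function(tracks, feature = c("confinement_ratio",
                                                  "total_path_length",
                                                  "lifetime"),
                              axis = c("radius", "angle", "depth"),
                              B = NULL, frame, cell) {
  feature <- match.arg(feature)
  axis <- match.arg(axis)
  circular <- axis == "angle"
  if (is.null(B)) B <- if (circular) 36L else 20L
  stopifnot(B >= 2, length(tracks) >= 1)
  ffun <- switch(feature, confinement_ratio = confinement_ratio,
                 total_path_length = function(tr) total_path_length(tr, cell$voxel_size),
                 lifetime = lifetime)
  med <- lapply(tracks, function(tr) {
    k <- floor((nrow(tr) - 1) / 2) + 1
    data.frame(x = tr$x[k], y = tr$y[k], z = tr$z[k])
  })
  S <- to_cylindrical(do.call(rbind, med), frame, cell)
  coord <- switch(axis, radius = S$r_norm, angle = S$theta, depth = S$z_norm)
  m <- vapply(tracks, ffun, numeric(1))
  brk <- if (circular) seq(0, 2 * pi, length.out = B + 1)
         else seq(0, 1, length.out = B + 1)
  bi <- pmin(findInterval(coord, brk, rightmost.closed = TRUE), B)
  counts <- tabulate(bi, B)
  if (all(counts == 0)) stop("all bins empty")
  mean_feature <- rep(NA_real_, B)
  for (b in which(counts > 0)) mean_feature[b] <- mean(m[bi == b])
  structure(list(axis = axis, breaks = brk,
                 mids = (brk[-1] + brk[-length(brk)]) / 2,
                 mean_feature = mean_feature, counts = counts,
                 feature = feature, n = length(tracks)),
            class = "feature_histogram")
}

#' Smooth a binned feature profile into a comparable density
#'
#' Kernel-smooths the per-bin feature averages over the axis support
#' (reflected Gaussian on linear axes, von Mises on the angular axis), with
#' the bandwidth estimated from the bin-center locations of the nonempty
#' bins, then renormalizes to unit mass.  Empty bins are skipped, not
#' zero-filled, so sparsely sampled regions do not create spurious minima.
#' The renormalization makes feature profiles comparable with distribution
#' distances even though a profile of averages is not itself a probability
#' density.
#'
#' @param hist a \code{\link{feature_histogram}} with >= 2 nonempty bins.
#' @param K grid size (default 100 linear, 360 circular).
#' @return a \code{density1d}.
#' @export
feature_density <- function(hist, K = NULL) {
  ok <- which(hist$counts > 0)
  if (length(ok) < 2) stop("need at least 2 nonempty bins")
  circular <- hist$axis == "angle"
  if (is.null(K)) K <- if (circular) 360L else 100L
  centers <- hist$mids[ok]
  hv <- hist$mean_feature[ok]
  if (any(hv < 0)) stop("negative feature averages cannot be smoothed to a density")
  if (circular) {
    kappa <- tryCatch(vonmises_concentration(centers),
                      warning = function(w) 1e3)
    grid <- seq(0, 2 * pi, length.out = K + 1)[seq_len(K)]
    vals <- vapply(grid, function(g)
      sum(hv * vonmises_kernel(centers - g, kappa)), numeric(1))
    vals <- vals / (sum(vals) * 2 * pi / K)
    bw <- kappa
  } else {
    sig <- tryCatch(silverman_bandwidth(centers, support_width = 1),
                    warning = function(w) 1e-3)
    grid <- seq(0, 1, length.out = K)
    vals <- vapply(grid, function(g)
      sum(hv * gauss_reflect(g, centers, sig)), numeric(1))
    tot <- trapz(grid, vals)
    if (tot <= 0) stop("degenerate feature profile")
    vals <- vals / tot
    bw <- sig
  }
  density1d(support = if (circular) "circular" else "linear",
            grid = grid, values = vals,
            histogram = list(breaks = hist$breaks, mids = hist$mids,
                             weight = ifelse(is.na(hist$mean_feature), 0,
                                             hist$mean_feature),
                             density = ifelse(is.na(hist$mean_feature), 0,
                                              hist$mean_feature)),
            bandwidth = bw, n = hist$n)
}
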