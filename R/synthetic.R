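#' Rasterize a synthetic cell mask
#'
#' Deterministic binary masks emulating micro-patterned cell shapes: a disk,
#' an ellipse (axis ratio 0.6), a square, or a stylized crossbow (a central
#' disk with three lobes at 0 and +/- 2 pi / 3 from its principal axis).
#' Multi-plane masks are either flat (every plane identical) or dome-shaped
#' (the lateral extent shrinks with height as a hemisphere profile).
#'
#' @param shape \code{"disk"}, \code{"crossbow"}, \code{"ellipse"} or
#'   \code{"square"}.
#' @param size lateral radius / half-width in voxels (>= 10).
#' @param planes number of z-planes (default 1).
#' @param profile \code{"flat"} or \code{"dome"}.
#' @param margin background margin around the shape, in voxels.
#' @param voxel_size passed to \code{\link{cell_support}}.
#' @param name mask identifier.
#' @return a \code{\link{cell_support}}.
#' @export
make_cell_mask <- function(shape = c("disk", "crossbow", "ellipse", "square"),
                           size, planes = 1L, profile = c("flat", "dome"),
                           margin = 5L, voxel_size = c(1, 1, 1),
                           name = shape) {
  shape <- match.arg(shape)
  profile <- match.arg(profile)
  if (size < 10) stop("degenerate mask size (need >= 10 voxels)")
  L <- 2L * (ceiling(size) + margin) + 1L
  ctr <- (L - 1) / 2
  xg <- matrix(rep(0:(L - 1), L), L) - ctr
  yg <- t(xg)
  plane_for <- function(s) {
    switch(shape,
      disk = xg^2 + yg^2 <= s^2,
      ellipse = (xg / s)^2 + (yg / (0.6 * s))^2 <= 1,
      square = abs(xg) <= s & abs(yg) <= s,
      crossbow = {
        m <- xg^2 + yg^2 <= (0.7 * s)^2
        for (a in c(0, 2 * pi / 3, -2 * pi / 3)) {
          cx <- 0.55 * s * cos(a); cy <- 0.55 * s * sin(a)
          m <- m | ((xg - cx)^2 + (yg - cy)^2 <= (0.45 * s)^2)
        }
        m
      })
  }
  mask <- array(FALSE, dim = c(L, L, planes))
  for (k in seq_len(planes)) {
    s_k <- if (profile == "flat") size
           else size * sqrt(pmax(1 - ((k - 1) / planes)^2, 0.05))
    mask[, , k] <- plane_for(s_k)
  }
  cell_support(mask, voxel_size = voxel_size, name = name)
}

#' Generative model for synthetic events
#'
#' Describes the shape-normalized laws the analysis assumes: a radial law on
#' \code{r_norm} in [0, 1], an angular law on [0, 2 pi), a depth law on
#' \code{z_norm}, and a weight model.  All randomness flows from the single
#' \code{seed}.
#'
#' @param n number of events (>= 1).
#' @param radial \code{"uniform"} or \code{"beta"} (with \code{radial_shape}
#'   = c(a, b)).
#' @param radial_shape beta parameters for the radial law.
#' @param angular \code{"uniform"}, \code{"vonmises"} (mean \code{mu},
#'   concentration \code{kappa}) or \code{"mixture"} (list of components
#'   \code{list(mu=, kappa=, prob=)}).
#' @param mu,kappa von Mises parameters.
#' @param mixture list of mixture components.
#' @param depth beta parameters c(a, b) for the depth law.
#' @param weight \code{"unit"} or \code{"lognormal"} (meanlog, sdlog in
#'   \code{weight_pars}).
#' @param weight_pars lognormal parameters.
#' @param seed RNG seed.
#' @return an object of class \code{event_model}.
#' @export
event_model <- function(n, radial = c("uniform", "beta"),
                        radial_shape = c(1, 1),
                        angular = c("uniform", "vonmises", "mixture"),
                        mu = 0, kappa = 1, mixture = NULL,
                        depth = c(1, 1),
                        weight = c("unit", "lognormal"),
                        weight_pars = c(0, 0.5), seed = 1) {
  radial <- match.arg(radial)
  angular <- match.arg(angular)
  weight <- match.arg(weight)
  stopifnot(n >= 1, kappa > 0, all(radial_shape > 0), all(depth > 0))
  if (angular == "mixture" && is.null(mixture))
    stop("angular mixture requires mixture components")
  structure(list(n = as.integer(n), radial = radial,
                 radial_shape = radial_shape, angular = angular, mu = mu,
                 kappa = kappa, mixture = mixture, depth = depth,
                 weight = weight, weight_pars = weight_pars,
                 seed = as.integer(seed)),
            class = "event_model")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (> 0).
#' @return angles in [0, 2 pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    zz <- cos(pi * u1)
    f <- (1 + r * zz) / (r + zz)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

sample_model_coords <- function(model) {
  r <- switch(model$radial,
              uniform = stats::runif(model$n),
              beta = stats::rbeta(model$n, model$radial_shape[1],
                                  model$radial_shape[2]))
  th <- switch(model$angular,
    uniform = stats::runif(model$n, 0, 2 * pi),
    vonmises = rvonmises(model$n, model$mu, model$kappa),
    mixture = {
      probs <- vapply(model$mixture, function(c) c$prob, numeric(1))
      comp <- sample(length(model$mixture), model$n, replace = TRUE,
                     prob = probs)
      vapply(seq_len(model$n), function(i)
        rvonmises(1, model$mixture[[comp[i]]]$mu,
                  model$mixture[[comp[i]]]$kappa), numeric(1))
    })
  zn <- stats::rbeta(model$n, model$depth[1], model$depth[2])
  w <- switch(model$weight,
              unit = rep(1, model$n),
              lognormal = stats::rlnorm(model$n, model$weight_pars[1],
                                        model$weight_pars[2]))
  list(r_norm = r, theta = th, z_norm = zn, w = w)
}

#' Sample synthetic events into a cell mask
#'
#' Draws shape-normalized coordinates \code{(r_norm, theta, z_norm)} from an
#' \code{\link{event_model}} and maps them into the mask by inverting the
#' boundary-distance normalization of the geometry layer: the lateral
#' position is \code{origin + r_norm * d_theta(theta) * (cos, sin)} and the
#' height interpolates the foreground z-column at that position.  Draws
#' landing outside the mask (rasterization edge cases) are redrawn; failure
#' after 1e5 total draws signals a mask/model mismatch.
#'
#' @param cell a \code{\link{cell_support}}.
#' @param model an \code{\link{event_model}}.
#' @param frame reference frame used for the mapping (default
#'   \code{\link{default_frame}}).
#' @return data.frame \code{x, y, z, w} with the generating model and frame
#'   attached as attribute \code{truth}.
#' @export
sample_events <- function(cell, model, frame = default_frame(cell)) {
  set.seed(model$seed)
  zp <- round(frame$origin[3])
  a0 <- frame_angle(frame)
  out <- vector("list", model$n)
  got <- 0L
  tries <- 0L
  while (got < model$n) {
    need <- model$n - got
    m2 <- model; m2$n <- need
    cc <- sample_model_coords(m2)
    d_th <- boundary_distance_angular(cell, frame, cc$theta, zp)
    x <- frame$origin[1] + cc$r_norm * d_th * cos(cc$theta + a0)
    y <- frame$origin[2] + cc$r_norm * d_th * sin(cc$theta + a0)
    z <- numeric(need)
    ok <- logical(need)
    for (i in seq_len(need)) {
      # boundary-adjacent draws can round onto background; nudge them up to
      # one voxel inward (identically for every mask shape) before redrawing
      for (inset in c(0, 0.25, 0.5, 0.75, 1)) {
        ri <- max(cc$r_norm[i] * d_th[i] - inset, 0)
        xi <- frame$origin[1] + ri * cos(cc$theta[i] + a0)
        yi <- frame$origin[2] + ri * sin(cc$theta[i] + a0)
        ext <- column_extent(cell, xi, yi)
        if (is.null(ext)) next
        zi <- ext[1] + cc$z_norm[i] * (ext[2] - ext[1])
        if (inside_mask(cell, xi, yi, zi)) {
          x[i] <- xi; y[i] <- yi; z[i] <- zi; ok[i] <- TRUE
          break
        }
      }
    }
    if (any(ok)) {
      out[[got + 1L]] <- data.frame(x = x[ok], y = y[ok], z = z[ok],
                                    w = cc$w[ok])
      got <- got + sum(ok)
    }
    tries <- tries + need
    if (tries > 1e5) stop("rejection sampling failed; mask/model mismatch")
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  ev <- ev[seq_len(model$n), ]
  rownames(ev) <- NULL
  structure(ev, truth = list(model = model, frame = frame))
}

#' Sample synthetic trajectories with known directionality
#'
#' Biased random walks emulating outward- and inward-moving vesicles: each
#' track starts at a fraction \code{r0} of the boundary distance along a
#' random angle and drifts radially outward (with probability
#' \code{p_outward}) or inward, its heading perturbed by Gaussian angular
#' noise per step.  Outward tracks stop at the cell boundary; inward tracks
#' stop within one step of the origin (arrival at the hub); all stop at
#' \code{max_life} steps.  The planted labels are attached for recovery
#' tests.
#'
#' @param cell a \code{\link{cell_support}}.
#' @param n number of tracks.
#' @param p_outward probability of the outward kinematics.
#' @param r0 starting radius as a fraction of the angular boundary distance.
#' @param step_len step length in voxels per frame.
#' @param angular_noise standard deviation (radians) of the per-step heading
#'   perturbation.
#' @param max_life maximal number of steps.
#' @param frame reference frame (default mask centroid / principal axis).
#' @param dt seconds per frame.
#' @param seed RNG seed.
#' @return list of \code{\link{trajectory}} objects with attribute
#'   \code{truth}: data.frame \code{track_id, label}.
#' @export
sample_trajectories <- function(cell, n, p_outward = 1, r0 = 0.3,
                                step_len = 1.5, angular_noise = 0,
                                max_life = 30, frame = default_frame(cell),
                                dt = 1, seed = 1) {
  set.seed(seed)
  zp <- round(frame$origin[3])
  a0 <- frame_angle(frame)
  ox <- frame$origin[1]; oy <- frame$origin[2]
  tracks <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    outward <- stats::runif(1) < p_outward
    labels[i] <- if (outward) "toward_periphery" else "toward_center"
    th <- stats::runif(1, 0, 2 * pi)
    d <- boundary_distance_angular(cell, frame, th, zp)
    px <- ox + r0 * d * cos(th + a0)
    py <- oy + r0 * d * sin(th + a0)
    heading <- (th + a0) + if (outward) 0 else pi
    xs <- px; ys <- py
    r_prev <- sqrt((px - ox)^2 + (py - oy)^2)
    for (s in seq_len(max_life)) {
      heading <- heading + stats::rnorm(1, 0, angular_noise)
      nx <- xs[length(xs)] + step_len * cos(heading)
      ny <- ys[length(ys)] + step_len * sin(heading)
      if (!inside_mask(cell, nx, ny, zp)) break
      xs <- c(xs, nx); ys <- c(ys, ny)
      r_new <- sqrt((nx - ox)^2 + (ny - oy)^2)
      # an inward track arrives once its radius stops decreasing (at the
      # hub, or at closest approach when noise makes it miss the origin)
      if (!outward && (r_new < step_len || r_new > r_prev)) break
      r_prev <- r_new
    }
    if (length(xs) < 2) { xs <- c(xs, xs); ys <- c(ys, ys) }
    tracks[[i]] <- trajectory(t = seq_along(xs) - 1L, x = xs, y = ys, z = zp,
                              id = sprintf("sim%04d", i), dt = dt)
  }
  structure(tracks,
            truth = data.frame(track_id = sprintf("sim%04d", seq_len(n)),
                               label = labels, stringsAsFactors = FALSE))
}
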