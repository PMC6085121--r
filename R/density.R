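#' Weighted Silverman bandwidth
#'
#' Rule-of-thumb Gaussian bandwidth
#' \code{0.9 * min(sd, IQR/1.34) * n^(-1/5)} extended to weighted samples:
#' the standard deviation and interquartile range are weighted moments and
#' the sample size is replaced by the effective size
#' \code{n_eff = (sum w)^2 / sum(w^2)}, so the rule reduces to the textbook
#' form at unit weights and is invariant to rescaling all weights.
#'
#' @param samples numeric vector (at least 2 values).
#' @param weights nonnegative weights, default 1.
#' @param support_width width of the axis support, used only for the floor
#'   bandwidth (1e-3 of the width) returned when the weighted variance is
#'   degenerate.
#' @return a positive bandwidth.
#' @export
silverman_bandwidth <- function(samples, weights = NULL, support_width = 1) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples for a bandwidth")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  sw <- sum(weights)
  if (sw <= 0) stop("total weight is zero")
  p <- weights / sw
  mu <- sum(p * samples)
  v <- sum(p * (samples - mu)^2)
  iqr <- weighted_quantile(samples, weights, 0.75) -
         weighted_quantile(samples, weights, 0.25)
  spread <- min(sqrt(v), iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) {
    # zero-variance guard: all mass at one point
    warning("degenerate sample spread; using floor bandwidth")
    return(1e-3 * support_width)
  }
  n_eff <- sw^2 / sum(weights^2)
  0.9 * spread * n_eff^(-1 / 5)
}

# weighted quantile by linear interpolation of the cumulative weight
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = p, rule = 2, ties = "ordered")$y
}

# A(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises
# distribution with concentration kappa (scaled Bessels avoid overflow;
# besselI underflows past ~1.5e5, where the asymptotic expansion takes over)
vm_A <- function(kappa) {
  if (kappa > 1e5) return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# I0(kappa) * exp(-kappa), with the large-argument asymptotic branch
i0_scaled <- function(kappa) {
  ifelse(kappa > 1e5,
         (1 + 1 / (8 * kappa)) / sqrt(2 * pi * kappa),
         besselI(kappa, 0, expon.scaled = TRUE))
}

#' Von Mises plug-in concentration (circular rule of thumb)
#'
#' Kernel concentration for circular density estimation: the sample
#' concentration \code{kappa0} is obtained by inverting the weighted mean
#' resultant length through \code{A(kappa) = I1(kappa)/I0(kappa)} (bisection
#' to 1e-8), and the smoothing concentration follows Taylor's (2008) rule
#' \deqn{\hat\kappa = \left(\frac{3 n \hat\kappa_0^2 I_2(2\hat\kappa_0)}
#'   {4 \sqrt{\pi} I_0(\hat\kappa_0)^2}\right)^{2/5},}
#' with \code{n} the effective sample size for weighted data.  The
#' concentration plays the role of an inverse squared bandwidth.
#'
#' @param angles numeric vector of angles in radians (at least 2).
#' @param weights nonnegative weights, default 1.
#' @return a positive concentration, capped at 1e6 (with a warning) when all
#'   angles coincide.
#' @export
vonmises_concentration <- function(angles, weights = NULL) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sum(weights)
  if (sw <= 0) stop("total weight is zero")
  rbar <- sqrt(sum(weights * cos(angles))^2 + sum(weights * sin(angles))^2) / sw
  if (rbar >= 1 - 1e-9) {
    warning("all angles coincide; capping concentration at 1e6")
    return(1e6)
  }
  n_eff <- sw^2 / sum(weights^2)
  kappa0 <- invert_vm_A(rbar)
  if (kappa0 < 1e-8) kappa0 <- 1e-8
  # I2(2 k0) / I0(k0)^2 with the exp(2 k0) factors cancelling exactly;
  # asymptotically sqrt(pi * k0) once the Bessel ratios underflow
  ratio <- if (kappa0 > 1e5) sqrt(pi * kappa0)
           else besselI(2 * kappa0, 2, expon.scaled = TRUE) /
                besselI(kappa0, 0, expon.scaled = TRUE)^2
  kap <- (3 * n_eff * kappa0^2 * ratio / (4 * sqrt(pi)))^(2 / 5)
  min(max(kap, 1e-6), 1e6)
}

invert_vm_A <- function(rbar) {
  if (rbar <= 0) return(0)
  lo <- 1e-10; hi <- 1
  while (vm_A(hi) < rbar && hi < 1e9) hi <- hi * 2
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (vm_A(mid) < rbar) lo <- mid else hi <- mid
    if (hi - lo < 1e-8 * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Von Mises kernel
#'
#' \code{exp(kappa * cos(theta)) / (2 pi I0(kappa))}, the circular analogue of
#' the Gaussian kernel; integrates to 1 over the circle.
#'
#' @param theta angle(s) in radians.
#' @param kappa concentration.
#' @return kernel values.
#' @export
vonmises_kernel <- function(theta, kappa) {
  # scaled form is stable for large kappa
  exp(kappa * (cos(theta) - 1)) / (2 * pi * i0_scaled(kappa))
}

# Gaussian kernel on [0, 1] with reflection at both boundaries, so kernel
# mass does not leak outside the support (peripheral events sit at r_norm ~ 1)
gauss_reflect <- function(x, center, sigma) {
  stats::dnorm(x, center, sigma) + stats::dnorm(x, -center, sigma) +
    stats::dnorm(x, 2 - center, sigma)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Bandwidth parameter bundle
#'
#' Fixes the three smoothing parameters instead of estimating them from the
#' data; useful for equivariance checks and for comparing conditions under a
#' common smoothing.
#'
#' @param sigma_r,sigma_z Gaussian bandwidths for the radial and depth axes.
#' @param kappa von Mises concentration for the angular axis.
#' @return an object of class \code{bandwidth_params}.
#' @export
bandwidth_params <- function(sigma_r = NULL, sigma_z = NULL, kappa = NULL) {
  if (!is.null(sigma_r)) stopifnot(sigma_r > 0)
  if (!is.null(sigma_z)) stopifnot(sigma_z > 0)
  if (!is.null(kappa)) stopifnot(kappa > 0, kappa <= 1e6)
  structure(list(sigma_r = sigma_r, sigma_z = sigma_z, kappa = kappa),
            class = "bandwidth_params")
}

# internal constructor
density1d <- function(support, grid, values, histogram, bandwidth, n) {
  structure(list(support = support, grid = grid, values = values,
                 histogram = histogram, bandwidth = bandwidth, n = n),
            class = "density1d")
}

#' @export
print.density1d <- function(x, ...) {
  cat("<density1d> ", x$support, " support, K = ", length(x$grid),
      ", n = ", x$n, ", bandwidth = ", signif(x$bandwidth, 4), "\n", sep = "")
  invisible(x)
}

#' Plot a 1D event density with its histogram
#'
#' Histogram bars with the smoothed density overlaid, the standard way of
#' presenting per-axis event distributions.
#'
#' @param x a \code{density1d}.
#' @param ... passed to \code{plot}.
#' @export
plot.density1d <- function(x, ...) {
  h <- x$histogram
  graphics::plot(NA, xlim = range(x$grid), ylim = c(0, max(x$values, h$density)),
                 xlab = x$support, ylab = "density", ...)
  graphics::rect(h$breaks[-length(h$breaks)], 0, h$breaks[-1], h$density,
                 col = "grey85", border = "grey60")
  graphics::lines(x$grid, x$values, lwd = 2, col = "steelblue")
  invisible(x)
}

#' Weighted shape-normalized event density along one cylindrical axis
#'
#' Kernel density estimate of the radial (\code{r_norm} on [0, 1]), angular
#' (\code{theta} on [0, 2 pi)) or depth (\code{z_norm} on [0, 1]) event
#' distribution.  Each event contributes with weight \code{w * d_theta}
#' (radius, angle) or \code{w * d_z} (depth): the boundary distances act as
#' multiplicative weights so that, combined with the normalized coordinates,
#' the estimate is independent of cell shape and size.  Linear axes use a
#' Gaussian kernel reflected at both boundaries; the angular axis uses a von
#' Mises kernel.  Bandwidths default to the weighted Silverman rule
#' (\code{\link{silverman_bandwidth}}) and Taylor's circular rule
#' (\code{\link{vonmises_concentration}}).  The returned grid values are
#' renormalized to integrate to exactly 1 (trapezoid rule) so that
#' distribution distances are well-defined.
#'
#' @param S a \code{\link{to_cylindrical}} event set.
#' @param axis \code{"radius"}, \code{"angle"} or \code{"depth"}.
#' @param K number of grid points (default 100 linear, 360 circular).
#' @param bins number of histogram bins (default 20 linear, 36 circular).
#' @param params optional \code{\link{bandwidth_params}} overriding the
#'   estimated bandwidths.
#' @return a \code{density1d} with the evaluation grid, density values, the
#'   weighted histogram it smooths, and the bandwidth used.
#' @export
weighted_density <- function(S, axis = c("radius", "angle", "depth"),
                             K = NULL, bins = NULL, params = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(S, "cylindrical_events"), nrow(S) >= 1)
  if (sum(S$w) <= 0) stop("all event weights are zero")
  circular <- axis == "angle"
  if (is.null(K)) K <- if (circular) 360L else 100L
  if (is.null(bins)) bins <- if (circular) 36L else 20L
  samples <- switch(axis, radius = S$r_norm, angle = S$theta, depth = S$z_norm)
  wts <- S$w * switch(axis, radius = S$d_theta, angle = S$d_theta,
                      depth = S$d_z)
  if (circular) {
    grid <- seq(0, 2 * pi, length.out = K + 1)[seq_len(K)]
    kappa <- if (!is.null(params) && !is.null(params$kappa)) params$kappa
             else vonmises_concentration(samples, wts)
    vals <- as.vector(vonmises_kernel(outer(grid, samples, "-"), kappa) %*% wts)
    dgrid <- 2 * pi / K
    vals <- vals / (sum(vals) * dgrid)     # periodic rectangle rule
    bw <- kappa
    brk <- seq(0, 2 * pi, length.out = bins + 1)
  } else {
    grid <- seq(0, 1, length.out = K)
    sig0 <- if (length(samples) >= 2)
      tryCatch(silverman_bandwidth(samples, wts, 1),
               warning = function(w) 1e-3)
      else 0.05
    sig <- if (!is.null(params)) {
      ov <- if (axis == "radius") params$sigma_r else params$sigma_z
      if (is.null(ov)) sig0 else ov
    } else sig0
    vals <- as.vector(outer(grid, samples,
                            function(g, s) gauss_reflect(g, s, sig)) %*% wts)
    tot <- trapz(grid, vals)
    if (tot <= 0) stop("degenerate density (zero mass on the grid)")
    vals <- vals / tot
    bw <- sig
    brk <- seq(0, 1, length.out = bins + 1)
  }
  # weighted histogram over the same support (for display and as the
  # bandwidth-to-zero limit of the estimator)
  bi <- pmin(findInterval(samples, brk, rightmost.closed = TRUE), bins)
  hw <- vapply(seq_len(bins), function(b) sum(wts[bi == b]), numeric(1))
  hdens <- hw / (sum(hw) * diff(brk))
  density1d(support = if (circular) "circular" else "linear",
            grid = grid, values = vals,
            histogram = list(breaks = brk, mids = (brk[-1] + brk[-length(brk)]) / 2,
                             weight = hw, density = hdens),
            bandwidth = bw, n = nrow(S))
}

# linear re-interpolation of a density onto a K-point grid (comparisons need
# a common grid); circular densities wrap
resample_density <- function(d, K) {
  if (length(d$grid) == K) return(d)
  if (d$support == "circular") {
    grid <- seq(0, 2 * pi, length.out = K + 1)[seq_len(K)]
    gx <- c(d$grid, d$grid[1] + 2 * pi)
    gy <- c(d$values, d$values[1])
  } else {
    grid <- seq(0, 1, length.out = K)
    gx <- d$grid; gy <- d$values
  }
  vals <- stats::approx(gx, gy, xout = grid, rule = 2)$y
  d$grid <- grid
  d$values <- vals
  d
}
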