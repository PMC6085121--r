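# Shared fixtures and independent oracles, all built in code.

# --- transport oracles -------------------------------------------------------

# Minimum-cost transport between two integer-mass histograms on a line:
# expand each histogram into unit masses at bin positions and match them in
# sorted order (the optimal coupling in 1D for convex ground costs).
# Independent of the cumulative-difference formula under test.
emd_unit_mass_oracle <- function(c1, c2) {
  stopifnot(sum(c1) == sum(c2))
  u1 <- rep(seq_along(c1), c1)
  u2 <- rep(seq_along(c2), c2)
  sum(abs(sort(u1) - sort(u2))) / sum(c1)
}

# Circular transport: unit masses matched in sorted order under every cyclic
# offset of one side, with wrap-around ground distance; minimum over offsets.
cemd_unit_mass_oracle <- function(c1, c2) {
  K <- length(c1)
  stopifnot(sum(c1) == sum(c2))
  u1 <- sort(rep(seq_along(c1), c1))
  u2 <- sort(rep(seq_along(c2), c2))
  M <- length(u1)
  best <- Inf
  for (off in 0:(M - 1)) {
    v2 <- u2[((seq_len(M) - 1 + off) %% M) + 1]
    dd <- abs(u1 - v2)
    cost <- sum(pmin(dd, K - dd))
    best <- min(best, cost)
  }
  best / M
}

# Literal wrapped-cumulative enumeration of the circular EMD: for each start
# bin k build Q_k exactly as defined (cumulate from k, wrap past K) and take
# the minimal L1 difference.
cemd_literal_oracle <- function(p1, p2) {
  K <- length(p1)
  p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
  Q <- function(f, k) {
    vapply(seq_len(K), function(i) {
      if (i >= k) sum(f[k:i])
      else sum(f[k:K]) + sum(f[1:i])
    }, numeric(1))
  }
  min(vapply(seq_len(K), function(k)
    sum(abs(Q(p1, k) - Q(p2, k))), numeric(1)))
}

# Exact one-sided signed-rank p value by enumerating all 2^n sign patterns
# of the absolute-value ranks (no ties assumed).
signed_rank_enum_p <- function(deltas) {
  deltas <- deltas[deltas != 0]
  n <- length(deltas)
  rk <- rank(abs(deltas))
  W <- sum(rk[deltas > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% rk)
  mean(Wnull >= W)
}

# --- synthetic helpers -------------------------------------------------------

# cylindrical event set built directly (unit boundary distances), for tests
# of the density layer that do not involve a mask
bare_events <- function(r_norm = NULL, theta = NULL, z_norm = NULL, w = 1,
                        d_theta = 1, d_z = 1) {
  n <- max(length(r_norm), length(theta), length(z_norm))
  if (is.null(r_norm)) r_norm <- rep(0.5, n)
  if (is.null(theta)) theta <- rep(0, n)
  if (is.null(z_norm)) z_norm <- rep(0.5, n)
  structure(data.frame(r = r_norm, theta = theta, z = z_norm,
                       w = rep_len(w, n), d_theta = rep_len(d_theta, n),
                       d_z = rep_len(d_z, n), r_norm = r_norm,
                       z_norm = z_norm),
            class = c("cylindrical_events", "data.frame"))
}

# angular density of n von Mises draws through the package pipeline
angle_density_from_draws <- function(theta, K = 360) {
  weighted_density(bare_events(theta = theta,
                               r_norm = rep(0.5, length(theta))),
                   "angle", K = K)
}

# planted tracks plus jittered copies and per-method spurious tracks, the
# ground-truth fixture for the consensus filter
consensus_fixture <- function(n_planted = 10, n_spurious = 3, jitter = 0.3,
                              len = 5, seed = 42) {
  set.seed(seed)
  planted <- lapply(seq_len(n_planted), function(i) {
    x0 <- runif(1, 20, 80); y0 <- runif(1, 20, 80)
    ang <- runif(1, 0, 2 * pi)
    trajectory(t = 0:(len - 1),
               x = x0 + (0:(len - 1)) * cos(ang),
               y = y0 + (0:(len - 1)) * sin(ang),
               id = sprintf("planted%02d", i))
  })
  jittered <- function(tag) {
    lapply(planted, function(tr)
      trajectory(tr$t, tr$x + runif(len, -jitter, jitter),
                 tr$y + runif(len, -jitter, jitter),
                 id = paste0(traj_id_(tr), "_", tag)))
  }
  spurious <- function(tag) {
    lapply(seq_len(n_spurious), function(i)
      trajectory(0:(len - 1), runif(len, 100, 200), runif(len, 100, 200),
                 id = sprintf("spur_%s_%d", tag, i)))
  }
  list(
    truth = vapply(planted, traj_id_, character(1)),
    methods = list(
      m1 = c(jittered("m1"), spurious("m1")),
      m2 = c(jittered("m2"), spurious("m2")),
      m3 = c(jittered("m3"), spurious("m3"))))
}

traj_id_ <- function(tr) attr(tr, "id")
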