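test_that("weighted Silverman rule reduces to the textbook rule at unit weights", {
  set.seed(1)
  x <- rnorm(1000)
  # closed form on the empirical moments, cross-checked against bw.nrd0 (the
  # quantile interpolation conventions differ at the 4th decimal)
  expect_equal(silverman_bandwidth(x), bw.nrd0(x), tolerance = 1e-3)
  expect_lt(abs(silverman_bandwidth(x) - 0.2256), 0.03)
  # weight-scale invariance
  expect_equal(silverman_bandwidth(x, rep(2, 1000)),
               silverman_bandwidth(x, rep(7, 1000)), tolerance = 1e-12)
  # degenerate spread falls back to the floor with a warning
  expect_warning(bw <- silverman_bandwidth(rep(1, 10)), "floor")
  expect_equal(bw, 1e-3)
  expect_error(silverman_bandwidth(1), "2 samples")
})

test_that("bandwidth follows the n^(-1/5) effective-sample-size scaling", {
  set.seed(2)
  x <- rnorm(200)
  # replicating every sample 32-fold leaves the moments unchanged and
  # multiplies the effective sample size exactly
  expect_equal(silverman_bandwidth(rep(x, 32)) / silverman_bandwidth(x),
               32^(-1 / 5), tolerance = 1e-9)
})

test_that("von Mises concentration rule recovers sensible smoothing", {
  # uniform angles: near-zero resultant, tiny concentration
  expect_lt(vonmises_concentration(seq(0, 2 * pi, length.out = 201)[-201]), 1)
  # coincident angles: capped with a warning
  expect_warning(k <- vonmises_concentration(rep(1.3, 10)), "cap")
  expect_equal(k, 1e6)
  # Monte-Carlo oracle for the plug-in rule: on von Mises(pi, 4) draws the
  # selected concentration must beat clearly over- and under-smoothed fixed
  # concentrations in integrated squared error against the true density
  grid <- seq(0, 2 * pi, length.out = 361)[-361]
  truth <- vonmises_kernel(grid - pi, 4)
  for (seed in 3:5) {
    set.seed(seed)
    th <- rvonmises(500, pi, 4)
    rbar <- sqrt(sum(cos(th))^2 + sum(sin(th))^2) / 500
    kappa0 <- celldistr:::invert_vm_A(rbar)
    expect_gt(kappa0, 3); expect_lt(kappa0, 5.5)
    ise <- function(kap) {
      d <- weighted_density(bare_events(theta = th), "angle",
                            params = bandwidth_params(kappa = kap))
      sum((d$values - truth)^2) * 2 * pi / 360
    }
    k_hat <- vonmises_concentration(th)
    expect_lt(ise(k_hat), ise(0.5))
    expect_lt(ise(k_hat), ise(300))
  }
})

test_that("densities integrate to one on every axis", {
  set.seed(4)
  S <- bare_events(r_norm = runif(200), theta = runif(200, 0, 2 * pi),
                   z_norm = rbeta(200, 2, 3), w = rlnorm(200),
                   d_theta = runif(200, 10, 30), d_z = runif(200, 5, 15))
  for (ax in c("radius", "angle", "depth")) {
    d <- weighted_density(S, ax)
    integral <- if (d$support == "circular") sum(d$values) * 2 * pi / length(d$grid)
                else celldistr:::trapz(d$grid, d$values)
    expect_equal(integral, 1, tolerance = 1e-6)
    expect_true(all(d$values >= 0))
  }
})

test_that("weights: global rescaling is absorbed and zero weights are inert", {
  set.seed(5)
  S <- bare_events(r_norm = runif(100), theta = runif(100, 0, 2 * pi),
                   z_norm = runif(100), w = runif(100, 0.5, 2),
                   d_theta = runif(100, 10, 30), d_z = runif(100, 5, 15))
  S2 <- S; S2$w <- S2$w * 37.5
  S3 <- rbind(S, transform(S, w = 0))
  class(S3) <- class(S)
  for (ax in c("radius", "angle", "depth")) {
    d1 <- weighted_density(S, ax)
    expect_lt(max(abs(d1$values - weighted_density(S2, ax)$values)), 1e-12)
    expect_lt(max(abs(d1$values - weighted_density(S3, ax)$values)), 1e-12)
  }
  S0 <- S; S0$w <- 0
  expect_error(weighted_density(S0, "radius"), "zero")
})

test_that("a single kernel is returned for a single event", {
  S1 <- bare_events(r_norm = 0.4, theta = 2.1, z_norm = 0.5)
  d <- weighted_density(S1, "angle", params = bandwidth_params(kappa = 2))
  ref <- vonmises_kernel(d$grid - 2.1, 2)
  expect_lt(max(abs(d$values - ref)), 1e-3)
  integral <- sum(d$values) * 2 * pi / length(d$grid)
  expect_equal(integral, 1, tolerance = 1e-6)
})

test_that("angular density is shift-equivariant at fixed concentration", {
  set.seed(6)
  th <- runif(300, 0, 2 * pi)
  K <- 360
  shift_bins <- 45
  delta <- 2 * pi * shift_bins / K
  d1 <- weighted_density(bare_events(theta = th), "angle", K = K,
                         params = bandwidth_params(kappa = 8))
  d2 <- weighted_density(bare_events(theta = (th + delta) %% (2 * pi)),
                         "angle", K = K, params = bandwidth_params(kappa = 8))
  shifted <- d2$values[((seq_len(K) - 1 + shift_bins) %% K) + 1]
  expect_lt(max(abs(d1$values - shifted)), 1e-6)
})

test_that("with vanishing bandwidth the density converges to its histogram", {
  set.seed(7)
  S <- bare_events(r_norm = rbeta(500, 2, 2), theta = runif(500, 0, 2 * pi),
                   z_norm = runif(500))
  # fine grid so that near-delta kernels are resolved by the integration
  d <- weighted_density(S, "radius", K = 4001, bins = 20,
                        params = bandwidth_params(sigma_r = 1e-3))
  # bin-integrated density mass vs histogram mass, L1 over the 20 bins
  brk <- d$histogram$breaks
  mass_d <- vapply(seq_len(20), function(b) {
    sel <- d$grid >= brk[b] & d$grid <= brk[b + 1]
    celldistr:::trapz(d$grid[sel], d$values[sel])
  }, numeric(1))
  mass_h <- d$histogram$weight / sum(d$histogram$weight)
  expect_lt(sum(abs(mass_d - mass_h)), 0.05)
})

test_that("shape normalization: one law sampled into a small and a large disk agrees", {
  small <- make_cell_mask("disk", 18, margin = 4)
  large <- make_cell_mask("disk", 45, margin = 4)
  m <- event_model(1500, radial = "beta", radial_shape = c(2, 2), seed = 21)
  ds <- lapply(list(small, large), function(cell) {
    E <- sample_events(cell, m)
    weighted_density(to_cylindrical(E, default_frame(cell), cell), "radius")
  })
  expect_lt(emd(ds[[1]], ds[[2]]), 3)   # K = 100 bins; EMD ~ sampling noise
})

test_that("resampling a density preserves shape and wraps circular supports", {
  set.seed(8)
  d <- angle_density_from_draws(rvonmises(300, 1, 3), K = 360)
  d2 <- celldistr:::resample_density(d, 180)
  expect_length(d2$values, 180)
  expect_equal(d2$values[1], d$values[1], tolerance = 1e-9)
  expect_equal(sum(d2$values) * 2 * pi / 180, 1, tolerance = 5e-3)
})
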