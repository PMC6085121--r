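test_that("gated distance matches hand-worked values and its bounds", {
  a <- trajectory(0:2, c(0, 1, 2), c(0, 0, 0))
  b <- trajectory(0:2, c(0, 1, 2), c(0, 3, 0))
  expect_equal(gated_distance(a, a, 2), 0)
  expect_equal(gated_distance(a, b, 2), 2)       # 0 + min(3, 2) + 0
  far <- trajectory(0:2, c(100, 101, 102), c(100, 100, 100))
  expect_equal(gated_distance(a, far, 2), 3 * 2) # saturation on T + 1 frames
  # disjoint frame supports contribute the gate per frame
  c1 <- trajectory(0:1, c(0, 1), c(0, 0))
  c2 <- trajectory(5:6, c(0, 1), c(0, 0))
  expect_equal(gated_distance(c1, c2, 3), 4 * 3)
  # symmetry and bounds on random pairs
  set.seed(9)
  for (i in 1:20) {
    t1 <- trajectory(0:5, runif(6, 0, 10), runif(6, 0, 10))
    t2 <- trajectory(2:8, runif(7, 0, 10), runif(7, 0, 10))
    d12 <- gated_distance(t1, t2, 1.5)
    expect_equal(d12, gated_distance(t2, t1, 1.5))
    expect_gte(d12, 0)
    expect_lte(d12, length(union(t1$t, t2$t)) * 1.5)
  }
})

test_that("consensus filter keeps supported tracks and drops unsupported ones", {
  tr <- trajectory(0:3, 1:4, rep(2, 4), id = "same")
  kept <- consensus_filter(list(a = list(tr), b = list(tr), c = list(tr)))
  expect_length(kept, 1)
  lone <- trajectory(0:3, seq(50, 80, 10), rep(50, 4), id = "lone")
  kept2 <- consensus_filter(list(a = list(lone), b = list(tr), c = list(tr)))
  expect_length(kept2, 0)
  expect_error(consensus_filter(list(a = list(tr))), "2 track sets")
})

test_that("consensus filter recovers exactly the planted tracks", {
  fx <- consensus_fixture()
  kept <- consensus_filter(fx$methods)
  ids <- vapply(kept, function(tr) attr(tr, "id"), character(1))
  expect_length(kept, 10)
  expect_true(all(grepl("^planted", ids)))
})

test_that("raising the consensus threshold never shrinks the output", {
  fx <- consensus_fixture(jitter = 0.6, seed = 13)
  sizes <- vapply(c(0.5, 1, 2, 4, 8), function(th)
    length(consensus_filter(fx$methods, threshold = th)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  # output is always a subset of the reference set
  kept <- consensus_filter(fx$methods, threshold = 4)
  ref_ids <- vapply(fx$methods[[1]], function(tr) attr(tr, "id"), character(1))
  ids <- vapply(kept, function(tr) attr(tr, "id"), character(1))
  expect_true(all(ids %in% ref_ids))
})

test_that("trajectory features match closed forms", {
  straight <- trajectory(0:3, c(0, 1, 2, 3), rep(0, 4))
  expect_equal(confinement_ratio(straight), 1)
  loop <- trajectory(0:4, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(confinement_ratio(loop), 0)
  half <- trajectory(0:2, c(0, 1, 1), c(0, 0, 1))
  expect_equal(confinement_ratio(half), sqrt(2) / 2, tolerance = 1e-9)
  expect_warning(r <- confinement_ratio(trajectory(0:2, rep(1, 3), rep(1, 3))),
                 "stationary")
  expect_equal(r, 1)
  # path length applies voxel sizes; lifetime applies dt
  tr <- trajectory(c(0, 4), c(0, 3), c(0, 4), dt = 0.5)
  expect_equal(total_path_length(tr), 5)
  expect_equal(total_path_length(tr, c(2, 2, 2)), 10)
  expect_equal(lifetime(tr), 2)
  # bounds on random walks
  set.seed(10)
  for (i in 1:20) {
    tr <- trajectory(0:10, cumsum(rnorm(11)), cumsum(rnorm(11)))
    cr <- confinement_ratio(tr)
    expect_gte(cr, 0); expect_lte(cr, 1)
  }
})

test_that("direction classification follows the net normalized radius", {
  disk <- make_cell_mask("disk", 25, margin = 5)
  ctr <- (disk$dim[1] - 1) / 2
  fr <- reference_frame(c(ctr, ctr, 0))
  outw <- trajectory(0:2, ctr + c(2, 8, 14), rep(ctr, 3))
  inw <- trajectory(0:2, ctr + c(14, 8, 2), rep(ctr, 3))
  expect_equal(as.character(classify_direction(outw, fr, disk)),
               "toward_periphery")
  expect_equal(as.character(classify_direction(inw, fr, disk)),
               "toward_center")
  # tangential arc between symmetry-equivalent angles (identical boundary
  # distance, hence identical r_norm): tie branch, flagged
  th <- seq(0, pi / 2, length.out = 5)
  arc <- trajectory(0:4, ctr + 10 * cos(th), ctr + 10 * sin(th))
  cls <- classify_direction(arc, fr, disk)
  expect_equal(as.character(cls), "toward_center")
  expect_true(attr(cls, "tie"))
})

test_that("feature histogram averages per bin and keeps empty bins missing", {
  disk <- make_cell_mask("disk", 25, margin = 5)
  ctr <- (disk$dim[1] - 1) / 2
  fr <- reference_frame(c(ctr, ctr, 0))
  # two 2-point tracks whose median (first) point sits at r_norm ~ 0.42 and
  # path lengths 2 and 4: one nonempty bin with mean 3
  mk <- function(len) trajectory(0:1, ctr + c(10.5, 10.5 + len), c(ctr, ctr))
  fh <- feature_histogram(list(mk(2), mk(4)), "total_path_length", "radius",
                          B = 10, frame = fr, cell = disk)
  expect_equal(sum(fh$counts), 2)
  nb <- which(fh$counts > 0)
  expect_length(nb, 1)
  expect_equal(fh$mean_feature[nb], 3)
  expect_true(all(is.na(fh$mean_feature[-nb])))
  # single track: its bin equals its feature exactly
  fh1 <- feature_histogram(list(mk(2)), "total_path_length", "radius",
                           B = 10, frame = fr, cell = disk)
  expect_equal(fh1$mean_feature[which(fh1$counts > 0)], 2)
})

test_that("a planted radial feature gradient is recovered bin by bin", {
  disk <- make_cell_mask("disk", 40, margin = 5)
  ctr <- (disk$dim[1] - 1) / 2
  fr <- reference_frame(c(ctr, ctr, 0))
  set.seed(12)
  # 2-point tracks whose median point sits at radius t * d_theta and whose
  # path length equals t, so the binned feature field is m(r_norm) = r_norm
  tracks <- lapply(1:200, function(i) {
    t0 <- runif(1, 0.05, 0.95)
    th <- runif(1, 0, 2 * pi)
    d <- boundary_distance_angular(disk, fr, th)
    x0 <- ctr + t0 * d * cos(th); y0 <- ctr + t0 * d * sin(th)
    trajectory(0:1, c(x0, x0 + t0 * cos(th + pi / 2)),
               c(y0, y0 + t0 * sin(th + pi / 2)))
  })
  fh <- feature_histogram(tracks, "total_path_length", "radius", B = 10,
                          frame = fr, cell = disk)
  nb <- which(fh$counts > 0)
  expect_true(all(abs(fh$mean_feature[nb] - fh$mids[nb]) < 0.05))
  # the smoothed profile increases over the sampled interior
  fd <- feature_density(fh)
  sel <- fd$grid >= 0.1 & fd$grid <= 0.9
  expect_true(all(diff(fd$values[sel]) > -1e-9))
})

test_that("feature density is flat for a constant field and skips empty bins", {
  disk <- make_cell_mask("disk", 30, margin = 5)
  ctr <- (disk$dim[1] - 1) / 2
  fr <- reference_frame(c(ctr, ctr, 0))
  set.seed(14)
  tracks <- lapply(1:100, function(i) {
    t0 <- runif(1, 0.05, 0.95); th <- runif(1, 0, 2 * pi)
    d <- boundary_distance_angular(disk, fr, th)
    x0 <- ctr + t0 * d * cos(th); y0 <- ctr + t0 * d * sin(th)
    trajectory(0:1, c(x0, x0 + 2), c(y0, y0))   # constant feature 2
  })
  fh <- feature_histogram(tracks, "total_path_length", "radius", B = 10,
                          frame = fr, cell = disk)
  fd <- feature_density(fh)
  expect_lt(max(fd$values) / min(fd$values), 1.01)
  # dropping an empty bin does not change the density
  fh2 <- fh
  empty <- which(fh2$counts == 0)
  if (length(empty) == 0) {   # force one
    fh2$counts[3] <- 0L; fh2$mean_feature[3] <- NA_real_
    fh_ref <- fh2
  } else fh_ref <- fh2
  d_with <- feature_density(fh_ref)
  expect_true(all(is.finite(d_with$values)))
  expect_error(feature_histogram(list(), "lifetime", "radius", B = 5,
                                 frame = fr, cell = disk))
})
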