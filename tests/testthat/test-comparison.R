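test_that("linear EMD matches trivial cases and the transport oracle", {
  f <- runif(10)
  expect_equal(emd(f, f), 0)
  K <- 12
  p1 <- c(1, rep(0, K - 1)); p2 <- c(rep(0, K - 1), 1)
  expect_equal(emd(p1, p2), K - 1)
  expect_error(emd(runif(5), runif(6)), "mismatch")
  set.seed(15)
  for (i in 1:50) {
    K <- sample(3:8, 1)
    c1 <- rmultinom(1, 40, runif(K))[, 1]
    c2 <- rmultinom(1, 40, runif(K))[, 1]
    expect_equal(emd(c1, c2), emd_unit_mass_oracle(c1, c2), tolerance = 1e-9)
  }
})

test_that("circular EMD matches brute-force enumeration and transport matching", {
  f <- runif(8)
  expect_equal(cemd(f, f), 0)
  # point masses two bins apart on an 8-bin circle, and diametrically opposed
  p <- function(k, K = 8) { v <- rep(0, K); v[k] <- 1; v }
  expect_equal(cemd(p(1), p(3)), 2)
  expect_equal(cemd(p(1), p(5)), 4)
  expect_equal(cemd(p(8), p(1)), 1)   # wrap-around shortcut
  set.seed(16)
  for (i in 1:50) {
    K <- sample(3:8, 1)
    c1 <- rmultinom(1, 36, runif(K))[, 1]
    c2 <- rmultinom(1, 36, runif(K))[, 1]
    expect_equal(cemd(c1, c2), cemd_literal_oracle(c1, c2), tolerance = 1e-9)
    expect_equal(cemd(c1, c2), cemd_unit_mass_oracle(c1, c2), tolerance = 1e-9)
    expect_lte(cemd(c1, c2), emd(c1, c2) + 1e-12)  # k = 1 term is the line EMD
  }
})

test_that("EMD and CEMD are metrics on the grid and CEMD is rotation invariant", {
  set.seed(17)
  rot <- function(v, j) v[((seq_along(v) - 1 - j) %% length(v)) + 1]
  for (i in 1:20) {
    K <- 24
    f1 <- runif(K); f2 <- runif(K); f3 <- runif(K)
    for (fun in list(emd, cemd)) {
      expect_equal(fun(f1, f2), fun(f2, f1), tolerance = 1e-12)
      expect_gte(fun(f1, f2), 0)
      expect_lte(fun(f1, f3), fun(f1, f2) + fun(f2, f3) + 1e-9)
    }
    expect_gt(emd(f1, f2), 0)   # distinct histograms separate
    for (j in c(1, 7, 13))
      expect_equal(cemd(rot(f1, j), rot(f2, j)), cemd(f1, f2),
                   tolerance = 1e-9)
  }
})

test_that("condition differences vanish under exchangeability and equal EMD(A,B) for separated conditions", {
  set.seed(18)
  base <- angle_density_from_draws(rvonmises(200, 1, 3))
  clones <- setNames(replicate(6, base, simplify = FALSE), paste0("e", 1:6))
  cd <- condition_difference(clones, rep(c("A", "B"), each = 3))
  expect_true(all(abs(cd$delta) < 1e-12))
  # two internally identical but mutually different conditions
  dA <- angle_density_from_draws(rvonmises(200, 0.5, 4))
  dB <- angle_density_from_draws(rvonmises(200, 0.5 + pi / 2, 4))
  dl <- list(a1 = dA, a2 = dA, a3 = dA, b1 = dB, b2 = dB, b3 = dB)
  cd2 <- condition_difference(dl, rep(c("A", "B"), each = 3))
  ref <- cemd(dA, dB)
  expect_equal(cd2$delta, rep(ref, 6), tolerance = 1e-9)
  expect_true(all(cd2$intra < 1e-12))
  # singleton conditions are named in the error
  expect_error(condition_difference(dl, c("A", "A", "A", "A", "A", "solo")),
               "solo")
})

test_that("the comparison pipeline is equivariant under experiment reordering", {
  set.seed(19)
  dl <- lapply(1:8, function(i)
    angle_density_from_draws(rvonmises(150, ifelse(i <= 4, 0, pi / 2), 3)))
  names(dl) <- paste0("e", 1:8)
  conds <- rep(c("A", "B"), each = 4)
  cd <- condition_difference(dl, conds)
  p <- wilcoxon_condition_test(cd$delta)
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  cd2 <- condition_difference(dl[perm], conds[perm])
  expect_equal(sort(cd2$delta), sort(cd$delta), tolerance = 1e-12)
  expect_equal(as.numeric(wilcoxon_condition_test(cd2$delta)),
               as.numeric(p), tolerance = 1e-12)
})

test_that("signed-rank p values agree with exact enumeration of the null", {
  # all-positive differences: the one-sided exact minimum 1 / 2^n
  p <- suppressWarnings(wilcoxon_condition_test(1:10 / 10 + 0.01))
  expect_equal(as.numeric(p), 1 / 2^10, tolerance = 1e-12)
  set.seed(20)
  for (i in 1:10) {
    d <- round(rnorm(8), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d))) || length(d) < 5) next
    expect_equal(as.numeric(suppressWarnings(wilcoxon_condition_test(d))),
                 signed_rank_enum_p(d), tolerance = 1e-12)
    # sign flip maps p to the complementary tail (plus the atom at W)
    p_pos <- signed_rank_enum_p(d)
    p_neg <- signed_rank_enum_p(-d)
    expect_gte(p_pos + p_neg, 1)       # the shared atom makes the sum >= 1
    expect_lt(abs(p_pos + p_neg - 1), 0.25)
  }
  # zeros are dropped before ranking
  d <- c(0.4, -0.2, 0.9, 0.7, -0.5, 0.31)
  expect_equal(as.numeric(suppressWarnings(wilcoxon_condition_test(c(d, 0, 0)))),
               as.numeric(suppressWarnings(wilcoxon_condition_test(d))),
               tolerance = 1e-12)
  expect_warning(pz <- wilcoxon_condition_test(rep(0, 6)), "zero")
  expect_equal(as.numeric(pz), 1)
  # symmetric differences sit near the center of the null
  set.seed(21)
  ps <- replicate(40, {
    d <- rnorm(9)
    as.numeric(suppressWarnings(wilcoxon_condition_test(d)))
  })
  expect_gt(mean(ps), 0.3); expect_lt(mean(ps), 0.7)
})

test_that("large-sample test switches to the corrected normal approximation", {
  set.seed(22)
  d <- rnorm(40, 0.4)
  p_pkg <- as.numeric(wilcoxon_condition_test(d))
  ref <- stats::wilcox.test(d[d != 0], alternative = "greater", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(p_pkg, ref, tolerance = 1e-12)
})

test_that("same-condition splits give null-like p values and flag heterogeneity", {
  set.seed(23)
  dl <- lapply(1:8, function(i) angle_density_from_draws(rvonmises(250, 1, 3)))
  ps <- same_condition_control(dl, n_splits = 40, seed = 5)
  expect_length(ps, 40)
  med <- unname(attr(ps, "quartiles")[2])
  expect_gt(med, 0.2); expect_lt(med, 0.8)
  # cloned replicates: every split yields all-zero differences, p = 1
  base <- dl[[1]]
  clones <- replicate(6, base, simplify = FALSE)
  psc <- same_condition_control(clones, n_splits = 10, seed = 5)
  expect_true(all(psc == 1))
  # hidden sub-populations push the p distribution down (diagnostic)
  mixed <- c(lapply(1:4, function(i) angle_density_from_draws(rvonmises(250, 1, 4))),
             lapply(1:4, function(i) angle_density_from_draws(rvonmises(250, 1 + pi, 4))))
  psm <- same_condition_control(mixed, n_splits = 40, seed = 5)
  expect_lt(median(psm), med)
  expect_error(same_condition_control(dl[1:3]), "at least 4")
})
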