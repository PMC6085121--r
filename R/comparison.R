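density_values <- function(f) {
  if (inherits(f, "density1d")) f$values else as.numeric(f)
}

#' Earth Mover's Distance between two densities on a line
#'
#' First-order Wasserstein distance between two 1D distributions sampled on
#' the same K-point grid: each is renormalized to total mass 1 over its bins
#' and the distance is the sum of absolute differences of the cumulative
#' distribution functions,
#' \deqn{EMD(f_1, f_2) = \sum_{i=1}^{K} |F_1(i) - F_2(i)|,}
#' which equals the minimum-cost transport with \code{|i - j|} ground cost.
#' The value scales with K, so distances are only comparable at a fixed,
#' study-wide grid size.
#'
#' @param f1,f2 \code{density1d} objects or numeric vectors on identical
#'   grids.
#' @return nonnegative distance (in bin units).
#' @export
emd <- function(f1, f2) {
  v1 <- density_values(f1); v2 <- density_values(f2)
  if (length(v1) != length(v2)) stop("grid mismatch: ", length(v1), " vs ",
                                     length(v2), " bins")
  p1 <- v1 / sum(v1); p2 <- v2 / sum(v2)
  sum(abs(cumsum(p1) - cumsum(p2)))
}

#' Circular Earth Mover's Distance between two densities on the circle
#'
#' For circular supports the cumulative distribution depends on where the
#' circle is cut.  The CEMD takes the minimum over all K possible start bins
#' \code{k} of the linear EMD computed with cumulative sums started at bin
#' \code{k} and wrapped around the circle:
#' \deqn{CEMD(f_1, f_2) = \min_k \sum_{i=1}^{K} |Q_k^1(i) - Q_k^2(i)|.}
#' Since both distributions are normalized to mass 1, the wrapped cumulative
#' difference satisfies \code{Q_k^1(i) - Q_k^2(i) = D(i) - D(k - 1)} with
#' \code{D = cumsum(p1 - p2)}, which is how the minimum is evaluated (ties
#' broken by the smallest \code{k}).  The result is invariant to a common
#' rotation of both inputs.
#'
#' @inheritParams emd
#' @return nonnegative distance (in bin units).
#' @export
cemd <- function(f1, f2) {
  v1 <- density_values(f1); v2 <- density_values(f2)
  if (length(v1) != length(v2)) stop("grid mismatch: ", length(v1), " vs ",
                                     length(v2), " bins")
  p1 <- v1 / sum(v1); p2 <- v2 / sum(v2)
  D <- cumsum(p1 - p2)
  offsets <- c(0, D[-length(D)])        # D(k - 1) for k = 1..K
  min(vapply(offsets, function(o) sum(abs(D - o)), numeric(1)))
}

#' Pairwise distance matrix between experiment densities
#'
#' @param densities list of \code{density1d} on a common support; densities
#'   are resampled to a common grid size first.
#' @param K common grid size (default: the maximum across inputs).
#' @return symmetric matrix with zero diagonal.
#' @export
density_distance_matrix <- function(densities, K = NULL) {
  n <- length(densities)
  stopifnot(n >= 2)
  supports <- vapply(densities, function(d) d$support, character(1))
  if (length(unique(supports)) != 1) stop("mixed supports in density list")
  circular <- supports[1] == "circular"
  if (is.null(K)) K <- max(vapply(densities, function(d) length(d$grid),
                                  integer(1)))
  densities <- lapply(densities, resample_density, K = K)
  dfun <- if (circular) cemd else emd
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    dm[i, j] <- dm[j, i] <- dfun(densities[[i]], densities[[j]])
  dimnames(dm) <- list(names(densities), names(densities))
  dm
}

#' Per-experiment condition differences
#'
#' For each experiment \code{e} the intra-condition distance is the mean
#' density distance to all other replicates of the same condition, and the
#' inter-condition distance the mean distance to all experiments of the other
#' condition(s).  The condition difference \code{delta = inter - intra} is
#' positive when the experiment resembles its own condition more than the
#' others; it is the replicate-aware statistic on which the one-sided
#' signed-rank test operates, avoiding any pooling of replicates.
#'
#' @param densities list of per-experiment \code{density1d} on one axis (all
#'   linear or all circular).
#' @param conditions condition label per experiment (>= 2 distinct labels,
#'   each with >= 2 experiments).
#' @param K common grid size passed to \code{\link{density_distance_matrix}}.
#' @return data.frame with columns \code{experiment, condition, intra,
#'   inter, delta}, plus the distance matrix as attribute
#'   \code{distance_matrix}.
#' @export
condition_difference <- function(densities, conditions, K = NULL) {
  n <- length(densities)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == n, n >= 2)
  tab <- table(conditions)
  if (length(tab) < 2) stop("need at least 2 conditions")
  if (any(tab < 2))
    stop("singleton condition(s): ",
         paste(names(tab)[tab < 2], collapse = ", "),
         " (each condition needs >= 2 replicates)")
  dm <- density_distance_matrix(densities, K = K)
  ids <- if (!is.null(names(densities))) names(densities)
         else sprintf("exp%02d", seq_len(n))
  intra <- inter <- numeric(n)
  for (e in seq_len(n)) {
    same <- conditions == conditions[e]
    same[e] <- FALSE
    intra[e] <- mean(dm[e, same])
    inter[e] <- mean(dm[e, !(conditions == conditions[e])])
  }
  structure(data.frame(experiment = ids, condition = conditions,
                       intra = intra, inter = inter, delta = inter - intra,
                       stringsAsFactors = FALSE),
            distance_matrix = dm)
}

#' One-sided signed-rank test on condition differences
#'
#' Wilcoxon signed-rank test of the null that the per-experiment condition
#' differences are symmetric about 0, against the one-sided alternative that
#' their median is positive (conditions truly different).  Zero differences
#' are dropped (the standard convention); the exact distribution is used for
#' n <= 25 without ties in the absolute values, the normal approximation with
#' continuity correction otherwise.  Below 5 experiments the exact p value is
#' still returned but flagged as low powered.
#'
#' @param deltas numeric vector of per-experiment condition differences.
#' @return the one-sided p value, with attributes \code{n} (nonzero
#'   differences used) and \code{statistic}.
#' @export
wilcoxon_condition_test <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  nz <- deltas[deltas != 0]
  if (length(nz) == 0) {
    warning("all condition differences are zero; p = 1")
    return(structure(1, n = 0L, statistic = 0))
  }
  if (length(nz) < 5)
    warning("fewer than 5 nonzero condition differences; test has low power")
  use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(stats::wilcox.test(nz, mu = 0,
                                            alternative = "greater",
                                            exact = use_exact,
                                            correct = TRUE))
  structure(unname(ht$p.value), n = length(nz),
            statistic = unname(ht$statistic))
}

#' Same-condition random-split control
#'
#' Negative control for the condition-comparison procedure: the replicates of
#' a single condition are split at random into two pseudo-conditions (the
#' larger half takes the extra experiment when the count is odd), the full
#' condition-difference plus signed-rank procedure is run on each split, and
#' the p values over all splits are returned.  For genuinely exchangeable
#' replicates their distribution should be roughly uniform; a median far from
#' 0.5 flags either an over-sensitive distance or hidden sub-populations.
#'
#' @param densities list of per-experiment \code{density1d} of one condition
#'   (>= 4 experiments).
#' @param n_splits number of random splits (default 100).
#' @param seed RNG seed for the splits.
#' @param K common grid size.
#' @return numeric vector of p values with attribute \code{quartiles}.
#' @export
same_condition_control <- function(densities, n_splits = 100, seed = 1,
                                   K = NULL) {
  n <- length(densities)
  if (n < 4) stop("need at least 4 experiments for a split control")
  half <- n %/% 2
  pvals <- numeric(n_splits)
  rs <- local({ set.seed(seed); replicate(n_splits, sample(n, half),
                                          simplify = FALSE) })
  for (s in seq_len(n_splits)) {
    lab <- rep("B", n)
    lab[rs[[s]]] <- "A"
    cd <- condition_difference(densities, lab, K = K)
    pvals[s] <- suppressWarnings(as.numeric(wilcoxon_condition_test(cd$delta)))
  }
  structure(pvals, quartiles = stats::quantile(pvals, c(0.25, 0.5, 0.75)))
}
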