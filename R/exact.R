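# Unconditional exact Z-pooled test for 2x2 tables.
#
# For a 2x2 table of independent binomials (x1 successes of n1 trials vs x2
# of n2) the Z-pooled statistic is the familiar two-sample proportion Z with
# pooled variance. The unconditional exact test treats only the row margins
# (n1, n2) as fixed: for every value of the common nuisance success
# probability pi it sums the probabilities of all outcomes at least as
# extreme as the observed one, and reports the supremum over pi. This is the
# Suissa-Shuster / Barnard-type test applied here to direction counts of
# cone vs rod phototransduction genes (upregulated in tadpoles vs
# juveniles).

.check_table <- function(x1, n1, x2, n2) {
  for (v in list(x1, n1, x2, n2)) stopifnot_scalar_number(v, "table entry")
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("need 0 <= x <= n in both groups", call. = FALSE)
  }
  invisible(NULL)
}

# Vectorized pooled-Z over outcome vectors y1, y2.
.z_pooled_vec <- function(y1, n1, y2, n2) {
  phat <- (y1 + y2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (y1 / n1 - y2 / n2) / se, 0)
  z
}

#' Pooled-variance Z statistic for a 2x2 table
#'
#' `Z = (x1/n1 - x2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (x1 + x2)/(n1 + n2)`. Defined as 0 when the pooled proportion is
#' 0 or 1.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return The Z statistic.
#' @examples
#' z_pooled(8, 10, 3, 10)  # 2.247
#' @export
z_pooled <- function(x1, n1, x2, n2) {
  .check_table(x1, n1, x2, n2)
  .z_pooled_vec(x1, n1, x2, n2)
}

# p(pi) for a fixed rejection region: sum of independent-binomial outcome
# probabilities over the region. `region` is a logical (n1+1) x (n2+1)
# matrix indexed by [y1+1, y2+1].
.region_prob <- function(pi, region, n1, n2) {
  vapply(pi, function(p) {
    sum(outer(stats::dbinom(0:n1, n1, p),
              stats::dbinom(0:n2, n2, p)) [region])
  }, 0)
}

# Supremum of the region probability over the nuisance proportion: coarse
# grid plus local refinement around the grid argmax.
.sup_nuisance <- function(region, n1, n2, grid_step) {
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  d1 <- outer(0:n1, grid, function(y, p) stats::dbinom(y, n1, p))
  d2 <- outer(0:n2, grid, function(y, p) stats::dbinom(y, n2, p))
  # p(pi_g) = sum_{(y1,y2) in region} d1[y1+1,g] d2[y2+1,g]
  pg <- rowSums(crossprod(d1, region) * t(d2))
  g <- which.max(pg)
  p_best <- pg[g]
  pi_best <- grid[g]
  interval <- c(max(1e-9, grid[g] - grid_step),
                min(1 - 1e-9, grid[g] + grid_step))
  opt <- stats::optimize(function(p) .region_prob(p, region, n1, n2),
                         interval, maximum = TRUE, tol = 1e-9)
  if (opt$objective > p_best) {
    p_best <- opt$objective
    pi_best <- opt$maximum
  }
  list(p = min(1, p_best), pi = pi_best)
}

.zpooled_region <- function(n1, n2, z_obs, alternative) {
  ys <- expand.grid(y1 = 0:n1, y2 = 0:n2)
  z <- .z_pooled_vec(ys$y1, n1, ys$y2, n2)
  tol <- 1e-12  # floating-point ties count as equally extreme
  inc <- switch(alternative,
                two.sided = abs(z) >= abs(z_obs) - tol,
                greater = z >= z_obs - tol,
                less = z <= z_obs + tol)
  matrix(inc, nrow = n1 + 1, ncol = n2 + 1)
}

#' Unconditional exact Z-pooled test
#'
#' Exact test for equality of two binomial proportions with fixed row
#' margins: outcomes at least as extreme as the observed table (by the
#' pooled Z statistic; two-sided uses `|Z| >= |z_obs|`) are summed under
#' independent binomials with a common success probability, and the p-value
#' is the supremum over that nuisance probability (grid search plus local
#' refinement).
#'
#' @param x1,n1,x2,n2 The 2x2 table: successes and trials per group.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (group 1 proportion vs group 2).
#' @param grid_step Nuisance grid resolution (default 0.001).
#' @return An object of class `"htest"` with the Z statistic, p-value, the
#'   two sample proportions, and `nuisance_argmax`, the maximizing nuisance
#'   proportion.
#' @examples
#' zpooled_test(8, 10, 3, 10)  # Z = 2.247, p = 0.041
#' @export
zpooled_test <- function(x1, n1, x2, n2,
                         alternative = c("two.sided", "greater", "less"),
                         grid_step = 1e-3) {
  .check_table(x1, n1, x2, n2)
  alternative <- match.arg(alternative)
  stopifnot_scalar_number(grid_step, "grid_step", 1e-6, 0.1)
  if ((n1 + 1) * (n2 + 1) > 1e6) {
    stop("table too large for outcome enumeration", call. = FALSE)
  }
  z_obs <- z_pooled(x1, n1, x2, n2)
  region <- .zpooled_region(n1, n2, z_obs, alternative)
  sup <- .sup_nuisance(region, n1, n2, grid_step)
  res <- list(
    statistic = c(z = z_obs),
    p.value = sup$p,
    estimate = c(`proportion 1` = x1 / n1, `proportion 2` = x2 / n2),
    alternative = alternative,
    method = "Unconditional exact test (Z-pooled, binomial model, fixed row margins)",
    data.name = sprintf("%d/%d successes vs %d/%d successes", x1, n1, x2, n2),
    nuisance_argmax = sup$pi
  )
  class(res) <- "htest"
  res
}

#' Monte-Carlo size / power of the Z-pooled exact test
#'
#' Draws `n_reps` tables from independent binomials and reports the
#' rejection frequency at level `alpha`. With `p1 == p2` this estimates the
#' type-I error (which an exact test keeps at or below `alpha` up to
#' Monte-Carlo error); otherwise it estimates power.
#'
#' @param n1,n2 Group sizes.
#' @param p1,p2 True success probabilities.
#' @param alpha Nominal level (default 0.05).
#' @param n_reps Number of simulated tables (>= 100).
#' @param seed RNG seed (the simulation is reproducible given the seed).
#' @param alternative Passed to the test.
#' @param grid_step Nuisance grid resolution for the test's p-values.
#' @return The rejection rate, with the per-outcome p-value matrix in
#'   `attr(, "pvalues")`.
#' @export
simulate_size_power <- function(n1, n2, p1, p2, alpha = 0.05,
                                n_reps = 1000L, seed = 1L,
                                alternative = "two.sided",
                                grid_step = 1e-3) {
  stopifnot_scalar_number(p1, "p1", 0, 1)
  stopifnot_scalar_number(p2, "p2", 0, 1)
  stopifnot_scalar_number(alpha, "alpha", 0, 1)
  if (n_reps < 100L) stop("'n_reps' must be >= 100", call. = FALSE)
  pv <- exact_pvalue_matrix(n1, n2, alternative, grid_step)
  rej <- pv <= alpha
  rate <- with_seed(seed, {
    y1 <- stats::rbinom(n_reps, n1, p1)
    y2 <- stats::rbinom(n_reps, n2, p2)
    mean(rej[cbind(y1 + 1L, y2 + 1L)])
  })
  attr(rate, "pvalues") <- pv
  rate
}

#' Exact p-values for every outcome of a 2x2 design
#'
#' Convenience for size/power work: the Z-pooled exact p-value of each
#' possible table `(y1, y2)` with margins `n1`, `n2`. Outcomes sharing the
#' same rejection region (tied |Z|) are computed once.
#'
#' @inheritParams simulate_size_power
#' @param alternative Test sidedness.
#' @return An `(n1+1) x (n2+1)` matrix indexed by `[y1+1, y2+1]`.
#' @export
exact_pvalue_matrix <- function(n1, n2, alternative = "two.sided",
                                grid_step = 1e-3) {
  ys <- expand.grid(y1 = 0:n1, y2 = 0:n2)
  z <- .z_pooled_vec(ys$y1, n1, ys$y2, n2)
  key <- switch(alternative, two.sided = abs(z), greater = z, less = z)
  pv <- numeric(length(z))
  for (k in unique(key)) {
    i <- which(key == k)[1]
    region <- .zpooled_region(n1, n2, z[i], alternative)
    pv[key == k] <- .sup_nuisance(region, n1, n2, grid_step)$p
  }
  matrix(pv, nrow = n1 + 1, ncol = n2 + 1)
}
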