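# small random design shared across blocks
make_design <- function(n = 10, S = 40, K = 1, seed = 71, p_cov = 0) {
  set.seed(seed)
  grms <- lapply(seq_len(K), function(k) {
    Z <- standardize(matrix(rbinom(n * S, 1, 0.5), n, S), rep(0.5, S),
                     "haploid", ids = as.character(seq_len(n)))
    compute_grm(Z, c("M1", "M2", "P1")[k])
  })
  X <- if (p_cov > 0) matrix(rnorm(n * p_cov), n) else NULL
  y <- rnorm(n)
  reml_design(y, grms, X = X)
}

test_that("restricted likelihood reduces to the OLS closed form without genetics", {
  d <- make_design(n = 25, K = 1, p_cov = 2, seed = 73)
  s2 <- 1.7
  fit <- lm.fit(d$X, d$y)
  rss <- sum(fit$residuals^2)
  n <- d$n; p <- ncol(d$X)
  closed <- -0.5 * ((n - p) * log(s2) + determinant(crossprod(d$X))$modulus[1] +
                    rss / s2)
  expect_equal(reml_loglik(d, c(0, s2)), closed, tolerance = 1e-10)
})

test_that("restricted likelihood is invariant to joint relabeling", {
  d <- make_design(n = 12, K = 2, p_cov = 1, seed = 79)
  s2 <- c(0.4, 0.3, 0.8)
  ll <- reml_loglik(d, s2)
  perm <- sample(d$n)
  d2 <- d
  d2$y <- d$y[perm]; d2$X <- d$X[perm, , drop = FALSE]
  d2$grms <- lapply(d$grms, function(g) {
    g$A <- g$A[perm, perm]; g$ids <- g$ids[perm]; g
  })
  expect_equal(reml_loglik(d2, s2), ll, tolerance = 1e-9)
})

test_that("restricted likelihood matches an independently assembled formula", {
  d <- make_design(n = 10, K = 2, p_cov = 1, seed = 83)
  s2 <- c(0.5, 0.2, 0.9)
  # literal dense assembly, using generic solve()/determinant() only
  V <- s2[1] * d$grms[[1]]$A + s2[2] * d$grms[[2]]$A + s2[3] * diag(d$n)
  Vi <- solve(V)
  XtViX <- t(d$X) %*% Vi %*% d$X
  P <- Vi - Vi %*% d$X %*% solve(XtViX) %*% t(d$X) %*% Vi
  literal <- -0.5 * (determinant(V)$modulus[1] +
                     determinant(XtViX)$modulus[1] +
                     drop(t(d$y) %*% P %*% d$y))
  expect_equal(reml_loglik(d, s2), literal, tolerance = 1e-8)

  # a singular V is refused with the offending eigenvalue
  expect_error(reml_loglik(d, c(-5, 0, 0)), "positive definite")
})

test_that("the AI-REML optimum agrees with a likelihood grid search", {
  set.seed(89)
  n <- 50; S <- 200
  Z <- standardize(matrix(rbinom(n * S, 1, 0.4), n, S), rep(0.4, S),
                   "haploid", ids = as.character(1:n))
  g <- compute_grm(Z, "M1")
  u <- drop(Z$Z %*% rnorm(S, sd = sqrt(0.6 / S)))
  y <- u + rnorm(n, sd = sqrt(0.4))
  d <- reml_design(y, list(g))
  fit <- fit_reml(d)
  expect_true(fit$converged)

  dz <- d; dz$y <- (y - mean(y)) / sd(y)  # fit standardizes internally
  grid <- seq(0.01, 1.2, length.out = 60)
  best <- -Inf; arg <- c(NA, NA)
  for (a in grid) for (b in grid) {
    ll <- tryCatch(reml_loglik(dz, c(a, b)), error = function(e) -Inf)
    if (ll > best) { best <- ll; arg <- c(a, b) }
  }
  res <- grid[2] - grid[1]
  expect_lt(max(abs(fit$sigma2[1:2] - arg)), res + 1e-9)
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("a phenotype independent of the GRM gives a near-zero component", {
  set.seed(97)
  n <- 80; S <- 500
  Z <- standardize(matrix(rbinom(n * S, 1, 0.5), n, S), rep(0.5, S),
                   "haploid", ids = as.character(1:n))
  d <- reml_design(rnorm(n), list(compute_grm(Z, "M1")), precompute = TRUE)
  ests <- vapply(1:60, function(r) {
    fit_reml(set_phenotype(d, rnorm(n)))$h2[1]
  }, 0)
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))

  # bounded mode clamps the genetic variance at (effectively) zero
  bfit <- fit_reml(set_phenotype(d, rnorm(n)), bounded = TRUE)
  expect_gte(bfit$sigma2[1], 0)
})

test_that("variance estimates scale as c^2 and fractions are scale-free", {
  set.seed(101)
  n <- 60; S <- 300
  Z <- standardize(matrix(rbinom(n * S, 1, 0.5), n, S), rep(0.5, S),
                   "haploid", ids = as.character(1:n))
  g <- compute_grm(Z, "M1")
  y <- drop(Z$Z %*% rnorm(S, sd = 0.05)) + rnorm(n, sd = 0.7)
  f1 <- fit_reml(reml_design(y, list(g)))
  f2 <- fit_reml(reml_design(3 * y, list(g)))
  expect_equal(f2$sigma2_raw, 9 * f1$sigma2_raw, tolerance = 1e-6)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
})

test_that("duplicated GRMs warn and preserve the component sum", {
  set.seed(103)
  n <- 60; S <- 400
  Z <- standardize(matrix(rbinom(n * S, 1, 0.5), n, S), rep(0.5, S),
                   "haploid", ids = as.character(1:n))
  g <- compute_grm(Z, "M1")
  y <- drop(Z$Z %*% rnorm(S, sd = 0.05)) + rnorm(n, sd = 0.6)
  f1 <- fit_reml(reml_design(y, list(g)))
  expect_warning(fit_reml(reml_design(y, list(g, g))),
                 "not separately identifiable")
  d2 <- suppressWarnings(fit_reml(reml_design(y, list(g, g))))
  expect_equal(unname(d2$sigma2[1] + d2$sigma2[2]), unname(f1$sigma2[1]),
               tolerance = 0.02)
})

test_that("the score vanishes at converged unbounded optima", {
  set.seed(107)
  n <- 70; S <- 400
  mk <- function() standardize(matrix(rbinom(n * S, 1, 0.5), n, S),
                               rep(0.5, S), "haploid",
                               ids = as.character(1:n))
  Z1 <- mk(); Z2 <- mk()
  y <- drop(Z1$Z %*% rnorm(S, sd = 0.04)) + rnorm(n, sd = 0.7)
  fit <- fit_reml(reml_design(y, list(compute_grm(Z1, "M1"),
                                      compute_grm(Z2, "M2"))))
  expect_true(fit$converged)
  expect_lt(sqrt(sum(fit$gradient^2)), 1e-4 * n)
})

test_that("z-test p-values match the normal tail probabilities", {
  expect_equal(z_pvalue(0, 1, "one"), 0.5)
  expect_equal(z_pvalue(1.959964, 1, "two"), 0.05, tolerance = 1e-6)
  ratios <- c(-2.1, -0.3, 0.4, 1.7, 3.2)
  expect_equal(vapply(ratios, z_pvalue, 0, se = 1, sided = "one"),
               pnorm(ratios, lower.tail = FALSE))
  expect_equal(vapply(ratios, z_pvalue, 0, se = 1, sided = "two"),
               2 * pnorm(-abs(ratios)))
  expect_error(z_pvalue(1, 0), "positive")
})
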