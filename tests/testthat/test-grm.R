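test_that("standardization matches hand arithmetic", {
  zh <- standardize(matrix(c(1L, 0L), 2, 1), 0.5, "haploid")
  expect_equal(drop(zh$Z), c(1, -1))
  zd <- standardize(matrix(c(2L, 0L), 2, 1), 0.5, "diploid")
  expect_equal(zd$Z[1, 1], 1 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(zd$Z[1, 1], 1.4142, tolerance = 1e-4)

  # monomorphic columns are dropped with a warning
  expect_warning(
    z <- standardize(cbind(c(1L, 1L), c(1L, 0L)), c(1, 0.5), "haploid"),
    "monomorphic")
  expect_equal(ncol(z$Z), 1L)
})

test_that("columns standardized at sample frequencies are centered", {
  set.seed(5)
  x <- matrix(rbinom(20 * 50, 2, 0.3), 20, 50)
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  z <- standardize(x[, keep], p[keep], "diploid")
  expect_true(max(abs(colMeans(z$Z))) < 1e-12)
})

test_that("alpha-scaling and SNP weights transform columns as specified", {
  z <- standardize(matrix(c(1L, 0L, 1L, 1L, 0L, 0L), 3, 2), c(0.5, 0.5),
                   "haploid")
  # alpha = -1, unit weights: exponent 1 + alpha = 0, identity
  z1 <- apply_weights(z, weight_spec("GREML", alpha = -1))
  expect_equal(z1$Z, z$Z)

  # alpha = -0.25, p = 0.5, haploid: factor sqrt((p(1-p))^0.75) = 0.594604
  z2 <- apply_weights(z, weight_spec("LDAK_Thin", alpha = -0.25))
  expect_equal(z2$Z / z$Z, matrix(0.25^0.375, 3, 2), tolerance = 1e-6)
  expect_equal(0.25^0.375, 0.5946, tolerance = 1e-4)

  # zero weight silences a SNP; negative weights are rejected
  z3 <- apply_weights(z, weight_spec("LDAK_Weights", alpha = -1,
                                     weights = c(0, 1)))
  expect_equal(z3$Z[, 1], rep(0, 3))
  expect_error(weight_spec("LDAK_Weights", weights = c(-1, 1)), ">= 0")
})

test_that("GRM entries match hand arithmetic and the brute-force summation", {
  # one haploid SNP, alleles (1, 0), p = 0.5
  z <- standardize(matrix(c(1L, 0L), 2, 1), 0.5, "haploid")
  g <- compute_grm(z, "M1")
  expect_equal(g$A, rbind(c(1, -1), c(-1, 1)))

  # one diploid SNP, dosages (2, 0), p = 0.5: off-diagonal (1)(-1)/0.5 = -2
  zd <- standardize(matrix(c(2L, 0L), 2, 1), 0.5, "diploid")
  expect_equal(compute_grm(zd, "M")$A[1, 2], -2)

  # 5 duos x 20 SNPs against the explicit double-loop per-SNP summation
  set.seed(11)
  p <- runif(20, 0.2, 0.8)
  h <- matrix(rbinom(5 * 20, 1, rep(p, each = 5)), 5, 20)
  g5 <- compute_grm(standardize(h, p, "haploid"), "M1")
  expect_equal(g5$A, brute_grm_haploid(h, p), tolerance = 1e-12)
  expect_true(isSymmetric(g5$A))
})

test_that("weighted GRMs keep the expected unit diagonal", {
  cfg <- sim_config(150, 2000, "maternal", n_causal = 10, seed = 21)
  duos <- simulate_duo_genotypes(cfg)
  duos <- allele_frequencies(duos)
  for (spec in list(weight_spec("GREML"),
                    weight_spec("LDAK_Weights", alpha = -0.25,
                                weights = runif(2000, 0.2, 1)))) {
    z <- apply_weights(standardize(duos$m1, duos$snps$freq, "haploid"), spec)
    g <- compute_grm(z, "M1", spec)
    expect_lt(abs(mean(diag(g$A)) - 1), 0.05)
  }
})

test_that("haplotype GRMs behave like kinships of unrelated founders", {
  cfg <- sim_config(120, 2500, "maternal", n_causal = 10, seed = 31)
  duos <- simulate_duo_genotypes(cfg)
  # build at the generating frequencies: in-sample frequency estimates
  # shrink off-diagonals by ~ -1/n, which is what this check isolates
  duos$snps$freq <- duos$snps$gen_freq
  grms <- duo_grms(duos, kinds = c("M1", "M2", "P1", "MGCTA"))
  n <- 120
  for (k in c("M1", "M2", "P1")) {
    off <- grms[[k]]$A[upper.tri(grms[[k]]$A)]
    # unrelated founders: mean off-diagonal within 3 SE of 0
    expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)))
    ev <- eigen(grms[[k]]$A, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)   # PSD when S >= n
  }
  # mother-child genotype relatedness is 0.5: D diagonal expectation ~ 1
  expect_lt(abs(mean(diag(grms$D$A)) - 1), 0.1)
})

test_that("M-GCTA quadrants satisfy their algebraic identities", {
  set.seed(41)
  x <- matrix(rbinom(30 * 400, 2, 0.4), 30, 400)
  p <- pmin(pmax(colMeans(x) / 2, 0.05), 0.95)
  zm <- standardize(x, p, "diploid")

  # child copies mother: Mprime = G and D = 2 * Mprime
  q <- mgcta_quadrants(zm, zm)
  expect_equal(q$Mprime$A, q$G$A)
  expect_equal(q$D$A, 2 * q$Mprime$A)
  expect_true(isSymmetric(q$D$A))

  # independent mothers and children: D off-diagonals average to ~ 0
  x2 <- matrix(rbinom(30 * 400, 2, rep(p, each = 30)), 30, 400)
  q2 <- mgcta_quadrants(zm, standardize(x2, p, "diploid"))
  off <- q2$D$A[upper.tri(q2$D$A)]
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)))

  expect_error(mgcta_quadrants(zm, standardize(x2[, 1:100], p[1:100], "diploid")),
               "share")
})

test_that("top GRM eigenvectors obey the sign convention and match eigen()", {
  v <- c(3, 1, -2, 0.5, 1.5); v <- v / sqrt(sum(v^2))
  g1 <- structure(list(A = tcrossprod(v), ids = as.character(1:5),
                       n_snps_used = 1, kind = "M", N = NULL), class = "grm")
  pc <- top_pcs(g1, 1)
  expect_equal(abs(drop(pc)), abs(v), tolerance = 1e-10)
  expect_gt(pc[which.max(abs(pc)), 1], 0)

  gI <- g1; gI$A <- diag(5)
  expect_warning(top_pcs(gI, 2), "degenerate")

  set.seed(51)
  B <- crossprod(matrix(rnorm(40 * 30), 40, 30)) / 40
  g2 <- g1; g2$A <- B; g2$ids <- as.character(1:30)
  pcs <- top_pcs(g2, 5)
  e <- eigen(B, symmetric = TRUE)
  proj <- function(V) B - V %*% crossprod(V, B)
  expect_equal(norm(proj(pcs), "F"),
               norm(proj(e$vectors[, 1:5]), "F"), tolerance = 1e-10)

  g2$A[1, 2] <- g2$A[1, 2] + 1
  expect_error(top_pcs(g2, 2), "symmetric")
})
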