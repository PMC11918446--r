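test_that("simulated duos satisfy the transmission identities exactly", {
  cfg <- sim_config(100, 200, "maternal", n_causal = 20, seed = 7)
  duos <- simulate_duo_genotypes(cfg)
  expect_true(all(duos$m1 %in% 0:1))
  expect_true(all((duos$m1 + duos$m2) %in% 0:2))
  expect_true(all((duos$m1 + duos$p1) %in% 0:2))

  # determinism under seed
  again <- simulate_duo_genotypes(cfg)
  expect_identical(duos$m1, again$m1)
  expect_identical(duos$p1, again$p1)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_duo_genotypes(cfg2)$m1, duos$m1))
})

test_that("configuration validation enforces the architecture constraints", {
  expect_error(sim_config(10, 100, "maternal", 20, poe_fraction = 0.5),
               "fetal or joint")
  expect_error(sim_config(10, 100, "joint", 20, rho = 0.5, same_causal = FALSE),
               "undefined")
  expect_error(sim_config(10, 100, "joint", 80, same_causal = FALSE),
               "disjoint")
  expect_silent(sim_config(10, 100, "joint", 20, rho = -0.5))
})

test_that("effect draws implement the imprinting transform", {
  cfg <- sim_config(50, 100, "fetal", 40, poe_fraction = 0.5,
                    imprinting = 0.25, seed = 9)
  eff <- draw_effects(cfg)
  expect_equal(sum(eff$poe), 20)
  expect_equal(eff$u_f1[eff$poe], 0.75 * eff$u_f2[eff$poe])
  expect_equal(eff$u_f1[!eff$poe], eff$u_f2[!eff$poe])
  expect_true(all(eff$u_m == 0))

  # complete imprinting silences the maternal transmitted fetal effect
  cfg1 <- sim_config(50, 100, "fetal", 40, poe_fraction = 1,
                     imprinting = 1, seed = 9)
  eff1 <- draw_effects(cfg1)
  expect_true(all(eff1$u_f1 == 0))

  # fully correlated joint effects are equal elementwise
  cfgj <- sim_config(50, 100, "joint", 40, rho = 1, seed = 10)
  effj <- draw_effects(cfgj)
  expect_equal(effj$u_m, effj$u_f2, tolerance = 1e-12)

  # disjoint causal sets do not overlap
  cfgd <- sim_config(50, 100, "joint", 30, rho = 0, same_causal = FALSE,
                     seed = 11)
  effd <- draw_effects(cfgd)
  expect_equal(nrow(effd), 60)
  expect_false(any(effd$u_m != 0 & effd$u_f2 != 0))
})

test_that("bivariate effect draws realize the requested correlation", {
  cfg <- sim_config(50, 6000, "joint", 5000, rho = 0.5, seed = 13)
  eff <- draw_effects(cfg)
  expect_equal(cor(eff$u_m, eff$u_f2), 0.5, tolerance = 3 / sqrt(5000))
  expect_equal(sd(eff$u_m), 1, tolerance = 0.05)
  expect_equal(sd(eff$u_f2), 1, tolerance = 0.05)
})

test_that("maternal genetic values ignore the paternal haplotype", {
  cfg <- sim_config(80, 300, "maternal", 50, seed = 15)
  duos <- simulate_duo_genotypes(cfg)
  eff <- draw_effects(cfg)
  g1 <- simulate_phenotypes(duos, eff, cfg)$genetic_values
  duos2 <- duos
  duos2$p1 <- duos$p1[sample(80), ]   # scramble paternal alleles
  g2 <- simulate_phenotypes(duos2, eff, cfg)$genetic_values
  expect_equal(g1, g2)
})

test_that("residual scaling fixes the heritability of genetic values", {
  cfg <- sim_config(150, 400, "joint", 80, rho = 0.5, n_replicates = 40,
                    seed = 17)
  duos <- simulate_duo_genotypes(cfg)
  sim <- simulate_phenotypes(duos, draw_effects(cfg), cfg)
  expect_equal(sim$sigma2_g / (sim$sigma2_g + sim$sigma2_e),
               cfg$h2_total, tolerance = 1e-10)
  # replicates share genetic values; realized var(g)/var(y) averages to h2
  ratio <- mean(apply(sim$phenotypes, 2, function(y) sim$sigma2_g / var(y)))
  expect_equal(ratio, 0.5, tolerance = 0.05)
  expect_equal(ncol(sim$phenotypes), 40)
})

test_that("a single causal variant contributes its closed-form variance", {
  # with standardized haplotype columns, a joint causal variant with
  # maternal effect u_m and fetal effect u_f contributes
  # (u_m + u_f)^2 + u_m^2 + u_f^2 = 2(u_m^2 + u_f^2 + u_m u_f)
  # (the raw-allele form 2p(1-p)(u_m^2 + u_f^2 + u_m u_f) divided by p(1-p))
  cfg <- sim_config(20000, 1, "joint", 1, rho = 0, seed = 19)
  duos <- simulate_duo_genotypes(cfg)
  u_m <- 0.8; u_f <- -0.5
  eff <- data.frame(index = 1L, u_m = u_m, u_f1 = u_f, u_f2 = u_f,
                    poe = FALSE)
  g <- simulate_phenotypes(duos, eff, cfg)$genetic_values
  expected <- 2 * (u_m^2 + u_f^2 + u_m * u_f)
  expect_equal(var(g), expected, tolerance = 0.05)
})

test_that("closed-form expected fractions reproduce the canonical ratios", {
  h <- 0.5
  frac <- function(...) as.numeric(expected_fractions(sim_config(10, 100, ...,
                                                                 n_causal = 10)))
  expect_equal(frac("maternal"), c(0.25, 0.25, 0))
  expect_equal(frac("fetal"), c(0.25, 0, 0.25))
  expect_equal(frac("joint", rho = 0), h * c(2, 1, 1) / 4)          # 2:1:1
  expect_equal(frac("joint", rho = 1), h * c(4, 1, 1) / 6)          # 4:1:1
  expect_equal(frac("joint", rho = 1)[1], 1 / 3, tolerance = 1e-4)
  expect_equal(frac("joint", rho = -1), c(0, 0.25, 0.25))
  expect_equal(frac("joint", rho = 0, same_causal = FALSE), h * c(2, 1, 1) / 4)
  # complete maternal imprinting under full correlation: 1:1:1
  expect_equal(frac("joint", rho = 1, poe_fraction = 1, imprinting = 1),
               rep(h / 3, 3))
  # fetal with complete imprinting: all fetal variance through p1
  expect_equal(frac("fetal", poe_fraction = 1, imprinting = 1), c(0, 0, h))
  # partial imprinting interpolates
  f <- frac("fetal", poe_fraction = 0.5, imprinting = 0.5)
  expect_equal(f, h * c(0.5 * 0.25 + 0.5, 0, 1) / (0.5 * 0.25 + 0.5 + 1))
})

test_that("replicate phenotypes are reproducible from (seed, config)", {
  cfg <- sim_config(40, 100, "fetal", 20, n_replicates = 3, seed = 23)
  run <- function() {
    duos <- simulate_duo_genotypes(cfg)
    simulate_phenotypes(duos, draw_effects(cfg), cfg)$phenotypes
  }
  expect_identical(run(), run())
})
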