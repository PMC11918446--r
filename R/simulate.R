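#' Simulation configuration
#'
#' Describes one simulated genetic architecture for a duo cohort. The
#' defaults mirror the validation study conditions: random mating, linkage
#' equilibrium, total SNP heritability `h2_total = 0.5`, causal effect
#' sizes drawn from a standard normal on standardized haplotypes, and 100
#' residual replicates per architecture.
#'
#' Architectures:
#' * `"maternal"` - effects act only through the mother's genome:
#'   `u_m1 = u_m2 = u_m`, no fetal effect;
#' * `"fetal"` - effects act only through the child's genome:
#'   `u_f1 = u_f2 = u_f`, optionally shrunk on the maternal transmitted
#'   copy by an imprinting factor (`u_f1 = (1 - I) u_f2` on a
#'   `poe_fraction` subset of causal variants);
#' * `"joint"` - maternal and fetal effects at the same causal variants,
#'   drawn bivariate normal with unit variances and correlation `rho`
#'   (or, with `same_causal = FALSE` and `rho = 0`, at two disjoint causal
#'   sets), with the same optional imprinting transform on the fetal side.
#'
#' @param n_duos Number of mother-child duos.
#' @param n_snps Number of SNPs in the panel.
#' @param architecture One of `"maternal"`, `"fetal"`, `"joint"`.
#' @param n_causal Number of causal variants (per causal set).
#' @param h2_total Preset narrow-sense heritability of the genetic values
#'   (default 0.5).
#' @param rho Correlation of maternal and fetal effects (joint only).
#' @param same_causal Same causal set through mother and fetus? `FALSE`
#'   only with `rho = 0` (correlated effects at disjoint variants are
#'   undefined).
#' @param poe_fraction Fraction of causal variants showing a
#'   parent-of-origin effect (fetal/joint only).
#' @param imprinting Imprinting factor `I` in \[0, 1\]: the maternal
#'   transmitted effect is `(1 - I)` times the paternal transmitted one on
#'   the POE subset; `I = 1` is complete maternal imprinting.
#' @param maf_low,maf_high Uniform range for generating reference-allele
#'   frequencies.
#' @param n_replicates Residual replicates added per genetic value.
#' @param seed RNG seed for all draws made under this configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_duos, n_snps,
                       architecture = c("maternal", "fetal", "joint"),
                       n_causal, h2_total = 0.5,
                       rho = 0, same_causal = TRUE,
                       poe_fraction = 0, imprinting = 0,
                       maf_low = 0.01, maf_high = 0.5,
                       n_replicates = 100, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(n_causal <= n_snps, h2_total > 0, h2_total < 1,
            rho >= -1, rho <= 1,
            poe_fraction >= 0, poe_fraction <= 1,
            imprinting >= 0, imprinting <= 1,
            maf_low > 0, maf_high <= 0.5, maf_low <= maf_high)
  if (poe_fraction > 0 && architecture == "maternal") {
    stop("parent-of-origin effects require a fetal or joint architecture")
  }
  if (!same_causal) {
    if (architecture != "joint") stop("same_causal applies to joint architecture")
    if (rho != 0) {
      stop("correlated effects with disjoint causal sets are undefined; ",
           "rho must be 0 when same_causal = FALSE")
    }
    if (2 * n_causal > n_snps) stop("two disjoint causal sets need 2*n_causal <= n_snps")
  }
  structure(list(
    n_duos = as.integer(n_duos), n_snps = as.integer(n_snps),
    architecture = architecture, n_causal = as.integer(n_causal),
    h2_total = h2_total, rho = rho, same_causal = same_causal,
    poe_fraction = poe_fraction, imprinting = imprinting,
    maf_low = maf_low, maf_high = maf_high,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate duo genotypes under random mating
#'
#' Draws, per SNP, a reference-allele frequency uniform in
#' `[maf_low, maf_high]`, then for each duo four founder haplotypes
#' (mother's two and father's two) as independent Bernoulli draws at that
#' frequency (linkage equilibrium). The transmitted maternal haplotype `m1`
#' is one of the mother's two chosen per SNP with equal probability, `p1`
#' likewise from the father; the transmission labels are therefore known
#' exactly and stored as ground truth.
#'
#' An optional block-LD mode (`ld_blocks > 1`) makes SNPs within blocks of
#' that size copies of the block's first SNP with probability `ld_copy` per
#' haplotype, creating local LD; it exists to exercise [ld_prune()] and
#' [ld_weights()], not for the recovery studies.
#'
#' @param config A [sim_config()].
#' @param ld_blocks Block size for the optional LD mode (1 = independent
#'   SNPs, the default).
#' @param ld_copy Within-block copy probability under the LD mode.
#' @return A [duo_haplotypes()] object; `snps$gen_freq` carries the
#'   generating frequencies, positions are laid out 1 kb apart on one
#'   chromosome.
#' @export
simulate_duo_genotypes <- function(config, ld_blocks = 1, ld_copy = 0.95) {
  set.seed(config$seed)
  n <- config$n_duos; S <- config$n_snps
  p <- stats::runif(S, config$maf_low, config$maf_high)
  if (ld_blocks > 1) {
    block <- (seq_len(S) - 1) %/% ld_blocks
    p <- p[match(block, block)]  # one frequency per block
  }
  draw_hap <- function() {
    h <- matrix(stats::rbinom(n * S, 1L, rep(p, each = n)), n, S)
    if (ld_blocks > 1) {
      block <- (seq_len(S) - 1) %/% ld_blocks
      anchor <- match(block, block)
      copy <- matrix(stats::rbinom(n * S, 1L, ld_copy), n, S)
      h <- h * (1 - copy) + h[, anchor] * copy
    }
    h
  }
  mo_a <- draw_hap(); mo_b <- draw_hap()
  fa_a <- draw_hap(); fa_b <- draw_hap()
  tm <- matrix(stats::rbinom(n * S, 1L, 0.5), n, S)
  tf <- matrix(stats::rbinom(n * S, 1L, 0.5), n, S)
  m1 <- mo_a * tm + mo_b * (1L - tm)
  m2 <- mo_a * (1L - tm) + mo_b * tm
  p1 <- fa_a * tf + fa_b * (1L - tf)
  storage.mode(m1) <- "integer"
  storage.mode(m2) <- "integer"
  storage.mode(p1) <- "integer"
  snps <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(S)),
    chrom = "1",
    pos = seq_len(S) * 1000L,
    ref_allele = "A",
    freq = NA_real_,
    gen_freq = p,
    stringsAsFactors = FALSE
  )
  duo_haplotypes(m1, m2, p1,
                 mother_ids = sprintf("M%05d", seq_len(n)),
                 child_ids = sprintf("C%05d", seq_len(n)),
                 snps = snps)
}

#' Draw causal variants and allelic effects
#'
#' Selects the causal variant set(s) and draws per-variant effect sizes
#' according to the architecture: standard normal maternal effects, standard
#' normal fetal effects, or bivariate-normal maternal-fetal pairs with
#' correlation `rho`. The parent-of-origin transform multiplies the fetal
#' effect acting through the maternal transmitted copy by `(1 - I)` on a
#' random `poe_fraction` subset of the (fetal-)causal variants.
#'
#' @param config A [sim_config()].
#' @param causal Optional list with integer indices `maternal` and `fetal`
#'   (equal when `same_causal`); drawn at random if `NULL`.
#' @param seed Optional seed; defaults to the configuration seed. Pass a
#'   fresh value per replicate to redraw effects across replicates.
#' @return A data frame of class `duo_effects` with one row per causal
#'   variant: `index`, `u_m` (maternal effect), `u_f1` (fetal effect of the
#'   maternal transmitted copy), `u_f2` (fetal effect of the paternal
#'   transmitted copy), `poe` (in the POE subset?).
#' @export
draw_effects <- function(config, causal = NULL, seed = NULL) {
  set.seed(seed %||% config$seed)
  m <- config$n_causal
  if (is.null(causal)) {
    if (config$same_causal || config$architecture != "joint") {
      idx <- sort(sample.int(config$n_snps, m))
      causal <- list(maternal = idx, fetal = idx)
    } else {
      idx <- sample.int(config$n_snps, 2 * m)
      causal <- list(maternal = sort(idx[seq_len(m)]),
                     fetal = sort(idx[m + seq_len(m)]))
    }
  }
  stopifnot(length(causal$maternal) == m || length(causal$fetal) == m)
  arch <- config$architecture
  shared <- identical(causal$maternal, causal$fetal)
  idx <- sort(union(causal$maternal, causal$fetal))
  eff <- data.frame(index = idx, u_m = 0, u_f1 = 0, u_f2 = 0, poe = FALSE)
  im <- match(causal$maternal, idx)
  jf <- match(causal$fetal, idx)
  if (arch == "maternal") {
    eff$u_m[im] <- stats::rnorm(m)
  } else if (arch == "fetal") {
    eff$u_f2[jf] <- stats::rnorm(m)
    eff$u_f1 <- eff$u_f2
  } else {
    if (shared) {
      u_m <- stats::rnorm(m)
      u_f <- config$rho * u_m + sqrt(1 - config$rho^2) * stats::rnorm(m)
      eff$u_m[im] <- u_m
      eff$u_f2[jf] <- u_f
      eff$u_f1 <- eff$u_f2
    } else {
      eff$u_m[im] <- stats::rnorm(m)
      eff$u_f2[jf] <- stats::rnorm(m)
      eff$u_f1 <- eff$u_f2
    }
  }
  if (config$poe_fraction > 0) {
    n_poe <- round(config$poe_fraction * length(jf))
    poe_rows <- sample(jf, n_poe)
    eff$poe[poe_rows] <- TRUE
    eff$u_f1[poe_rows] <- (1 - config$imprinting) * eff$u_f2[poe_rows]
  }
  class(eff) <- c("duo_effects", "data.frame")
  eff
}

#' Simulate replicate phenotypes from drawn effects
#'
#' Builds genetic values
#' `g = Z_m1 (u_m + u_f1) + Z_m2 u_m + Z_p1 u_f2`
#' over the causal variants, where the `Z` are haploid-standardized
#' haplotype columns (using the generating frequencies) - note the maternal
#' transmitted haplotype acts through both the maternal and the fetal
#' effect, which is the crux of the duo design. The residual variance is
#' set from the realized genetic variance as
#' `sigma2_e = var(g) * (1 / h2 - 1)`, so the realized heritability of the
#' genetic values is exactly `h2_total`, and `n_replicates` phenotype
#' replicates are formed by adding fresh `N(0, sigma2_e)` residuals to the
#' same genetic values.
#'
#' @param duos A panel from [simulate_duo_genotypes()].
#' @param effects A [draw_effects()] result.
#' @param config The [sim_config()].
#' @param seed Optional residual seed (defaults to the configuration seed).
#' @return An object of class `sim_result`: list with `phenotypes`
#'   (`n_duos x n_replicates`), `genetic_values`, `effects`, `sigma2_g`,
#'   `sigma2_e`, `config`.
#' @export
simulate_phenotypes <- function(duos, effects, config, seed = NULL) {
  set.seed(seed %||% (config$seed + 1L))
  idx <- effects$index
  p <- duos$snps$gen_freq %||% duos$snps$freq
  p <- p[idx]
  sdv <- sqrt(p * (1 - p))
  zc <- function(h) sweep(sweep(h[, idx, drop = FALSE], 2, p, "-"), 2, sdv, "/")
  g <- drop(
    zc(duos$m1) %*% (effects$u_m + effects$u_f1) +
    zc(duos$m2) %*% effects$u_m +
    zc(duos$p1) %*% effects$u_f2
  )
  sigma2_g <- stats::var(g)
  if (sigma2_g == 0) stop("realized genetic variance is zero")
  sigma2_e <- sigma2_g * (1 / config$h2_total - 1)
  nrep <- config$n_replicates
  resid <- matrix(stats::rnorm(length(g) * nrep, sd = sqrt(sigma2_e)),
                  length(g), nrep)
  structure(list(
    phenotypes = g + resid,
    genetic_values = g,
    effects = effects,
    sigma2_g = sigma2_g,
    sigma2_e = sigma2_e,
    config = config
  ), class = "sim_result")
}

#' Closed-form expected variance fractions
#'
#' Expected fractions of phenotypic variance attributable to m1, m2 and p1
#' under a configuration, from the per-variant variance decomposition: with
#' haploid-standardized columns, a causal variant with maternal effect
#' `u_m` and fetal effects `u_f1` (maternal copy) and `u_f2` (paternal
#' copy) contributes `E[(u_m + u_f1)^2]`, `E[u_m^2]` and `E[u_f2^2]`
#' through m1, m2 and p1 respectively. Averaging over the effect
#' distribution gives, e.g., the 2:1:1 pattern for independent joint
#' effects, 4:1:1 for fully positively correlated effects, 0:1:1 for fully
#' negatively correlated ones, and 1:1:1 for fully correlated effects under
#' complete maternal imprinting.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector `c(m1, m2, p1)` of expected phenotypic
#'   variance fractions (summing to `h2_total`), plus attribute
#'   `"residual"` with the residual fraction.
#' @export
expected_fractions <- function(config) {
  phi <- config$poe_fraction
  cc <- 1 - config$imprinting   # fetal effect retained on the maternal copy
  arch <- config$architecture
  if (arch == "maternal") {
    e <- c(m1 = 1, m2 = 1, p1 = 0)
  } else if (arch == "fetal") {
    e <- c(m1 = phi * cc^2 + (1 - phi), m2 = 0, p1 = 1)
  } else if (config$same_causal) {
    rho <- config$rho
    e <- c(m1 = phi * (1 + cc^2 + 2 * cc * rho) +
             (1 - phi) * (2 + 2 * rho),
           m2 = 1, p1 = 1)
  } else {
    # disjoint maternal and fetal causal sets, independent effects
    e_mat <- c(1, 1, 0)
    e_fet <- c(phi * cc^2 + (1 - phi), 0, 1)
    e <- stats::setNames(e_mat + e_fet, c("m1", "m2", "p1"))
  }
  out <- config$h2_total * e / sum(e)
  attr(out, "residual") <- 1 - config$h2_total
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %s architecture: %d duos x %d replicates, h2 = %.2f\n",
    x$config$architecture, nrow(x$phenotypes), ncol(x$phenotypes),
    x$config$h2_total))
  invisible(x)
}
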