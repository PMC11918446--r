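#' Adjust and standardize a phenotype
#'
#' Regresses the raw outcome on an intercept, fetal sex and orthogonal
#' polynomials of gestational duration up to `degree` (the convention for
#' gestational-duration-adjusted birth size measurements; pass
#' `gest_duration = NULL` for outcomes adjusted for sex only, such as
#' gestational duration itself), and returns the residuals standardized to
#' mean 0 and variance 1.
#'
#' @param y Numeric outcome vector, no missing values.
#' @param sex Numeric or factor covariate (fetal sex).
#' @param gest_duration Gestational duration, or `NULL` to skip.
#' @param degree Orthogonal polynomial degree (default 3).
#' @return Standardized residual vector of the same length as `y`.
#' @export
adjust_phenotype <- function(y, sex, gest_duration = NULL, degree = 3) {
  stopifnot(!anyNA(y), !anyNA(sex))
  X <- stats::model.matrix(~ sex)
  if (!is.null(gest_duration)) {
    stopifnot(!anyNA(gest_duration))
    if (degree >= 1 && stats::sd(gest_duration) == 0) {
      stop("gest_duration is constant; polynomial adjustment is undefined")
    }
    X <- cbind(X, stats::poly(gest_duration, degree))
  }
  r <- stats::lm.fit(X, y)$residuals
  (r - mean(r)) / stats::sd(r)
}

#' Fit one of the duo study designs
#'
#' Runs a complete variance-partitioning analysis on a duo panel under one
#' of the four designs:
#' * `"GCTA_M"` / `"GCTA_F"` - conventional single-GRM analysis of the
#'   mothers' / children's genotype GRM;
#' * `"MGCTA"` - joint fit of the quadrant matrices `Mprime`, `G` and the
#'   mother-child cross matrix `D` (whose component is a covariance and may
#'   be negative in either REML mode);
#' * `"HGCTA"` - joint fit of the haplotype GRMs `M1`, `M2`, `P1`.
#'
#' Genotype-based designs can adjust for `n_pcs_genotype` leading principal
#' components of their GRM; the haplotype design concatenates
#' `n_pcs_per_haplotype` components from each of the three haplotype GRMs.
#' PCs default to off (`use_pcs = FALSE`), appropriate for homogeneous
#' simulated cohorts; turn them on for real-data runs. Optional kinship
#' filtering removes related duos (mothers' genotype relatedness above
#' `kinship_cutoff`, intersected across all GRMs in the design) before
#' fitting.
#'
#' @param design `"GCTA_M"`, `"GCTA_F"`, `"MGCTA"` or `"HGCTA"`.
#' @param duos A [duo_haplotypes()] panel.
#' @param y Phenotype vector, one value per duo, duo-ordered.
#' @param spec A [weight_spec()] (default GREML, `alpha = -1`).
#' @param use_pcs Include principal-component covariates?
#' @param n_pcs_genotype PCs for the genotype-based designs (default 20).
#' @param n_pcs_per_haplotype PCs per haplotype GRM for H-GCTA (default 10,
#'   i.e. 30 in total).
#' @param kinship_filter Apply relatedness filtering first?
#' @param kinship_cutoff Relatedness threshold (default 0.05).
#' @param bounded Restricted REML (clamp negative genetic variances)?
#' @param sided Sidedness of reported z-test p-values.
#' @param ... Passed to [fit_reml()] (e.g. `max_iter`, `tol`).
#' @return An `hgcta_fit` with design-appropriate component labels.
#' @export
run_design <- function(design = c("GCTA_M", "GCTA_F", "MGCTA", "HGCTA"),
                       duos, y, spec = weight_spec("GREML"),
                       use_pcs = FALSE, n_pcs_genotype = 20,
                       n_pcs_per_haplotype = 10,
                       kinship_filter = FALSE, kinship_cutoff = 0.05,
                       bounded = FALSE, sided = c("one", "two"), ...) {
  design <- match.arg(design)
  sided <- match.arg(sided)
  stopifnot(length(y) == n_duos(duos))
  kinds <- switch(design,
    GCTA_M = "M", GCTA_F = "F", MGCTA = "MGCTA",
    HGCTA = c("M1", "M2", "P1"))
  grms <- duo_grms(duos, kinds = unique(c(kinds, if (kinship_filter) "M")),
                   spec = spec)
  if (kinship_filter) {
    keep <- grms$M$ids
    for (g in grms) keep <- intersect(keep, filter_unrelated(g, kinship_cutoff))
    sel <- match(keep, grms[[1]]$ids)
    grms <- lapply(grms, subset_grm, sel)
    y <- y[sel]
  }
  grms <- switch(design,
    GCTA_M = grms["M"], GCTA_F = grms["F"],
    MGCTA = grms[c("Mprime", "G", "D")],
    HGCTA = grms[c("M1", "M2", "P1")])
  X <- NULL
  if (use_pcs) {
    X <- if (design == "HGCTA") {
      do.call(cbind, lapply(grms, top_pcs, k = n_pcs_per_haplotype))
    } else {
      # genotype-based designs use PCs of their own (first) genotype GRM
      top_pcs(grms[[1]], k = n_pcs_genotype)
    }
  }
  d <- reml_design(y, grms, X = X, precompute = length(grms) == 1)
  fit_reml(d, bounded = bounded, sided = sided, ...)
}

subset_grm <- function(grm, sel) {
  grm$A <- grm$A[sel, sel, drop = FALSE]
  grm$N <- grm$N[sel, sel, drop = FALSE]
  grm$ids <- grm$ids[sel]
  grm
}

#' Replicate a recovery experiment over simulated phenotypes
#'
#' The engine behind the simulation benchmarks: simulates one duo genotype
#' panel under `config`, builds the GRMs required by the requested designs
#' once, then for each replicate draws phenotypes and fits every design,
#' collecting per-component variance fractions. By default causal effects
#' are redrawn each replicate (averaging over architecture-sampling noise);
#' with `redraw_effects = FALSE` the replicates share one set of genetic
#' values and differ only in residuals.
#'
#' @param config A [sim_config()]; `config$n_replicates` replicates are
#'   fitted.
#' @param designs Subset of `c("HGCTA", "GCTA_M", "GCTA_F", "MGCTA")`.
#' @param redraw_effects Redraw causal effects each replicate?
#' @param n_panels Number of independently simulated genotype panels the
#'   replicates are spread across. With one panel (the default, mirroring a
#'   study on a single cohort) replicate estimates share the realized
#'   relatedness structure, so the replicate mean retains a panel-level
#'   noise term that does not average out over replicates; several panels
#'   remove it at the cost of rebuilding GRMs.
#' @param bounded Restricted REML? Default `FALSE` (unrestricted, the
#'   simulation-study convention).
#' @param use_pcs Include PC covariates (default off for the homogeneous
#'   simulated population).
#' @param ... Passed to [fit_reml()].
#' @return A tibble of class `recovery_study` with one row per
#'   replicate x design x component: columns `panel`, `replicate`,
#'   `design`, `component`, `h2`, `se`, `converged`, plus attributes
#'   `config` and `expected` (the [expected_fractions()] oracle).
#' @export
recovery_study <- function(config, designs = "HGCTA",
                           redraw_effects = TRUE, n_panels = 1,
                           bounded = FALSE, use_pcs = FALSE, ...) {
  stopifnot(all(designs %in% c("HGCTA", "GCTA_M", "GCTA_F", "MGCTA")),
            n_panels >= 1, config$n_replicates %% n_panels == 0)
  kinds <- unique(unlist(lapply(designs, switch,
    GCTA_M = "M", GCTA_F = "F", MGCTA = "MGCTA",
    HGCTA = c("M1", "M2", "P1"))))
  reps_per_panel <- config$n_replicates %/% n_panels
  rows <- list()
  for (pa in seq_len(n_panels)) {
    cfg_p <- config
    cfg_p$seed <- config$seed + 55001L * (pa - 1L)
    duos <- simulate_duo_genotypes(cfg_p)
    grms <- duo_grms(duos, kinds = kinds)
    rd <- list()
    dummy <- stats::rnorm(config$n_duos)
    for (ds in designs) {
      g <- switch(ds,
        GCTA_M = grms["M"], GCTA_F = grms["F"],
        MGCTA = grms[c("Mprime", "G", "D")],
        HGCTA = grms[c("M1", "M2", "P1")])
      rd[[ds]] <- reml_design(dummy, g, precompute = length(g) == 1)
    }
    if (!redraw_effects) {
      cfg_p$n_replicates <- reps_per_panel
      sim <- simulate_phenotypes(duos, draw_effects(cfg_p), cfg_p)
    }
    for (r in seq_len(reps_per_panel)) {
      if (redraw_effects) {
        eff_r <- draw_effects(cfg_p, seed = cfg_p$seed + 7919L * r)
        cfg1 <- cfg_p; cfg1$n_replicates <- 1L
        y <- simulate_phenotypes(duos, eff_r, cfg1,
                                 seed = cfg_p$seed + 104729L + r)$phenotypes[, 1]
      } else {
        y <- sim$phenotypes[, r]
      }
      for (ds in designs) {
        fit <- fit_reml(set_phenotype(rd[[ds]], y), bounded = bounded, ...)
        rows[[length(rows) + 1]] <- tibble::tibble(
          panel = pa, replicate = r, design = ds,
          component = fit$components,
          h2 = unname(fit$h2), se = unname(fit$se_h2),
          converged = fit$converged
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "expected") <- expected_fractions(config)
  class(out) <- c("recovery_study", class(out))
  out
}

#' Summarize a recovery study
#'
#' Replicate means and standard errors of the estimated variance fractions
#' per design and component, next to the closed-form expectation.
#'
#' @param object A [recovery_study()] result.
#' @param ... Unused.
#' @return A tibble with columns `design`, `component`, `mean_h2`,
#'   `se_mean` (standard error of the replicate mean), `expected` (`NA`
#'   for components without a closed form, e.g. genotype-design totals).
#' @export
summary.recovery_study <- function(object, ...) {
  exp_frac <- attr(object, "expected")
  sp <- split(object, list(object$design, object$component), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    tibble::tibble(
      design = d$design[1], component = d$component[1],
      mean_h2 = mean(d$h2),
      se_mean = stats::sd(d$h2) / sqrt(nrow(d)),
      expected = if (d$design[1] == "HGCTA" &&
                     d$component[1] %in% c("M1", "M2", "P1")) {
        unname(exp_frac[tolower(d$component[1])])
      } else NA_real_
    )
  }))
  out[order(out$design, out$component), ]
}
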