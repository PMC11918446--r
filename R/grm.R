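#' SNP weighting schemes for GRM construction
#'
#' A `weight_spec` pairs the MAF scaling exponent `alpha` with per-SNP
#' weights `w_i`. Under the assumed architecture the per-SNP effect variance
#' scales as `w_i * [p_i(1 - p_i)]^(1 + alpha)`; `alpha = -1` with unit
#' weights is the classical GREML (standardized-genotype) model, under which
#' weighting leaves standardized columns untouched. `model` records which of
#' the three GRM variants the weights encode:
#' * `"GREML"` - all SNPs, unit weights, recommended `alpha = -1`;
#' * `"LDAK_Thin"` - LD-pruned SNP set, unit weights, recommended
#'   `alpha = -0.25`;
#' * `"LDAK_Weights"` - LD-pruned set with per-SNP inverse-LD-score weights
#'   from [ld_weights()], recommended `alpha = -0.25`.
#'
#' @param model One of `"GREML"`, `"LDAK_Thin"`, `"LDAK_Weights"`.
#' @param alpha MAF scaling exponent; defaults to the model's recommended
#'   value (-1 for GREML, -0.25 otherwise).
#' @param weights Per-SNP non-negative weights; defaults to 1 for every SNP
#'   (required to be 1 for GREML and LDAK_Thin).
#' @param keep Optional integer index of retained (pruned) SNPs.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(model = c("GREML", "LDAK_Thin", "LDAK_Weights"),
                        alpha = NULL, weights = NULL, keep = NULL) {
  model <- match.arg(model)
  if (is.null(alpha)) alpha <- if (model == "GREML") -1 else -0.25
  if (!is.null(weights) && any(weights < 0)) stop("weights must be >= 0")
  if (model %in% c("GREML", "LDAK_Thin") && !is.null(weights) &&
      any(weights != 1)) {
    stop(model, " uses unit weights")
  }
  structure(list(model = model, alpha = alpha, weights = weights, keep = keep),
            class = "weight_spec")
}

#' Standardize an allele or dosage matrix
#'
#' Centers and scales each SNP column to the GREML scale: diploid dosages
#' `x` become `(x - 2p) / sqrt(2p(1 - p))`, haploid allele counts `c` become
#' `(c - p) / sqrt(p(1 - p))`, where `p` is the reference-allele frequency.
#' Missing entries are set to 0 after centering (mean imputation).
#' Monomorphic SNPs (`p` of 0 or 1) cannot be scaled and are dropped with a
#' warning.
#'
#' @param alleles Integer `n x S` matrix (0/1 haploid or 0/1/2 diploid).
#' @param freqs Per-SNP reference-allele frequencies in (0, 1).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param missing Optional logical mask of entries to mean-impute.
#' @param ids Optional row identifiers, carried into downstream GRMs.
#' @return An object of class `standardized_matrix`: list with `Z` (the
#'   standardized matrix), `ploidy`, `ids`, `freqs`, `var_weight` (expected
#'   per-column variance after any weighting; all 1 here) and `n_nonmissing`
#'   (per-pair SNP counts use this).
#' @export
standardize <- function(alleles, freqs,
                        ploidy = c("diploid", "haploid"),
                        missing = NULL, ids = NULL) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.matrix(alleles), length(freqs) == ncol(alleles))
  k <- if (ploidy == "diploid") 2 else 1
  bad <- freqs <= 0 | freqs >= 1
  if (any(bad)) {
    warning(sum(bad), " monomorphic SNP(s) excluded from standardization")
    alleles <- alleles[, !bad, drop = FALSE]
    freqs <- freqs[!bad]
    if (!is.null(missing)) missing <- missing[, !bad, drop = FALSE]
  }
  Z <- sweep(alleles, 2, k * freqs, "-")
  if (!is.null(missing)) Z[missing] <- 0
  Z <- sweep(Z, 2, sqrt(k * freqs * (1 - freqs)), "/")
  nm <- if (is.null(missing)) {
    matrix(TRUE, nrow(Z), ncol(Z))
  } else {
    !missing
  }
  structure(
    list(Z = Z, ploidy = ploidy, ids = ids, freqs = freqs,
         var_weight = rep(1, ncol(Z)), nonmissing = nm),
    class = "standardized_matrix"
  )
}

#' Apply alpha-scaling and SNP weights to a standardized matrix
#'
#' Multiplies standardized column `i` by
#' `sqrt(w_i * [k p_i (1 - p_i)]^(1 + alpha))` (`k = 2` diploid, 1 haploid),
#' so that the variance contributed by SNP `i` follows
#' `w_i * [p_i(1 - p_i)]^(1 + alpha)`. With `alpha = -1` and unit weights
#' this is the identity. If the spec carries a pruned SNP index (`keep`),
#' columns outside it are dropped first.
#'
#' @param Z A [standardize()] result.
#' @param spec A [weight_spec()].
#' @return A `standardized_matrix` with weighted columns and an updated
#'   `var_weight` record (used by [compute_grm()] to normalize the
#'   diagonal).
#' @export
apply_weights <- function(Z, spec) {
  stopifnot(inherits(Z, "standardized_matrix"), inherits(spec, "weight_spec"))
  if (!is.null(spec$keep)) {
    Z$Z <- Z$Z[, spec$keep, drop = FALSE]
    Z$freqs <- Z$freqs[spec$keep]
    Z$var_weight <- Z$var_weight[spec$keep]
    Z$nonmissing <- Z$nonmissing[, spec$keep, drop = FALSE]
  }
  S <- ncol(Z$Z)
  w <- if (is.null(spec$weights)) rep(1, S) else spec$weights
  if (length(w) != S) stop("weights length does not match SNP count")
  if (any(w < 0)) stop("weights must be >= 0")
  k <- if (Z$ploidy == "diploid") 2 else 1
  f2 <- w * (k * Z$freqs * (1 - Z$freqs))^(1 + spec$alpha)
  Z$Z <- sweep(Z$Z, 2, sqrt(f2), "*")
  Z$var_weight <- Z$var_weight * f2
  Z
}

#' Compute a genetic relatedness matrix
#'
#' Forms `A = Z Z' / c` from a (possibly weighted) standardized matrix. The
#' normalizing constant `c` is the sum of expected per-column variances
#' (`S` for unweighted columns), so the expected diagonal is 1 under
#' Hardy-Weinberg equilibrium. For haplotype panels each entry is the
#' average over SNPs of products of standardized 0/1 allele indicators; for
#' genotype panels, of standardized 0/1/2 dosages.
#'
#' @param Z A [standardize()] / [apply_weights()] result.
#' @param kind Label for the alleles the GRM was built from: one of
#'   `"M"`, `"F"`, `"M1"`, `"M2"`, `"P1"`, `"Mprime"`, `"G"`, `"D"`.
#' @param spec The [weight_spec()] used (recorded on the object).
#' @return An object of class `grm`: list with symmetric `A`, `ids`,
#'   `n_snps_used`, `kind`, `weight_spec` and `N` (per-pair counts of SNPs
#'   observed in both members, for GCTA `.grm.N.bin` output).
#' @export
compute_grm <- function(Z, kind = c("M", "F", "M1", "M2", "P1",
                                    "Mprime", "G", "D"),
                        spec = weight_spec("GREML")) {
  kind <- match.arg(kind)
  stopifnot(inherits(Z, "standardized_matrix"), ncol(Z$Z) >= 1)
  cc <- sum(Z$var_weight)
  A <- tcrossprod(Z$Z) / cc
  A <- (A + t(A)) / 2
  N <- tcrossprod(Z$nonmissing * 1)
  structure(
    list(A = A, ids = Z$ids %||% as.character(seq_len(nrow(A))),
         n_snps_used = ncol(Z$Z), kind = kind, weight_spec = spec, N = N),
    class = "grm"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm %s> %d individuals, %d SNPs, mean diagonal %.3f\n",
              x$kind, nrow(x$A), x$n_snps_used, mean(diag(x$A))))
  invisible(x)
}

#' M-GCTA quadrant relatedness matrices
#'
#' Builds the joint mother+child genotype GRM by stacking the mothers'
#' standardized genotypes on top of the children's, and splits it into the
#' three quadrant matrices of the M-GCTA design: the upper-left quadrant is
#' the mothers' relatedness (`M'`), the lower-right the children's (`G`),
#' and the sum of the lower-left quadrant and its transpose is the symmetric
#' mother-child cross matrix (`D`), whose variance component captures the
#' covariance of maternal and fetal genetic effects (and may legitimately be
#' negative). `D` is not rescaled after symmetrization: for true duos its
#' expected diagonal is about 1 (twice the mother-child relatedness of 0.5),
#' which fixes the scale on which `sigma2_D` is reported.
#'
#' @param Zm,Zf [standardize()] results for mothers' and children's diploid
#'   genotypes over the same SNP panel, with duo-aligned rows.
#' @param spec The [weight_spec()] recorded on the output.
#' @return A named list of three `grm` objects: `Mprime`, `G`, `D`.
#' @export
mgcta_quadrants <- function(Zm, Zf, spec = weight_spec("GREML")) {
  stopifnot(inherits(Zm, "standardized_matrix"),
            inherits(Zf, "standardized_matrix"))
  if (ncol(Zm$Z) != ncol(Zf$Z) || nrow(Zm$Z) != nrow(Zf$Z)) {
    stop("mothers' and children's matrices must share SNP panel and duo ordering")
  }
  n <- nrow(Zm$Z)
  cc <- sum(Zm$var_weight)
  J <- tcrossprod(rbind(Zm$Z, Zf$Z)) / cc
  ids <- Zm$ids %||% as.character(seq_len(n))
  mk <- function(A, kind) {
    A <- (A + t(A)) / 2
    structure(list(A = A, ids = ids, n_snps_used = ncol(Zm$Z), kind = kind,
                   weight_spec = spec,
                   N = matrix(ncol(Zm$Z), n, n)),
              class = "grm")
  }
  low <- J[(n + 1):(2 * n), 1:n, drop = FALSE]
  list(
    Mprime = mk(J[1:n, 1:n, drop = FALSE], "Mprime"),
    G = mk(J[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE], "G"),
    D = mk(low + t(low), "D")
  )
}

#' Build the standard GRM set from a duo panel
#'
#' Convenience wrapper producing any subset of the five core relatedness
#' matrices of the duo designs - genotype-based `M` (mothers) and `F`
#' (children), and haplotype-based `M1`, `M2`, `P1` - plus, on request, the
#' M-GCTA quadrants `Mprime`/`G`/`D`. Frequencies are taken from
#' `duos$snps$freq` (computed with [allele_frequencies()] if absent,
#' mothers as founders).
#'
#' @param duos A [duo_haplotypes()] object.
#' @param kinds Character vector from
#'   `c("M", "F", "M1", "M2", "P1", "MGCTA")`.
#' @param spec A [weight_spec()]; weighting applies to every matrix.
#' @param founder_mode Frequency convention if frequencies are missing.
#' @return Named list of `grm` objects (the `"MGCTA"` request expands to
#'   `Mprime`, `G`, `D`).
#' @export
duo_grms <- function(duos, kinds = c("M1", "M2", "P1"),
                     spec = weight_spec("GREML"),
                     founder_mode = "mothers") {
  stopifnot(all(kinds %in% c("M", "F", "M1", "M2", "P1", "MGCTA")))
  if (all(is.na(duos$snps$freq))) {
    duos <- allele_frequencies(duos, founder_mode)
  }
  p <- duos$snps$freq
  ids <- paste(duos$mother_ids, duos$child_ids, sep = "-")
  std_h <- function(h) {
    apply_weights(standardize(h, p, "haploid", duos$missing, ids), spec)
  }
  std_g <- function(who) {
    g <- genotypes_from_duos(duos, who)
    apply_weights(standardize(g$dosage, p, "diploid", g$missing, ids), spec)
  }
  out <- list()
  for (k in intersect(kinds, c("M1", "M2", "P1"))) {
    out[[k]] <- compute_grm(std_h(duos[[tolower(k)]]), k, spec)
  }
  if ("M" %in% kinds) out$M <- compute_grm(std_g("mothers"), "M", spec)
  if ("F" %in% kinds) out$F <- compute_grm(std_g("children"), "F", spec)
  if ("MGCTA" %in% kinds) {
    out <- c(out, mgcta_quadrants(std_g("mothers"), std_g("children"), spec))
  }
  out
}
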