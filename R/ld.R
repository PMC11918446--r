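#' Greedy LD pruning
#'
#' Scans SNPs left to right within each chromosome and drops a SNP whose
#' squared Pearson correlation with any already-retained SNP within
#' `window_kb` exceeds `r2_max`. The default `r2_max = 0.98` removes only
#' near-duplicate markers, matching the thinning used for the equal-weight
#' pruned-SNP GRM variant.
#'
#' @param geno A `genotype_matrix` (see [genotypes_from_duos()]) with
#'   positions sorted within chromosome.
#' @param r2_max Squared-correlation threshold above which a SNP is dropped.
#' @param window_kb Window half-width in kilobases within which pairs are
#'   compared.
#' @return Integer vector of retained SNP column indices.
#' @export
ld_prune <- function(geno, r2_max = 0.98, window_kb = 100) {
  X <- geno$dosage
  pos <- geno$snps$pos
  chrom <- geno$snps$chrom
  if (is.unsorted(order(chrom, pos)) &&
      any(unlist(tapply(pos, chrom, is.unsorted)))) {
    stop("positions must be sorted within chromosome")
  }
  window <- window_kb * 1000
  keep <- integer(0)
  for (i in seq_len(ncol(X))) {
    near <- keep[chrom[keep] == chrom[i] & abs(pos[keep] - pos[i]) <= window]
    drop <- FALSE
    for (j in near) {
      r <- suppressWarnings(stats::cor(X[, i], X[, j]))
      if (!is.na(r) && r^2 > r2_max) { drop <- TRUE; break }
    }
    if (!drop) keep <- c(keep, i)
  }
  keep
}

#' Inverse-LD-score SNP weights
#'
#' Computes, for each SNP, `w_i = 1 / (1 + sum of r^2 with every other SNP
#' within the window)` - the inverse of its local LD score. SNPs in strong
#' local LD are down-weighted so that a region's total contribution to the
#' GRM is not inflated by marker density; an isolated SNP gets weight 1.
#' This is a deliberately simple surrogate for solver-based LD weighting
#' schemes, adequate for the pruned panels it is applied to.
#'
#' @inheritParams ld_prune
#' @param window_kb Window half-width in kilobases (default 100).
#' @return Numeric vector of weights in (0, 1], one per SNP.
#' @export
ld_weights <- function(geno, window_kb = 100) {
  X <- geno$dosage
  pos <- geno$snps$pos
  chrom <- geno$snps$chrom
  window <- window_kb * 1000
  S <- ncol(X)
  score <- numeric(S)
  for (i in seq_len(S)) {
    near <- which(chrom == chrom[i] & abs(pos - pos[i]) <= window)
    near <- setdiff(near, i)
    if (length(near)) {
      r <- suppressWarnings(stats::cor(X[, i], X[, near, drop = FALSE]))
      score[i] <- sum(r^2, na.rm = TRUE)
    }
  }
  1 / (1 + score)
}

#' Kinship filtering to a nominally unrelated set
#'
#' Greedily removes individuals until no off-diagonal relatedness exceeds
#' `cutoff`: while any pair exceeds the cutoff, the individual involved in
#' the most such pairs is dropped (ties broken toward the lower index).
#'
#' @param grm A `grm` object.
#' @param cutoff Relatedness threshold (default 0.05).
#' @return Character vector of retained ids, in original order.
#' @export
filter_unrelated <- function(grm, cutoff = 0.05) {
  A <- grm$A
  stopifnot(nrow(A) == ncol(A))
  keep <- seq_len(nrow(A))
  repeat {
    B <- A[keep, keep, drop = FALSE]
    over <- (B > cutoff) & upper.tri(B)
    over <- over | t(over)
    deg <- rowSums(over)
    if (all(deg == 0)) break
    keep <- keep[-which.max(deg)]
  }
  grm$ids[keep]
}
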