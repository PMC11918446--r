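#' Assemble a variance-component design
#'
#' Bundles a phenotype, fixed-effect covariates and an ordered list of
#' relatedness matrices into the design fitted by [fit_reml()]. The model is
#' `y = X b + sum_k u_k + e`, `u_k ~ N(0, A_k sigma2_k)`,
#' `e ~ N(0, I sigma2_e)`, so `V = sum_k sigma2_k A_k + sigma2_e I`.
#'
#' @param y Numeric phenotype vector, one value per individual/duo.
#' @param grms A `grm` object or list of `grm` objects sharing id ordering
#'   with `y`.
#' @param X Fixed-effect matrix (full column rank). Defaults to an
#'   intercept; an intercept column is prepended if absent.
#' @param precompute If `TRUE` and a single GRM is supplied, its
#'   eigendecomposition is cached so repeated fits (e.g. over simulation
#'   replicates via [set_phenotype()]) cost O(n^2) each.
#' @return An object of class `reml_design`.
#' @export
reml_design <- function(y, grms, X = NULL, precompute = FALSE) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1, all(vapply(grms, inherits, TRUE, "grm")))
  n <- length(y)
  for (g in grms) {
    if (nrow(g$A) != n) stop("GRM dimension does not match phenotype length")
  }
  ids0 <- grms[[1]]$ids
  for (g in grms[-1]) {
    if (!identical(g$ids, ids0)) stop("GRMs do not share id ordering")
  }
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
      X <- cbind("(Intercept)" = 1, X)
    }
  }
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  if (is.null(names(grms))) {
    names(grms) <- vapply(grms, `[[`, "", "kind")
  }
  eig <- NULL
  if (precompute && length(grms) == 1) {
    eig <- eigen(grms[[1]]$A, symmetric = TRUE)
  }
  structure(list(y = as.numeric(y), X = X, grms = grms, n = n, eig = eig),
            class = "reml_design")
}

#' Swap the phenotype of an existing design
#'
#' Keeps the GRMs (and any cached eigendecomposition) while replacing `y`;
#' used to fit many simulation replicates against the same relatedness
#' structure.
#'
#' @param design A [reml_design()].
#' @param y New phenotype vector of the same length.
#' @return The updated design.
#' @export
set_phenotype <- function(design, y) {
  stopifnot(inherits(design, "reml_design"), length(y) == design$n)
  design$y <- as.numeric(y)
  design
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates `-0.5 * (log|V| + log|X' V^-1 X| + y' P y)` with
#' `V = sum_k sigma2_k A_k + sigma2_e I` and
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`. The additive constant
#' `-0.5 (n - p) log(2 pi)` is omitted, as is the non-varying `log|X'X|`
#' term; only likelihood differences are meaningful.
#'
#' @param design A [reml_design()].
#' @param sigma2 Numeric vector of length `K + 1`: one variance per GRM in
#'   design order, residual variance last.
#' @return The restricted log-likelihood (a scalar).
#' @export
reml_loglik <- function(design, sigma2) {
  parts <- reml_parts(design, sigma2, need_ai = FALSE)
  if (is.null(parts)) {
    V <- v_matrix(design, sigma2)
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("V is singular or not positive definite (smallest eigenvalue %.3e)", ev))
  }
  parts$loglik
}

v_matrix <- function(design, sigma2) {
  K <- length(design$grms)
  V <- diag(sigma2[K + 1], design$n)
  for (k in seq_len(K)) V <- V + sigma2[k] * design$grms[[k]]$A
  V
}

# One evaluation of the restricted likelihood and, optionally, of the
# score vector and average-information matrix. Returns NULL if V (or
# X'V^-1X) is not positive definite, letting the caller step-halve.
reml_parts <- function(design, sigma2, need_ai = TRUE) {
  y <- design$y; X <- design$X; n <- design$n
  K <- length(design$grms)
  if (!is.null(design$eig) && K == 1) {
    return(reml_parts_eig(design, sigma2, need_ai))
  }
  V <- v_matrix(design, sigma2)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  logdetV <- 2 * sum(log(diag(R)))
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  logdetX <- 2 * sum(log(diag(Rx)))
  P <- Vi - ViX %*% chol2inv(Rx) %*% t(ViX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  loglik <- -0.5 * (logdetV + logdetX + yPy)
  out <- list(loglik = loglik)
  if (!need_ai) return(out)
  # q_k = A_k P y (q for residual is Py itself); all O(n^2) from here on
  q <- vector("list", K + 1)
  trPA <- numeric(K + 1)
  for (k in seq_len(K)) {
    A <- design$grms[[k]]$A
    q[[k]] <- drop(A %*% Py)
    trPA[k] <- sum(P * A)
  }
  q[[K + 1]] <- Py
  trPA[K + 1] <- sum(diag(P))
  grad <- numeric(K + 1)
  for (k in seq_len(K + 1)) {
    grad[k] <- -0.5 * (trPA[k] - sum(Py * q[[k]]))
  }
  Pq <- lapply(q, function(v) drop(P %*% v))
  AI <- matrix(0, K + 1, K + 1)
  for (k in seq_len(K + 1)) {
    for (l in k:(K + 1)) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(q[[k]] * Pq[[l]])
    }
  }
  c(out, list(grad = grad, AI = AI, trPA = trPA, Py = Py))
}

# Single-GRM path in the GRM eigenbasis: V is diagonal there, so each
# likelihood evaluation is O(n p^2) instead of O(n^3).
reml_parts_eig <- function(design, sigma2, need_ai = TRUE) {
  e <- design$eig
  lam <- e$values
  yt <- drop(crossprod(e$vectors, design$y))
  Xt <- crossprod(e$vectors, design$X)
  d <- sigma2[1] * lam + sigma2[2]
  if (any(d <= 0)) return(NULL)
  di <- 1 / d
  XtViX <- crossprod(Xt, Xt * di)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  XtViXi <- chol2inv(Rx)
  Viy <- yt * di
  b <- XtViXi %*% crossprod(Xt, Viy)
  Py <- Viy - (Xt %*% b) * di          # P y in the eigenbasis
  yPy <- sum(yt * Py)
  loglik <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(Rx))) + yPy)
  out <- list(loglik = loglik)
  if (!need_ai) return(out)
  Pv <- function(v) v * di - (Xt %*% (XtViXi %*% crossprod(Xt, v * di))) * di
  trP_diag <- function(a) {
    # tr(P diag(a)) = sum(a * di) - tr((X'ViX)^-1 X' Vi diag(a) Vi X)
    W <- Xt * (a * di)
    sum(a * di) - sum(XtViXi * crossprod(Xt * di, W))
  }
  q <- list(lam * Py, Py)
  trPA <- c(trP_diag(lam), trP_diag(rep(1, length(lam))))
  grad <- vapply(1:2, function(k) -0.5 * (trPA[k] - sum(Py * q[[k]])), 0)
  Pq <- lapply(q, Pv)
  AI <- matrix(0, 2, 2)
  for (k in 1:2) for (l in k:2) {
    AI[k, l] <- AI[l, k] <- 0.5 * sum(q[[k]] * Pq[[l]])
  }
  c(out, list(grad = grad, AI = AI, trPA = trPA, Py = Py))
}

#' Fit variance components by average-information REML
#'
#' Estimates the variance components of a [reml_design()] by restricted
#' maximum likelihood. The optimizer starts from an equal split of the
#' phenotypic variance across all components, takes one EM warm-up step,
#' then iterates average-information (AI) updates with step-halving until
#' the log-likelihood changes by less than `tol`. The phenotype is
#' standardized to unit variance internally, so fitted variances are
#' phenotypic fractions up to their total; estimates are also reported on
#' the original scale.
#'
#' In unbounded mode (`bounded = FALSE`, the convention for simulation
#' studies) genetic variances may go negative, which keeps component means
#' unbiased around zero and is essential for interpreting negatively
#' correlated maternal-fetal architectures. In bounded mode any negative
#' genetic variance is clamped to `1e-8 * var(y)` and held at the bound
#' while its gradient points outward (re-released if it turns positive);
#' the M-GCTA cross-component `D` is exempt, since it estimates a
#' covariance and may legitimately be negative in either mode. The residual
#' variance is always kept positive.
#'
#' Standard errors come from the inverse AI matrix at the optimum; standard
#' errors of the variance fractions use the delta method with the full
#' component covariance. P-values are normal-theory z tests via
#' [z_pvalue()] (one-sided by default, the convention for empirical-data
#' reports; simulation comparisons typically use two-sided).
#'
#' @param design A [reml_design()].
#' @param bounded Clamp negative genetic variances (restricted mode)?
#' @param max_iter Maximum AI iterations (default 100).
#' @param tol Convergence threshold on the log-likelihood change.
#' @param sided `"one"` or `"two"`, for the reported z-test p-values.
#' @return An object of class `hgcta_fit`; see [tidy.hgcta_fit()] for the
#'   tabular view. Fields include `sigma2` (unit-variance scale, residual
#'   last), `sigma2_raw` (original phenotype scale), `h2` (fractions of
#'   total), `se_sigma2`, `se_h2`, `cov_sigma2`, `pvalues`, `loglik`,
#'   `n_iter`, `converged`, `bounded`, `gradient`.
#' @export
fit_reml <- function(design, bounded = FALSE, max_iter = 100, tol = 1e-6,
                     sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(inherits(design, "reml_design"))
  K <- length(design$grms)
  if (design$n <= ncol(design$X) + K) stop("too few observations")
  warn_identical_grms(design)
  sdy <- stats::sd(design$y)
  if (sdy == 0) stop("phenotype has zero variance")
  dz <- design
  dz$y <- (design$y - mean(design$y)) / sdy
  vp <- 1
  lower <- 1e-8 * vp
  unbounded_ok <- !bounded | vapply(design$grms, function(g)
    identical(g$kind, "D"), TRUE)   # D may go negative even when bounded

  sigma2 <- rep(vp / (K + 1), K + 1)
  parts <- reml_parts(dz, sigma2)
  if (is.null(parts)) stop("initial V not positive definite")

  # one EM warm-up step: sigma_k^2 <- sigma_k^2 + sigma_k^4/n (y'PA_kPy - tr(PA_k))
  em <- sigma2
  for (k in seq_len(K + 1)) {
    q_yPAPy <- 2 * parts$grad[k] + parts$trPA[k]   # y'P A_k P y
    em[k] <- sigma2[k] + sigma2[k]^2 / dz$n * (q_yPAPy - parts$trPA[k])
  }
  em <- clamp_sigma(em, lower, bounded, unbounded_ok)
  p_em <- reml_parts(dz, em)
  if (!is.null(p_em)) { sigma2 <- em; parts <- p_em }

  converged <- FALSE
  iter <- 0L
  fixed <- rep(FALSE, K + 1)
  while (iter < max_iter) {
    iter <- iter + 1L
    free <- !fixed
    AIf <- parts$AI[free, free, drop = FALSE]
    step <- rep(0, K + 1)
    sol <- tryCatch(solve(AIf, parts$grad[free]), error = function(e) NULL)
    if (is.null(sol)) sol <- parts$grad[free] / max(diag(AIf), 1e-8)
    step[free] <- sol
    prev <- parts$loglik
    h <- 1
    repeat {
      cand <- sigma2 + h * step
      if (bounded) {
        hit <- cand < lower & !unbounded_ok
        cand[hit] <- lower
        cand[K + 1] <- max(cand[K + 1], lower)
      } else {
        cand[K + 1] <- max(cand[K + 1], lower)
      }
      p_new <- reml_parts(dz, cand)
      if (!is.null(p_new) && p_new$loglik >= prev - 1e-10) break
      h <- h / 2
      if (h < 1e-8) { p_new <- NULL; break }
    }
    if (is.null(p_new)) break           # cannot improve; report last state
    sigma2 <- cand; parts <- p_new
    if (bounded) {
      at_bound <- sigma2 <= lower & !unbounded_ok
      fixed <- at_bound & parts$grad < 0   # held down while gradient points out
    }
    if (abs(parts$loglik - prev) < tol) { converged <- TRUE; break }
  }

  cov_sigma2 <- tryCatch(solve(parts$AI), error = function(e)
    matrix(NA_real_, K + 1, K + 1))
  se_sigma2 <- sqrt(pmax(diag(cov_sigma2), 0))
  total <- sum(sigma2)
  h2 <- sigma2 / total
  # delta method: d(sigma_i/T)/d(sigma_j) = (I[i==j] * T - sigma_i) / T^2
  Jc <- (diag(K + 1) * total - matrix(sigma2, K + 1, K + 1)) / total^2
  cov_h2 <- Jc %*% cov_sigma2 %*% t(Jc)
  se_h2 <- sqrt(pmax(diag(cov_h2), 0))
  labels <- c(names(design$grms), "residual")
  pv <- rep(NA_real_, K + 1)
  ok <- !is.na(se_h2) & se_h2 > 0
  pv[ok] <- vapply(which(ok), function(k)
    z_pvalue(h2[k], se_h2[k], sided), 0)

  structure(list(
    sigma2 = stats::setNames(sigma2, labels),
    sigma2_raw = stats::setNames(sigma2 * sdy^2, labels),
    h2 = stats::setNames(h2, labels),
    se_sigma2 = stats::setNames(se_sigma2, labels),
    se_h2 = stats::setNames(se_h2, labels),
    cov_sigma2 = cov_sigma2,
    pvalues = stats::setNames(pv, labels),
    sided = sided,
    loglik = parts$loglik,
    gradient = parts$grad,
    n_iter = iter,
    converged = converged,
    bounded = bounded,
    n = design$n,
    components = labels
  ), class = "hgcta_fit")
}

clamp_sigma <- function(sigma2, lower, bounded, unbounded_ok) {
  K1 <- length(sigma2)
  if (bounded) {
    hit <- sigma2 < lower & !unbounded_ok
    sigma2[hit] <- lower
  }
  sigma2[K1] <- max(sigma2[K1], lower)
  sigma2
}

warn_identical_grms <- function(design) {
  K <- length(design$grms)
  if (K < 2) return(invisible())
  for (k in seq_len(K - 1)) for (l in (k + 1):K) {
    if (max(abs(design$grms[[k]]$A - design$grms[[l]]$A)) < 1e-12) {
      warning("GRMs ", k, " and ", l, " are identical; their components ",
              "are not separately identifiable (only their sum is)")
    }
  }
  invisible()
}

#' Normal-theory z-test p-value
#'
#' One-sided p-values are the upper-tail normal probability of
#' `estimate / se` (the convention for testing a variance fraction against
#' zero); two-sided p-values double the smaller tail.
#'
#' @param estimate Point estimate.
#' @param se Standard error, `> 0`.
#' @param sided `"one"` or `"two"`.
#' @return A p-value in \[0, 1\].
#' @export
z_pvalue <- function(estimate, se, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  z <- estimate / se
  if (sided == "one") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(-abs(z))
  }
}

#' @export
print.hgcta_fit <- function(x, ...) {
  cat(sprintf("<hgcta_fit> %s REML, %d components + residual, n = %d\n",
              if (x$bounded) "restricted" else "unrestricted",
              length(x$h2) - 1, x$n))
  cat(sprintf("  logLik %.4f after %d iterations (%sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT "))
  tab <- data.frame(
    component = x$components,
    h2 = round(x$h2, 4),
    se = round(x$se_h2, 4),
    p = signif(x$pvalues, 3)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
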