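#' Build design matrices for a single-trait animal model
#'
#' Maps phenotype records to individuals: `X` is an intercept column (one
#' fixed effect, the overall mean) and `Z` is the records-by-individuals
#' incidence matrix. Individuals without records (candidates) get all-zero
#' Z columns and are predicted through their kinship rows.
#'
#' @param record_ids individual IDs of the phenotype records, in record order
#' @param all_ids IDs of every individual in the relationship matrix
#' @return list with `X` (records x 1) and `Z` (records x n)
#' @export
design_matrices <- function(record_ids, all_ids) {
  idx <- match(record_ids, all_ids)
  if (anyNA(idx)) stop_blupga("record individual absent from kinship IDs")
  nrec <- length(record_ids)
  Z <- matrix(0, nrec, length(all_ids), dimnames = list(NULL, all_ids))
  Z[cbind(seq_len(nrec), idx)] <- 1
  list(X = matrix(1, nrec, 1), Z = Z)
}

## Restricted log-likelihood machinery: rotate the phenotypes into the
## eigenbasis of Q' (Z K Z') Q, where Q spans the orthogonal complement of
## the fixed effects. The profile REML log-likelihood then separates over
## the variance ratio delta = sigma_e^2 / sigma_u^2.
reml_spectral <- function(y, X, Z, K) {
  H <- Z %*% K %*% t(Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_blupga("X is not full column rank")
  n <- length(y); p <- ncol(X)
  Q <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  A <- crossprod(Q, H %*% Q)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(theta = pmax(eg$values, 0), ytil = drop(crossprod(eg$vectors, crossprod(Q, y))),
       df = n - p)
}

reml_loglik <- function(delta, sp) {
  v <- sp$theta + delta
  s2u <- sum(sp$ytil^2 / v) / sp$df
  -0.5 * (sp$df * log(2 * pi * s2u) + sum(log(v)) + sp$df)
}

#' Estimate variance components by restricted maximum likelihood
#'
#' Single-random-effect model `y = X b + Z u + e` with
#' `u ~ N(0, sigma_u2 * K)` and `e ~ N(0, sigma_e2 * I)`. The fixed effects
#' are projected out, the projected covariance `Z K Z'` is
#' eigendecomposed, and the restricted likelihood is maximized by bracketed
#' 1-D optimization over the variance-ratio parameter
#' `gamma = sigma_u2 / (sigma_u2 + sigma_e2)` in (0, 1), tolerance 1e-8.
#'
#' The reported `h2` is on the variance-explained scale:
#' `sigma_u2 * vbar / (sigma_u2 * vbar + sigma_e2)`, where
#' `vbar = (tr(Kp) - sum(Kp)/n) / (n - 1)` is the expected sample variance
#' of the genetic values per unit `sigma_u2` on the phenotyped block `Kp`.
#' Under the fixed p = 0.5 centering, K carries a common allele-frequency
#' component that shifts all individuals together without contributing to
#' phenotypic variance; using the centered diagonal removes it, so `h2`
#' estimates `var(g) / var(y)` as a trait designer would define it.
#'
#' @param y numeric response vector (records)
#' @param X fixed-effect design (records x p, full column rank)
#' @param Z random-effect incidence (records x n)
#' @param K symmetric PSD relationship matrix (n x n)
#' @return list with `sigma_u2`, `sigma_e2`, `lambda`, `h2`,
#'   `log_restricted_likelihood`
#' @export
estimate_variance_components <- function(y, X, Z, K) {
  if (length(y) < 3) stop_blupga("need at least 3 phenotyped records")
  K <- ensure_psd(unclass(K), attr(K, "label") %||% "K")
  sp <- reml_spectral(y, X, Z, K)
  if (max(sp$theta) - min(sp$theta) < 1e-10 * max(sp$theta, 1))
    stop_blupga("kinship has no eigenvalue spread on the phenotyped subset; variance components are not identifiable")
  obj <- function(g) reml_loglik((1 - g) / g, sp)
  opt <- stats::optimize(obj, interval = c(1e-6, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-8)
  g <- opt$maximum
  delta <- (1 - g) / g
  s2u <- sum(sp$ytil^2 / (sp$theta + delta)) / sp$df
  s2e <- s2u * delta
  Kp <- Z %*% K %*% t(Z)
  np <- nrow(Kp)
  vbar <- (sum(diag(Kp)) - sum(Kp) / np) / (np - 1)
  list(sigma_u2 = s2u, sigma_e2 = s2e, lambda = delta,
       h2 = s2u * vbar / (s2u * vbar + s2e),
       log_restricted_likelihood = opt$objective)
}

## Phenotypic-scale covariance of the records, V = Z K Z' + lambda I,
## shared by the GLS and BLUP steps below.
record_vmat <- function(Z, K, lambda) {
  V <- Z %*% unclass(K) %*% t(Z)
  diag(V) <- diag(V) + lambda
  V
}

#' Generalized least-squares fixed-effect solution
#'
#' `b = (X' V^-1 X)^-1 X' V^-1 y` with `V = Z K Z' + lambda I` on the
#' record scale (the equivalent-model form of the mixed-model fixed-effect
#' solution; identical to the MME solution for b).
#'
#' @inheritParams estimate_variance_components
#' @param lambda variance ratio `sigma_e2 / sigma_u2`
#' @return numeric vector of fixed-effect estimates
#' @export
gls_fixed_effects <- function(y, X, Z, K, lambda) {
  V <- record_vmat(Z, K, lambda)
  ViX <- solve(V, X)
  drop(solve(crossprod(X, ViX), crossprod(ViX, y)))
}

#' Auxiliary solution vector of the equivalent algorithm
#'
#' `s = V^-1 (y - X b)` with `V = Z K Z' + lambda I`; breeding values
#' follow as `u = K Z' s` and RRBLUP marker effects as `g = M' Z' s / c`.
#'
#' @inheritParams gls_fixed_effects
#' @param b_hat fixed-effect estimates from [gls_fixed_effects]
#' @return numeric vector of length records
#' @export
solve_shat <- function(y, X, Z, K, lambda, b_hat) {
  V <- record_vmat(Z, K, lambda)
  drop(solve(V, y - drop(X %*% b_hat)))
}

#' Breeding values from the auxiliary vector
#'
#' `u = K Z' s`: the kinship rows carry predictions to every individual in
#' K, including unphenotyped candidates.
#'
#' @param K relationship matrix (n x n)
#' @param Z incidence matrix (records x n)
#' @param s_hat auxiliary vector from [solve_shat]
#' @return named numeric vector of GEBVs, one per individual in K
#' @export
gebv_from_shat <- function(K, Z, s_hat) {
  u <- drop(unclass(K) %*% crossprod(Z, s_hat))
  names(u) <- colnames(Z) %||% rownames(K)
  u
}

#' RRBLUP marker effects from the auxiliary vector
#'
#' `g = M' Z' s / c` with `c = 2 * sum(p(1-p))` the same normalization used
#' for G; this is the ridge-regression BLUP solution and satisfies the
#' equivalence `M g = u` exactly when `K = G = M M' / c`.
#'
#' @param M centered genotype matrix from [center_genotypes]
#' @param Z incidence matrix
#' @param s_hat auxiliary vector
#' @param scale_constant the constant c used to normalize G
#' @return named numeric vector of per-marker effects
#' @export
marker_effects_rrblup <- function(M, Z, s_hat, scale_constant) {
  if (scale_constant <= 0) stop_blupga("scale_constant must be positive")
  g <- drop(crossprod(M, crossprod(Z, s_hat))) / scale_constant
  names(g) <- colnames(M)
  g
}

#' Fit a kinship BLUP model with the equivalent algorithm
#'
#' Convenience wrapper running the GLS fixed-effect step, the auxiliary
#' solve and the GEBV step in sequence for a given kinship (G for GBLUP, T
#' for BLUP|GA); optionally also returns RRBLUP marker effects.
#'
#' @inheritParams gls_fixed_effects
#' @param geno optional [geno_matrix]; when supplied, marker effects are
#'   computed with the G-scale constant `m / 2`
#' @param label kinship label stored in the result (`"G"` or `"T"`)
#' @return list of class `blup_fit`: `b_hat`, `s_hat`, `gebv`,
#'   `marker_effects` (or NULL), `lambda`, `kinship_label`
#' @export
fit_blup <- function(y, X, Z, K, lambda, geno = NULL,
                     label = attr(K, "label") %||% "K") {
  b <- gls_fixed_effects(y, X, Z, K, lambda)
  s <- solve_shat(y, X, Z, K, lambda, b)
  u <- gebv_from_shat(K, Z, s)
  g <- NULL
  if (!is.null(geno)) {
    cg <- center_genotypes(geno)
    g <- marker_effects_rrblup(cg$M, Z, s, cg$scale_constant)
  }
  structure(list(b_hat = b, s_hat = s, gebv = u, marker_effects = g,
                 lambda = lambda, kinship_label = label),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("BLUP fit (K = %s): %d GEBVs, lambda = %.4g\n",
              x$kinship_label, length(x$gebv), x$lambda))
  invisible(x)
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBVs and reference values (conventional
#' EBVs, deregressed proofs, or simulated true breeding values), on the
#' individuals present in both vectors.
#'
#' @param gebv,reference_values named numeric vectors
#' @return correlation in `[-1, 1]`
#' @export
accuracy <- function(gebv, reference_values) {
  p <- pair_by_name(gebv, reference_values)
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop_blupga("accuracy undefined: zero variance in GEBV or reference")
  stats::cor(p$a, p$b)
}

#' Dispersion unbiasedness
#'
#' Ordinary least-squares slope of the reference values on the GEBVs
#' (`cov(ref, gebv) / var(gebv)`); 1 indicates no inflation or shrinkage of
#' the predictions. The reverse regression (GEBV on reference) is returned
#' as attribute `reverse_slope`.
#'
#' @inheritParams accuracy
#' @return slope, with attribute `reverse_slope`
#' @export
unbiasedness <- function(gebv, reference_values) {
  p <- pair_by_name(gebv, reference_values)
  if (stats::var(p$a) == 0) stop_blupga("unbiasedness undefined: zero GEBV variance")
  b <- stats::cov(p$b, p$a) / stats::var(p$a)
  rev <- if (stats::var(p$b) > 0) stats::cov(p$a, p$b) / stats::var(p$b) else NA_real_
  structure(b, reverse_slope = rev)
}

pair_by_name <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    ids <- intersect(names(a), names(b))
    if (length(ids) < 3) stop_blupga("need at least 3 paired values")
    list(a = unname(a[ids]), b = unname(b[ids]))
  } else {
    if (length(a) != length(b) || length(a) < 3)
      stop_blupga("need at least 3 paired values of equal length")
    list(a = unname(a), b = unname(b))
  }
}
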