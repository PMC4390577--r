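# Independent oracles and fixture generators. These deliberately avoid the
# package's own linear-algebra paths: the MME oracle builds and solves
# Henderson's equations directly, the brute-force G/S builders loop over
# columns, and the grid REML oracle scans the likelihood on a lattice.

# Direct solve of Henderson's mixed-model equations
#   [X'X  X'Z          ] [b]   [X'y]
#   [Z'X  Z'Z + lam*K^-1] [u] = [Z'y]
oracle_mme <- function(y, X, Z, K, lambda) {
  Ki <- solve(K)
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lambda * Ki))
  sol <- solve(LHS, c(crossprod(X, y), crossprod(Z, y)))
  p <- ncol(X)
  list(b = sol[seq_len(p)], u = sol[-seq_len(p)])
}

# Brute-force G: explicit column loop, no matrix products
oracle_G <- function(dosages) {
  M <- dosages - 1
  n <- nrow(M); m <- ncol(M)
  G <- matrix(0, n, n)
  for (k in seq_len(m)) G <- G + outer(M[, k], M[, k])
  G / (m / 2)
}

# Brute-force S: sum of weighted rank-one terms
oracle_S <- function(dosages, weights) {
  M <- dosages[, names(weights), drop = FALSE] - 1
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (k in seq_along(weights)) S <- S + weights[k] * outer(M[, k], M[, k])
  S / (length(weights) / 2)
}

# Elementwise-loop sigma over the upper triangle incl. diagonal
oracle_sigma <- function(Tm, Gm) {
  d <- c()
  for (i in seq_len(nrow(Tm))) for (j in i:ncol(Tm)) d <- c(d, Tm[i, j] - Gm[i, j])
  sqrt(sum((d - mean(d))^2) / (length(d) - 1))
}

# Random genotype fixture with binomial dosages at random frequencies
rand_geno <- function(n, m, seed) {
  set.seed(seed)
  q <- runif(m, 0.1, 0.9)
  geno_matrix(matrix(rbinom(n * m, 2, rep(q, each = n)), n, m,
                     dimnames = list(paste0("i", 1:n), paste0("s", 1:m))))
}

# Phenotypes at a target variance-explained heritability, drawn from the
# kinship model: tbv ~ N(0, K), residual scaled against realized var(tbv)
sim_y_from_K <- function(K, h2, seed) {
  set.seed(seed)
  n <- nrow(K)
  L <- t(chol(unclass(K) + diag(1e-8 * mean(diag(K)), n)))
  tbv <- drop(L %*% rnorm(n))
  y <- if (h2 == 0) rnorm(n) else
    tbv + rnorm(n, sd = sqrt(var(tbv) * (1 - h2) / h2))
  list(tbv = tbv, y = y)
}

# Simple uniform map fixture over one or more chromosomes
toy_map <- function(marker_ids, n_chrom = 1L) {
  m <- length(marker_ids)
  per <- ceiling(m / n_chrom)
  marker_map(data.frame(
    marker_id = marker_ids,
    chromosome = paste0("chr", rep(seq_len(n_chrom), each = per)[seq_len(m)]),
    position = rep(seq_len(per), n_chrom)[seq_len(m)]))
}

# Reduced hyperparameter grid used by the simulation-backed tests (a
# subset of the default grid values, chosen for runtime, fixed up front)
small_grid <- function() {
  default_grid(omega = c(0, 0.02, 0.1, 0.3, 0.6),
               top_pct = c(0.0005, 0.005, 0.05),
               nflank = c(0L, 3L))
}
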