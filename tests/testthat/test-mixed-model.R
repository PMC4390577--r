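test_that("equivalent algorithm reproduces the direct MME solution", {
  # random small instances, some with unphenotyped individuals, K = G or T
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:30, 1)
    g <- rand_geno(n, 3 * n, seed = seed + 500)
    K <- unclass(build_G(g)) + diag(1e-6, n)  # invertible for the oracle
    nrec <- n - sample(0:floor(n / 5), 1)
    rec_ids <- sample(g$individual_ids, nrec)
    y <- rnorm(nrec)
    dm <- design_matrices(rec_ids, g$individual_ids)
    lam <- runif(1, 0.3, 3)

    b <- gls_fixed_effects(y, dm$X, dm$Z, K, lam)
    s <- solve_shat(y, dm$X, dm$Z, K, lam, b)
    u <- gebv_from_shat(K, dm$Z, s)
    mme <- oracle_mme(y, dm$X, dm$Z, K, lam)
    expect_lt(max(abs(b - mme$b)), 1e-10)
    expect_lt(max(abs(u - mme$u)), 1e-10)

    # same equivalence for a blended T matrix
    w <- build_D(setNames(runif(5, 0.2, 2), g$marker_ids[1:5]))
    Tm <- unclass(build_T(build_S(g, w), build_G(g), 0.4)) + diag(1e-6, n)
    bT <- gls_fixed_effects(y, dm$X, dm$Z, Tm, lam)
    sT <- solve_shat(y, dm$X, dm$Z, Tm, lam, bT)
    uT <- gebv_from_shat(Tm, dm$Z, sT)
    mmeT <- oracle_mme(y, dm$X, dm$Z, Tm, lam)
    expect_lt(max(abs(uT - mmeT$u)), 1e-10)
  }
})

test_that("closed-form special cases hold", {
  # V proportional to I makes GLS collapse to the plain mean
  I3 <- diag(3); dimnames(I3) <- list(letters[1:3], letters[1:3])
  dm <- design_matrices(letters[1:3], letters[1:3])
  y <- c(1, 2, 3)
  expect_equal(gls_fixed_effects(y, dm$X, dm$Z, I3, 1), 2)
  s <- solve_shat(y, dm$X, dm$Z, I3, 1, 2)
  expect_equal(unname(s), c(-0.5, 0, 0.5))
  expect_equal(unname(gebv_from_shat(I3, dm$Z, s)), c(-0.5, 0, 0.5))
  # y equal to the fitted fixed part gives a zero auxiliary vector
  expect_equal(unname(solve_shat(rep(2, 3), dm$X, dm$Z, I3, 1, 2)), rep(0, 3))

  # a candidate unrelated to every phenotyped individual predicts to zero
  K <- diag(4); K[4, 1:3] <- 0; K[1:3, 4] <- 0
  dimnames(K) <- list(letters[1:4], letters[1:4])
  dm4 <- design_matrices(letters[1:3], letters[1:4])
  s4 <- solve_shat(y, dm4$X, dm4$Z, K, 1, gls_fixed_effects(y, dm4$X, dm4$Z, K, 1))
  expect_equal(unname(gebv_from_shat(K, dm4$Z, s4)["d"]), 0)
})

test_that("RRBLUP marker effects satisfy the GBLUP equivalence M g = u", {
  m0 <- rbind(c(-1, 1), c(1, -1))
  expect_equal(unname(marker_effects_rrblup(m0, diag(2), c(0.5, -0.5), 1)),
               c(-1, 1))
  expect_equal(marker_effects_rrblup(m0, diag(2), c(0, 0), 1), c(0, 0),
               ignore_attr = TRUE)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    g <- rand_geno(n, 60, seed = seed + 900)
    G <- build_G(g)
    rec <- sample(g$individual_ids, 16)
    y <- rnorm(16)
    dm <- design_matrices(rec, g$individual_ids)
    fit <- fit_blup(y, dm$X, dm$Z, G, 1.2, geno = g)
    cg <- center_genotypes(g)
    expect_lt(max(abs(drop(cg$M %*% fit$marker_effects) - fit$gebv)), 1e-10)
  }
})

test_that("REML locates the restricted-likelihood optimum (grid oracle)", {
  g <- rand_geno(80, 300, seed = 77)
  K <- build_G(g)
  sim <- sim_y_from_K(K, 0.5, seed = 78)
  dm <- design_matrices(g$individual_ids, g$individual_ids)
  vc <- estimate_variance_components(sim$y, dm$X, dm$Z, K)
  expect_equal(vc$lambda, vc$sigma_e2 / vc$sigma_u2, tolerance = 1e-10)

  # independent 1000-point grid over the ratio parameter
  sp <- blupga:::reml_spectral(sim$y, dm$X, dm$Z, unclass(K))
  grid <- seq(1e-4, 1 - 1e-4, length.out = 1000)
  ll <- vapply(grid, function(gm) blupga:::reml_loglik((1 - gm) / gm, sp), 0)
  g_hat <- vc$sigma_u2 / (vc$sigma_u2 + vc$sigma_e2)
  expect_lt(abs(g_hat - grid[which.max(ll)]), diff(grid[1:2]) + 1e-8)
  expect_gte(vc$log_restricted_likelihood, max(ll) - 1e-6)
})

test_that("REML recovers simulated heritability and detects pure noise", {
  # moderate-scale parameter recovery (acceptance runs the full version)
  ests <- vapply(1:10, function(r) {
    g <- rand_geno(300, 800, seed = 4000 + r)
    K <- build_G(g)
    sim <- sim_y_from_K(K, 0.5, seed = 4100 + r)
    dm <- design_matrices(g$individual_ids, g$individual_ids)
    estimate_variance_components(sim$y, dm$X, dm$Z, K)$h2
  }, 0)
  expect_lt(abs(mean(ests) - 0.5), 0.07)

  # pure noise drives the estimate toward the zero boundary
  noise <- vapply(1:10, function(r) {
    g <- rand_geno(200, 400, seed = 6000 + r)
    K <- build_G(g)
    set.seed(6100 + r)
    dm <- design_matrices(g$individual_ids, g$individual_ids)
    estimate_variance_components(rnorm(200), dm$X, dm$Z, K)$h2
  }, 0)
  expect_gte(mean(noise < 0.1), 0.9)

  # identity kinship is non-identifiable
  I5 <- diag(50); dimnames(I5) <- list(paste0("i", 1:50), paste0("i", 1:50))
  dm <- design_matrices(paste0("i", 1:50), paste0("i", 1:50))
  expect_error(estimate_variance_components(rnorm(50), dm$X, dm$Z, I5),
               "not identifiable")
})

test_that("shrinkage behaves monotonically in lambda", {
  g <- rand_geno(25, 100, seed = 55)
  G <- unclass(build_G(g)) + diag(1e-6, 25)
  set.seed(56)
  y <- rnorm(25)
  dm <- design_matrices(g$individual_ids, g$individual_ids)
  norms <- vapply(c(0.01, 1, 100, 1e4), function(l) {
    fit <- fit_blup(y, dm$X, dm$Z, G, l)
    sqrt(sum(fit$gebv^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  # lambda -> 0 makes the fit interpolate the data
  fit0 <- fit_blup(y, dm$X, dm$Z, G, 1e-8)
  expect_lt(max(abs(fit0$b_hat + fit0$gebv - y)), 1e-4)
})

test_that("accuracy and unbiasedness match their closed forms", {
  expect_equal(accuracy(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3)), 1)
  expect_equal(accuracy(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1)), -1)
  expect_equal(as.numeric(unbiasedness(c(a = 1, b = 2, c = 3),
                                       c(a = 2, b = 4, c = 6))), 2)
  expect_equal(as.numeric(unbiasedness(c(a = 1, b = 2, c = 3),
                                       c(a = 1, b = 2, c = 3))), 1)
  set.seed(99)
  for (i in 1:5) {
    x <- rnorm(30); z <- rnorm(30)
    names(x) <- names(z) <- paste0("i", 1:30)
    # independent loop computation of r and the regression slope
    mx <- sum(x) / 30; mz <- sum(z) / 30
    sxy <- sxx <- szz <- 0
    for (k in 1:30) {
      sxy <- sxy + (x[k] - mx) * (z[k] - mz)
      sxx <- sxx + (x[k] - mx)^2
      szz <- szz + (z[k] - mz)^2
    }
    expect_equal(accuracy(x, z), unname(sxy / sqrt(sxx * szz)), tolerance = 1e-12)
    expect_equal(as.numeric(unbiasedness(x, z)), unname(sxy / sxx), tolerance = 1e-12)
    expect_equal(attr(unbiasedness(x, z), "reverse_slope"), unname(sxy / szz),
                 tolerance = 1e-12)
  }
  expect_error(accuracy(c(a = 1, b = 1, c = 1), c(a = 1, b = 2, c = 3)),
               "zero variance")
})
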