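test_that("fold plans partition, balance and reproduce", {
  ids <- paste0("i", 1:10)
  fp <- make_folds(ids, 5, 2, seed = 3)
  for (r in 1:2) {
    folds <- fp$assignments[[r]]
    expect_equal(lengths(folds), rep(2L, 5), ignore_attr = TRUE)
    expect_setequal(unlist(folds), ids)
  }
  expect_identical(make_folds(ids, 5, 2, seed = 3), fp)
  # n = 11, k = 5 -> sizes 3,2,2,2,2
  fp11 <- make_folds(paste0("i", 1:11), 5, 1, seed = 1)
  expect_equal(unname(sort(lengths(fp11$assignments[[1]]), decreasing = TRUE)),
               c(3L, 2L, 2L, 2L, 2L))
  expect_error(make_folds(ids, 11), "more folds")
})

make_small_sim <- function(seed, major = TRUE) {
  cfg <- sim_config(n_ref = 120L, n_cand = 40L, n_chrom = 2L,
                    markers_per_chrom = 150L, n_qtl = 300L,
                    effect_dist = "normal", h2 = 0.6,
                    major_share = if (major) 0.5 else 0, seed = seed)
  simulate_dataset(cfg)
}

test_that("run_fold guards leakage and degenerate folds", {
  sim <- make_small_sim(21)
  data <- as_wgp_data(sim)
  ref <- sim$reference_ids
  expect_error(run_fold(data, ref[1:80], ref[80:100], list(omega = 0, top_pct = 1, nflank = 0L)),
               "overlap")

  # omega = 0 equals a GBLUP-only run on the same split
  f0 <- run_fold(data, ref[1:90], ref[91:120], list(omega = 0, top_pct = 1, nflank = 0L))
  ctx <- blupga:::fold_context(data, ref[1:90], ref[91:120])
  expect_identical(f0$gebv, ctx$fit$gebv[ref[91:120]])

  # constant reference values flag NA instead of crashing
  data2 <- data
  data2$reference_values[ref[91:120]] <- 1
  expect_warning(
    fna <- run_fold(data2, ref[1:90], ref[91:120], list(omega = 0.2, top_pct = 0.01, nflank = 1L)),
    "degenerate fold")
  expect_true(is.na(fna$accuracy))
})

test_that("no-leakage: test phenotypes cannot influence marker selection", {
  sim <- make_small_sim(22)
  data <- as_wgp_data(sim)
  ref <- sim$reference_ids
  train <- ref[1:90]; test <- ref[91:120]
  sel_of <- function(d) {
    ctx <- blupga:::fold_context(d, train, test)
    names(selected_weights(ctx$fit$marker_effects, d$map, 0.01, 2))
  }
  perm <- data
  set.seed(1)
  perm$phenotypes[test] <- sample(perm$phenotypes[test])
  perm$reference_values <- perm$phenotypes
  expect_identical(sel_of(data), sel_of(perm))
})

test_that("grid search aggregates correctly and applies the tie-break", {
  sim <- make_small_sim(23)
  data <- as_wgp_data(sim)
  fp <- make_folds(sim$reference_ids, 3, 2, seed = 5)

  # omega-zero-only grid reduces to cross-validated GBLUP
  g0 <- default_grid(omega = 0, top_pct = 0.01, nflank = 0)
  res0 <- grid_search(fp, data, g0)
  expect_equal(nrow(res0$cells), 1L)
  expect_equal(res0$best_params$omega, 0)
  accs <- vapply(1:2, function(r) {
    folds <- fp$assignments[[r]]
    mean(vapply(seq_along(folds), function(f) {
      run_fold(data, setdiff(unlist(folds), folds[[f]]), folds[[f]],
               list(omega = 0, top_pct = 1, nflank = 0L))$accuracy
    }, 0))
  }, 0)
  expect_equal(res0$cells$accuracy, mean(accs), tolerance = 1e-12)

  # reported cell means equal the replicate-mean aggregation of fold metrics
  grid <- default_grid(omega = c(0, 0.3), top_pct = c(0.01, 0.05), nflank = 0)
  res <- grid_search(fp, data, grid)
  fm <- res$fold_metrics
  for (ci in seq_len(nrow(res$cells))) {
    sub <- fm[fm$omega == res$cells$omega[ci] & fm$top_pct == res$cells$top_pct[ci] &
                fm$nflank == res$cells$nflank[ci], ]
    repmeans <- tapply(sub$accuracy, sub$replicate, mean)
    expect_equal(res$cells$accuracy[ci], mean(repmeans), tolerance = 1e-12)
  }

  # ties break to the smaller omega, then top_pct, then nflank
  with_mocked_bindings(
    eval_cell = function(ctx, params, ...) list(accuracy = 0.5, unbiasedness = 1, gebv = NULL),
    {
      r <- grid_search(fp, data, grid)
      expect_equal(r$best_params$omega, 0)
    },
    .package = "blupga")
})

test_that("application stage predicts held-out candidates and reduces to GBLUP at omega 0", {
  sim <- make_small_sim(24)
  data <- as_wgp_data(sim)
  rep0 <- apply_stage(data, sim$reference_ids, sim$candidate_ids,
                      list(omega = 0, top_pct = 1, nflank = 0L))
  expect_identical(rep0$gebv_blupga, rep0$gebv_gblup)
  expect_error(apply_stage(data, sim$reference_ids,
                           c(sim$candidate_ids, sim$reference_ids[1]),
                           list(omega = 0, top_pct = 1, nflank = 0L)),
               "overlap")

  # candidates genetically unrelated to the reference predict near zero
  set.seed(77)
  g1 <- rand_geno(150, 400, seed = 771)
  g2 <- rand_geno(120, 400, seed = 772)
  rownames(g2$dosages) <- g2$individual_ids <- paste0("c", 1:120)
  both <- geno_matrix(rbind(g1$dosages, g2$dosages),
                      c(g1$individual_ids, g2$individual_ids), g1$marker_ids)
  mp <- toy_map(g1$marker_ids, 2)
  qtl <- data.frame(marker_id = sample(g1$marker_ids, 50),
                    effect = rnorm(50), is_major = FALSE)
  ph <- simulate_phenotypes(both, qtl, 0.5, seed = 773,
                            reference_ids = g1$individual_ids)
  # independent population: TBVs of candidates are re-simulated noise
  tbv <- ph$tbv
  tbv[g2$individual_ids] <- sample(tbv[g2$individual_ids])
  d <- wgp_data(both, mp, ph$phenotypes, tbv)
  repn <- apply_stage(d, g1$individual_ids, g2$individual_ids,
                      list(omega = 0.3, top_pct = 0.05, nflank = 1L))
  expect_lt(abs(repn$gblup_accuracy), 0.25)
  expect_lt(abs(repn$blupga_accuracy), 0.25)
})

test_that("major-gene simulation favors architecture-aware cells (directional)", {
  # reduced-scale version of the acceptance directional check: 3 replicates,
  # tiny grid; the full 10-replicate run lives in test-acceptance.R
  wins <- vapply(1:3, function(r) {
    cfg <- sim_config(n_ref = 200L, n_cand = 0L, n_chrom = 2L,
                      markers_per_chrom = 400L, n_qtl = 800L,
                      effect_dist = "normal", h2 = 0.6, major_share = 0.4,
                      seed = 300 + r)
    sim <- simulate_dataset(cfg)
    data <- as_wgp_data(sim)
    fp <- make_folds(sim$reference_ids, 4, 1, seed = r)
    res <- grid_search(fp, data,
                       default_grid(omega = c(0, 0.3), top_pct = 0.005, nflank = 2))
    acc <- res$cells$accuracy
    acc[res$cells$omega > 0] > acc[res$cells$omega == 0]
  }, TRUE)
  expect_gte(sum(wins), 2L)
})
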