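#' Bundle a dataset for the prediction workflow
#'
#' @param geno a [geno_matrix] covering every individual involved
#' @param map a [marker_map] aligned with the genotype columns
#' @param phenotypes named numeric vector (training responses; only
#'   reference individuals should carry one)
#' @param reference_values named numeric vector used to score predictions
#'   (conventional EBVs or simulated true breeding values); defaults to
#'   the phenotypes
#' @return list of class `wgp_data`
#' @export
wgp_data <- function(geno, map, phenotypes, reference_values = phenotypes) {
  check_alignment(geno, map, names(phenotypes))
  if (is.null(names(phenotypes))) stop_blupga("phenotypes must be named by individual")
  structure(list(geno = geno, map = map, phenotypes = phenotypes,
                 reference_values = reference_values), class = "wgp_data")
}

#' Plan cross-validation folds
#'
#' Random partition of the reference individuals into `n_folds` groups of
#' (near-)equal size, repeated `n_replicates` times. Each replicate's
#' assignment is seeded deterministically from the master seed.
#'
#' @param individual_ids reference individuals
#' @param n_folds folds per replicate (>= 2)
#' @param n_replicates number of repeated partitions
#' @param seed master seed
#' @return list of class `fold_plan`; `$assignments[[r]]` is a list of
#'   `n_folds` disjoint ID vectors covering all individuals
#' @export
make_folds <- function(individual_ids, n_folds = 5L, n_replicates = 1L, seed = 1L) {
  n <- length(individual_ids)
  if (n_folds > n) stop_blupga("more folds than individuals")
  if (n_folds < 2) stop_blupga("need at least 2 folds")
  assignments <- lapply(seq_len(n_replicates), function(r) {
    rs <- derive_seed(seed, paste0("folds/rep", r))
    old <- .Random.seed_save()
    set.seed(rs)
    ord <- sample(individual_ids)
    .Random.seed_restore(old)
    ## sizes differ by at most one: first (n %% k) folds get the extra
    sizes <- rep(n %/% n_folds, n_folds) + c(rep(1L, n %% n_folds),
                                             rep(0L, n_folds - n %% n_folds))
    split(ord, rep(seq_len(n_folds), times = sizes))
  })
  structure(list(n_folds = as.integer(n_folds),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), assignments = assignments),
            class = "fold_plan")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## Per-fold training context: everything that does not depend on the
## BLUP|GA cell. G is built over all individuals in `ids` (genotypes carry
## no phenotype information, so sharing G across folds leaks nothing);
## variance components, b, s and the RRBLUP effects use only training
## phenotypes.
fold_context <- function(data, train_ids, test_ids, G = NULL) {
  if (length(intersect(train_ids, test_ids)))
    stop_blupga("train and test sets overlap")
  ids <- data$geno$individual_ids
  if (is.null(G)) G <- build_G(data$geno)
  y <- data$phenotypes[train_ids]
  if (anyNA(y)) stop_blupga("training individual without phenotype")
  dm <- design_matrices(train_ids, ids)
  vc <- estimate_variance_components(y, dm$X, dm$Z, G)
  fit <- fit_blup(y, dm$X, dm$Z, G, vc$lambda, geno = data$geno, label = "G")
  list(data = data, train_ids = train_ids, test_ids = test_ids,
       ids = ids, y = y, X = dm$X, Z = dm$Z, G = G, vc = vc, fit = fit)
}

## Evaluate one hyperparameter cell inside a prepared fold context.
eval_cell <- function(ctx, params, variance_policy = "reuse_lambda",
                      transform = "abs") {
  stopifnot(all(c("omega", "top_pct", "nflank") %in% names(params)))
  if (params$omega == 0) {
    gebv <- ctx$fit$gebv[ctx$test_ids]
  } else {
    w <- selected_weights(ctx$fit$marker_effects, ctx$data$map,
                          params$top_pct, params$nflank, transform)
    S <- build_S(ctx$data$geno, w)
    Tm <- build_T(S, ctx$G, params$omega)
    lamT <- ctx$vc$lambda
    if (identical(variance_policy, "reestimate")) {
      lamT <- estimate_variance_components(ctx$y, ctx$X, ctx$Z, Tm)$lambda
    }
    fitT <- fit_blup(ctx$y, ctx$X, ctx$Z, Tm, lamT, label = "T")
    gebv <- fitT$gebv[ctx$test_ids]
  }
  ref <- ctx$data$reference_values[ctx$test_ids]
  if (length(ref) < 3 || stats::sd(ref) == 0 || stats::sd(gebv) == 0) {
    warning("degenerate fold (constant GEBV or reference); metrics recorded as NA")
    return(list(accuracy = NA_real_, unbiasedness = NA_real_, gebv = gebv))
  }
  list(accuracy = accuracy(gebv, ref),
       unbiasedness = as.numeric(unbiasedness(gebv, ref)),
       gebv = gebv)
}

#' Evaluate one cross-validation fold at one hyperparameter setting
#'
#' Runs the core algorithm on the training individuals only — variance
#' components, the auxiliary solve, RRBLUP marker effects, top-SNP
#' selection and the S/T build all see training phenotypes exclusively —
#' then predicts the held-out individuals through their kinship rows and
#' scores accuracy and unbiasedness against the reference values.
#'
#' @param data a [wgp_data]
#' @param train_ids,test_ids disjoint individual ID vectors
#' @param params list or one-row data.frame with `omega`, `top_pct`,
#'   `nflank`
#' @param variance_policy `"reuse_lambda"` (lambda for T reused from the
#'   G fit) or `"reestimate"` (variance components re-estimated under T)
#' @param transform weight transform for [build_D]
#' @return list with `accuracy`, `unbiasedness`, `gebv` (test individuals)
#' @export
run_fold <- function(data, train_ids, test_ids, params,
                     variance_policy = "reuse_lambda", transform = "abs") {
  ctx <- fold_context(data, train_ids, test_ids)
  eval_cell(ctx, as.list(params), variance_policy, transform)
}

#' Cross-validated grid search over the BLUP|GA hyperparameters
#'
#' For every fold of every replicate, the fold's training-only context
#' (variance components, auxiliary vector, marker effects) is computed
#' once and reused across all grid cells; each cell then only rebuilds S
#' and T and re-solves the blended model. The best cell maximizes the mean
#' accuracy across folds and replicates; ties go to the smaller omega,
#' then smaller top_pct, then smaller nflank.
#'
#' @param fold_plan a [make_folds] plan over the reference individuals
#' @param data a [wgp_data]
#' @param grid data.frame of cells from [default_grid]
#' @inheritParams run_fold
#' @return list of class `grid_search_result`: `cells` (per-cell mean and
#'   SE of accuracy and unbiasedness, fold-pooled and replicate-averaged),
#'   `best_params`, `fold_metrics`
#' @export
grid_search <- function(fold_plan, data, grid,
                        variance_policy = "reuse_lambda", transform = "abs") {
  if (!nrow(grid)) stop_blupga("empty grid")
  G <- build_G(data$geno)
  recs <- list()
  for (r in seq_len(fold_plan$n_replicates)) {
    folds <- fold_plan$assignments[[r]]
    for (f in seq_along(folds)) {
      test_ids <- folds[[f]]
      train_ids <- setdiff(unlist(folds), test_ids)
      ctx <- fold_context(data, train_ids, test_ids, G = G)
      for (ci in seq_len(nrow(grid))) {
        met <- eval_cell(ctx, as.list(grid[ci, ]), variance_policy, transform)
        recs[[length(recs) + 1L]] <- data.frame(
          replicate = r, fold = f, cell = ci,
          omega = grid$omega[ci], top_pct = grid$top_pct[ci],
          nflank = grid$nflank[ci],
          accuracy = met$accuracy, unbiasedness = met$unbiasedness)
      }
    }
  }
  fm <- do.call(rbind, recs)
  ## replicate-level means are canonical; fold-pooled means also reported
  rep_means <- stats::aggregate(cbind(accuracy, unbiasedness) ~ cell + replicate,
                                fm, mean, na.action = stats::na.omit)
  cells <- stats::aggregate(cbind(accuracy, unbiasedness) ~ cell, rep_means, mean)
  se <- stats::aggregate(accuracy ~ cell, rep_means,
                         function(a) stats::sd(a) / sqrt(length(a)))
  pooled <- stats::aggregate(accuracy ~ cell, fm, mean, na.action = stats::na.omit)
  cells <- merge(cells, stats::setNames(se, c("cell", "accuracy_se")), by = "cell")
  cells <- merge(cells, stats::setNames(pooled, c("cell", "accuracy_pooled")),
                 by = "cell")
  cells <- cbind(grid[cells$cell, , drop = FALSE], cells[, -1, drop = FALSE])
  rownames(cells) <- NULL
  ord <- order(-round(cells$accuracy, 12), cells$omega, cells$top_pct, cells$nflank)
  best <- cells[ord[1], c("omega", "top_pct", "nflank")]
  structure(list(cells = cells, best_params = as.list(best), fold_metrics = fm),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  b <- x$best_params
  cat(sprintf("grid search: %d cells; best omega=%g top_pct=%g nflank=%d (mean acc %.4f)\n",
              nrow(x$cells), b$omega, b$top_pct, b$nflank,
              max(x$cells$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Application stage: predict never-seen candidates
#'
#' Runs the core algorithm once on the combined reference + candidate
#' data, with phenotypes entering only from the reference individuals, and
#' reports candidate accuracy and unbiasedness for both GBLUP and BLUP|GA
#' at the supplied parameters.
#'
#' @param data a [wgp_data] whose genotypes cover reference and candidates
#' @param reference_ids,candidate_ids disjoint ID vectors
#' @param best_params list with `omega`, `top_pct`, `nflank` (typically
#'   `grid_search(...)$best_params`)
#' @inheritParams run_fold
#' @return list of class `stage_report`: GEBVs and metrics for both models
#' @export
apply_stage <- function(data, reference_ids, candidate_ids, best_params,
                        variance_policy = "reuse_lambda", transform = "abs") {
  if (length(intersect(reference_ids, candidate_ids)))
    stop_blupga("candidates overlap the reference population")
  ctx <- fold_context(data, reference_ids, candidate_ids)
  gblup <- eval_cell(ctx, list(omega = 0, top_pct = 1, nflank = 0L))
  bga <- eval_cell(ctx, as.list(best_params), variance_policy, transform)
  structure(list(stage = "application", best_params = as.list(best_params),
                 variance_components = ctx$vc,
                 gblup_accuracy = gblup$accuracy, gblup_unbiasedness = gblup$unbiasedness,
                 blupga_accuracy = bga$accuracy, blupga_unbiasedness = bga$unbiasedness,
                 gebv_gblup = gblup$gebv, gebv_blupga = bga$gebv),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("application stage: GBLUP acc %.4f | BLUP|GA acc %.4f (omega=%g, top=%g, nflank=%d)\n",
              x$gblup_accuracy, x$blupga_accuracy, x$best_params$omega,
              x$best_params$top_pct, x$best_params$nflank))
  invisible(x)
}
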