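#' Simulation configuration
#'
#' Describes a synthetic genomic-prediction dataset: population sizes,
#' genome layout, QTL architecture and heritability. Genotypes come from a
#' per-chromosome AR(1) Gaussian copula thresholded to Hardy-Weinberg
#' dosages — a lightweight stand-in for coalescent simulation that
#' reproduces the qualitative local-LD structure the flanking-SNP
#' parameter relies on.
#'
#' @param n_ref,n_cand reference (phenotyped) and candidate counts
#' @param n_chrom,markers_per_chrom genome layout
#' @param n_qtl number of causal markers (sampled among the markers)
#' @param effect_dist `"normal"` (standard normal) or `"gamma"`
#'   (gamma(shape, scale) magnitudes with independent random signs)
#' @param gamma_shape,gamma_scale gamma parameters (used when
#'   `effect_dist = "gamma"`)
#' @param h2 target heritability of the simulated phenotype in `[0, 1]`
#' @param maf_min lower bound of the uniform allele-frequency draw
#' @param ld_rho adjacent-marker latent correlation in `[0, 1)`
#' @param major_share fraction of genetic variance fixed on one major QTL
#'   (0 = none)
#' @param mask_qtl drop QTL columns from the emitted marker panel
#'   (emulates designs whose causal loci are not on the SNP chip)
#' @param seed master seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_ref = 600L, n_cand = 300L, n_chrom = 3L,
                       markers_per_chrom = 1000L, n_qtl = 300L,
                       effect_dist = c("normal", "gamma"),
                       gamma_shape = 0.4, gamma_scale = 1.66,
                       h2 = 0.5, maf_min = 0.05, ld_rho = 0.5,
                       major_share = 0, mask_qtl = FALSE, seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  m <- n_chrom * markers_per_chrom
  if (n_qtl > m) stop_blupga("n_qtl exceeds the number of markers")
  if (h2 < 0 || h2 > 1) stop_blupga("h2 must lie in [0, 1]")
  if (ld_rho < 0 || ld_rho >= 1) stop_blupga("ld_rho must lie in [0, 1)")
  if (maf_min <= 0 || maf_min >= 0.5) stop_blupga("maf_min must lie in (0, 0.5)")
  if (major_share < 0 || major_share >= 1) stop_blupga("major_share must lie in [0, 1)")
  structure(list(n_ref = as.integer(n_ref), n_cand = as.integer(n_cand),
                 n_chrom = as.integer(n_chrom),
                 markers_per_chrom = as.integer(markers_per_chrom),
                 n_qtl = as.integer(n_qtl), effect_dist = effect_dist,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 h2 = h2, maf_min = maf_min, ld_rho = ld_rho,
                 major_share = major_share, mask_qtl = isTRUE(mask_qtl),
                 seed = as.integer(seed)), class = "sim_config")
}

#' Named simulation presets
#'
#' `gsa_gamma` / `gsa_normal` emulate the simulated-livestock validation
#' design (2,000 reference + 1,500 candidate individuals, 900 candidate
#' QTL, heritability 0.25, gamma(0.4, 1.66) or standard-normal effects) on
#' a 10,000-marker panel — a 6x marker-panel scale-down of the original
#' 60,000-SNP genome with the QTL count scaled to match. `qtlmas_like`
#' mirrors the five-chromosome, 4,000-SNPs-per-chromosome workshop design
#' with 50 gamma(0.42, 5.4) QTL, 3,000 training and 1,000 validation
#' individuals at heritability 0.36. `major_gene` places 30% of the
#' genetic variance on a single QTL over an otherwise polygenic
#' background, emulating a major-gene trait; `polygenic` is its matched
#' all-small-effects control.
#'
#' @param name preset name
#' @param seed master seed stored in the config
#' @return a [sim_config]
#' @export
preset <- function(name, seed = 1L) {
  cfgs <- list(
    gsa_gamma = sim_config(n_ref = 2000L, n_cand = 1500L, n_chrom = 5L,
                           markers_per_chrom = 2000L, n_qtl = 900L,
                           effect_dist = "gamma", gamma_shape = 0.4,
                           gamma_scale = 1.66, h2 = 0.25, seed = seed),
    gsa_normal = sim_config(n_ref = 2000L, n_cand = 1500L, n_chrom = 5L,
                            markers_per_chrom = 2000L, n_qtl = 900L,
                            effect_dist = "normal", h2 = 0.25, seed = seed),
    qtlmas_like = sim_config(n_ref = 3000L, n_cand = 1000L, n_chrom = 5L,
                             markers_per_chrom = 4000L, n_qtl = 50L,
                             effect_dist = "gamma", gamma_shape = 0.42,
                             gamma_scale = 5.4, h2 = 0.36, seed = seed),
    major_gene = sim_config(n_ref = 600L, n_cand = 300L, n_chrom = 3L,
                            markers_per_chrom = 1000L, n_qtl = 3000L,
                            effect_dist = "normal", h2 = 0.5,
                            major_share = 0.30, seed = seed),
    polygenic = sim_config(n_ref = 600L, n_cand = 300L, n_chrom = 3L,
                           markers_per_chrom = 1000L, n_qtl = 3000L,
                           effect_dist = "normal", h2 = 0.5, seed = seed))
  if (!name %in% names(cfgs))
    stop_blupga("unknown preset '%s'; valid: %s", name,
                paste(names(cfgs), collapse = ", "))
  cfgs[[name]]
}

#' Simulate genotypes with local linkage disequilibrium
#'
#' Two latent AR(1) Gaussian haplotype processes per individual and
#' chromosome are thresholded at the allele-frequency quantile, giving
#' Hardy-Weinberg dosages whose adjacent-marker correlation rises with
#' `ld_rho`. Allele frequencies are drawn uniform(maf_min, 1 - maf_min).
#'
#' @param config a [sim_config]
#' @return list with `geno` ([geno_matrix] over reference then candidate
#'   individuals) and `map` ([marker_map], 1-based positions)
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_ref + config$n_cand
  L <- config$markers_per_chrom
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "genotypes"))
  rho <- config$ld_rho
  blocks <- vector("list", config$n_chrom)
  for (ch in seq_len(config$n_chrom)) {
    ## allele frequencies share the AR(1) smoothness of the haplotypes:
    ## within an LD block neighbouring markers have similar frequencies,
    ## which keeps the dosage-scale correlation close to the latent rho
    qlat <- stats::rnorm(L)
    if (rho > 0 && L > 1) {
      w <- sqrt(1 - rho^2)
      for (j in 2:L) qlat[j] <- rho * qlat[j - 1] + w * qlat[j]
    }
    q <- config$maf_min + (1 - 2 * config$maf_min) * stats::pnorm(qlat)
    thr <- stats::qnorm(q)  # latent below threshold => carry the counted allele
    dos <- matrix(0L, n, L)
    for (hap in 1:2) {
      z <- matrix(stats::rnorm(n * L), n, L)
      if (rho > 0 && L > 1) {
        w <- sqrt(1 - rho^2)
        for (j in 2:L) z[, j] <- rho * z[, j - 1] + w * z[, j]
      }
      dos <- dos + (z < rep(thr, each = n))
    }
    blocks[[ch]] <- dos
  }
  dosages <- do.call(cbind, blocks)
  ids <- c(sprintf("ref%04d", seq_len(config$n_ref)),
           sprintf("cand%04d", seq_len(config$n_cand)))
  mids <- as.vector(t(outer(seq_len(config$n_chrom), seq_len(L),
                            function(c, j) sprintf("chr%d_m%04d", c, j))))
  map <- marker_map(data.frame(
    marker_id = mids,
    chromosome = rep(sprintf("chr%d", seq_len(config$n_chrom)), each = L),
    position = rep(seq_len(L), config$n_chrom)))
  list(geno = geno_matrix(dosages, ids, mids), map = map)
}

#' Draw QTL positions and effects
#'
#' Samples `n_qtl` markers without replacement and draws their additive
#' effects from the configured distribution; gamma magnitudes receive an
#' independent random sign with probability one half. When `major_share`
#' is positive the first sampled QTL is flagged as the major gene (its
#' effect is fixed later, against the realized polygenic variance).
#'
#' @param config a [sim_config]
#' @param marker_ids panel marker IDs to sample from
#' @return data.frame with `marker_id`, `effect`, `is_major`
#' @export
simulate_qtl_effects <- function(config, marker_ids) {
  if (config$n_qtl > length(marker_ids)) stop_blupga("n_qtl exceeds panel size")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "qtl"))
  qtl <- sample(marker_ids, config$n_qtl)
  eff <- if (config$effect_dist == "gamma") {
    mag <- stats::rgamma(config$n_qtl, shape = config$gamma_shape,
                         scale = config$gamma_scale)
    mag * sample(c(-1, 1), config$n_qtl, replace = TRUE)
  } else {
    stats::rnorm(config$n_qtl)
  }
  is_major <- rep(FALSE, config$n_qtl)
  if (config$major_share > 0) is_major[1] <- TRUE
  data.frame(marker_id = qtl, effect = eff, is_major = is_major,
             stringsAsFactors = FALSE)
}

#' Simulate phenotypes at a target heritability
#'
#' True breeding values are the centered QTL dosages times the effects;
#' the residual variance is set to `var(tbv) * (1 - h2) / h2` so the
#' realized heritability on the reference sample matches the target in
#' expectation. `h2 = 1` returns the TBV as phenotype; `h2 = 0` returns
#' standard-normal noise (TBV still emitted for null testing).
#'
#' @param geno a [geno_matrix]
#' @param qtl data.frame from [simulate_qtl_effects]
#' @param h2 target heritability
#' @param seed seed for the residual draw
#' @param reference_ids individuals that receive a phenotype (default all)
#' @return list with `tbv` (all individuals), `phenotypes` (reference
#'   only), `realized_h2`
#' @export
simulate_phenotypes <- function(geno, qtl, h2, seed,
                                reference_ids = geno$individual_ids) {
  Mq <- scale(geno$dosages[, qtl$marker_id, drop = FALSE], scale = FALSE)
  tbv <- drop(Mq %*% qtl$effect)
  names(tbv) <- geno$individual_ids
  vg <- stats::var(tbv[reference_ids])
  if (vg == 0 && h2 > 0) stop_blupga("TBV variance is zero; cannot hit h2 > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "phenotypes"))
  if (h2 == 0) {
    y <- stats::rnorm(length(reference_ids))
  } else {
    ve <- vg * (1 - h2) / h2
    y <- tbv[reference_ids] + stats::rnorm(length(reference_ids), sd = sqrt(ve))
  }
  names(y) <- reference_ids
  list(tbv = tbv, phenotypes = y,
       realized_h2 = if (h2 == 0) 0 else vg / stats::var(y))
}

#' Generate a complete simulated dataset
#'
#' Genotypes, map, QTL, true breeding values and reference phenotypes in
#' one call. With `major_share > 0` the major QTL's effect is set so that
#' its realized variance contribution is exactly that share of the total
#' genetic variance on the combined sample. With `mask_qtl = TRUE` the QTL
#' columns are removed from the emitted panel after TBV construction.
#'
#' @param config a [sim_config]
#' @return list of class `sim_dataset`: `geno`, `map`, `qtl`, `tbv`,
#'   `phenotypes`, `reference_ids`, `candidate_ids`, `realized_h2`,
#'   `config`
#' @export
simulate_dataset <- function(config) {
  gm <- simulate_genotypes(config)
  qtl <- simulate_qtl_effects(config, gm$geno$marker_ids)
  if (config$major_share > 0) {
    X <- scale(gm$geno$dosages[, qtl$marker_id, drop = FALSE], scale = FALSE)
    i <- which(qtl$is_major)
    small <- drop(X[, -i, drop = FALSE] %*% qtl$effect[-i])
    vsmall <- stats::var(small)
    vx <- stats::var(X[, i])
    ## share s of total: var_major = s/(1-s) * var_small (contributions
    ## near-orthogonal for a randomly placed QTL)
    qtl$effect[i] <- sign(qtl$effect[i]) *
      sqrt(config$major_share / (1 - config$major_share) * vsmall / vx)
  }
  ref_ids <- gm$geno$individual_ids[seq_len(config$n_ref)]
  cand_ids <- setdiff(gm$geno$individual_ids, ref_ids)
  ph <- simulate_phenotypes(gm$geno, qtl, config$h2, config$seed, ref_ids)
  geno <- gm$geno; map <- gm$map
  if (config$mask_qtl) {
    keep <- setdiff(geno$marker_ids, qtl$marker_id)
    geno <- geno_matrix(geno$dosages[, keep, drop = FALSE],
                        geno$individual_ids, keep)
    map <- marker_map(map[map$marker_id %in% keep,
                          c("marker_id", "chromosome", "position")])
  }
  structure(list(geno = geno, map = map, qtl = qtl, tbv = ph$tbv,
                 phenotypes = ph$phenotypes, reference_ids = ref_ids,
                 candidate_ids = cand_ids, realized_h2 = ph$realized_h2,
                 config = config), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d ref + %d cand, %d markers, %d QTL, realized h2 %.3f\n",
              length(x$reference_ids), length(x$candidate_ids),
              length(x$geno$marker_ids), nrow(x$qtl), x$realized_h2))
  invisible(x)
}

#' Convert a simulated dataset to workflow input
#'
#' @param sim a `sim_dataset`
#' @return a [wgp_data] scoring predictions against the true breeding values
#' @export
as_wgp_data <- function(sim) {
  wgp_data(sim$geno, sim$map, sim$phenotypes, reference_values = sim$tbv)
}
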