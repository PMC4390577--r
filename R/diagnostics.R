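#' Cumulative genetic-variance curve over ranked markers
#'
#' The genetic variance attributed to each marker is `2 p (1 - p) alpha^2`
#' with `p` the observed allele frequency and `alpha` the estimated
#' substitution effect (RRBLUP effect). Markers are sorted by `|alpha|`
#' descending (ties by input/map order) and the per-marker variances are
#' accumulated and normalized to end at 1. A steep initial rise — a large
#' share of variance in a small fraction of top SNPs — flags a trait where
#' an architecture-aware model can beat GBLUP.
#'
#' @param marker_effects named numeric vector in map order
#' @param allele_freqs frequencies of the counted allele, in `[0, 1]`,
#'   aligned with the effects
#' @return data.frame with `marker_id`, `abs_effect`, `variance`,
#'   `cumulative_fraction`
#' @export
variance_explained_curve <- function(marker_effects, allele_freqs) {
  if (length(marker_effects) != length(allele_freqs))
    stop_blupga("effects and frequencies are not aligned")
  if (any(allele_freqs < 0 | allele_freqs > 1))
    stop_blupga("allele frequencies must lie in [0, 1]")
  v <- 2 * allele_freqs * (1 - allele_freqs) * marker_effects^2
  tot <- sum(v)
  if (tot == 0) stop_blupga("total genetic variance is zero")
  ord <- order(-abs(marker_effects), seq_along(marker_effects))
  data.frame(marker_id = names(marker_effects)[ord] %||% as.character(ord),
             abs_effect = abs(marker_effects)[ord],
             variance = v[ord],
             cumulative_fraction = cumsum(v[ord]) / tot,
             row.names = NULL)
}

#' Observed allele frequency of the counted allele per marker
#'
#' @param geno a [geno_matrix]
#' @return named numeric vector, `colMeans(dosage) / 2`
#' @export
allele_frequencies <- function(geno) colMeans(geno$dosages) / 2

#' Rescale marker effects to mean absolute value 1
#'
#' Puts effect profiles from different traits or population sizes on a
#' common scale for Manhattan-plot comparison; signs are preserved.
#'
#' @param marker_effects numeric vector, not all zero
#' @return rescaled vector with `mean(abs(.)) == 1`
#' @export
rescale_effects_mean_abs_one <- function(marker_effects) {
  m <- mean(abs(marker_effects))
  if (m == 0) stop_blupga("all effects are zero")
  marker_effects / m
}

#' Zero-intercept regression of the accuracy gain on the matrix distance
#'
#' Regresses `delta` (accuracy of BLUP|GA minus accuracy of GBLUP) on
#' `sigma` (the T-G distance from [matrix_distance_sigma]) through the
#' origin — zero is the expectation when T equals G. Returns the slope
#' `sum(sigma * delta) / sum(sigma^2)` with its standard error, t statistic
#' and p-value under the zero-intercept model.
#'
#' @param points data.frame with columns `sigma` (>= 0) and `delta`
#' @return list with `slope`, `se`, `t`, `p_value`, `df`
#' @export
delta_sigma_regression <- function(points) {
  stopifnot(all(c("sigma", "delta") %in% names(points)))
  s <- points$sigma; d <- points$delta
  if (length(s) < 2) stop_blupga("need at least 2 points")
  if (all(s == 0)) stop_blupga("all sigma are zero")
  slope <- sum(s * d) / sum(s^2)
  df <- length(s) - 1L
  rss <- sum((d - slope * s)^2)
  se <- sqrt(rss / df / sum(s^2))
  tval <- slope / se
  list(slope = slope, se = se, t = tval,
       p_value = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Order a relationship matrix by the genotype of a top marker
#'
#' Permutes rows and columns so individuals are grouped by their dosage
#' (0, then 1, then 2) at the named marker, ties keeping original order —
#' the ordering that makes the block structure of an S matrix driven by a
#' major gene visible in a heat map.
#'
#' @param K relationship matrix with individual dimnames
#' @param geno a [geno_matrix]
#' @param top_marker_id the marker to sort by
#' @return list with `matrix` (permuted) and `permutation` (ID order)
#' @export
order_by_top_genotype <- function(K, geno, top_marker_id) {
  if (!top_marker_id %in% geno$marker_ids)
    stop_blupga("unknown marker: %s", top_marker_id)
  ids <- rownames(K)
  if (is.null(ids)) stop_blupga("matrix must carry individual IDs")
  dos <- geno$dosages[ids, top_marker_id]
  ord <- order(dos, seq_along(dos))
  list(matrix = K[ord, ord], permutation = ids[ord])
}
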