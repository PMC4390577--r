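#' Select the markers with the largest estimated effects
#'
#' Picks the `k = max(1, round(top_pct * m))` markers with the largest
#' absolute effect (round half up, so percentages like 0.01% still select
#' one marker on small panels). Ties are broken by map order: the earlier
#' marker wins, making selection fully deterministic.
#'
#' @param marker_effects named numeric vector in map order
#' @param top_pct fraction of markers to select, in `(0, 1]`
#' @return character vector of selected marker IDs, in map order
#' @export
select_top_snps <- function(marker_effects, top_pct) {
  m <- length(marker_effects)
  if (!m) stop_blupga("no marker effects supplied")
  if (top_pct <= 0 || top_pct > 1) stop_blupga("top_pct must be in (0, 1]")
  k <- max(1L, as.integer(floor(top_pct * m + 0.5)))
  ord <- order(-abs(marker_effects), seq_len(m))
  sel <- sort(ord[seq_len(k)])
  names(marker_effects)[sel]
}

#' Expand top markers with their map-adjacent flanking SNPs
#'
#' Adds up to `nflank` markers on each side of every top SNP, by map rank
#' within the same chromosome (adjacency, not base-pair distance), then
#' deduplicates. Flanking SNPs account for linkage disequilibrium between a
#' top SNP and its neighbourhood.
#'
#' @param top_ids character vector of top marker IDs
#' @param map a [marker_map]
#' @param nflank non-negative integer, flanking SNPs per side
#' @return data.frame with columns `marker_id`, `is_top`, ordered by map
#' @export
expand_flanks <- function(top_ids, map, nflank = 0L) {
  if (nflank < 0) stop_blupga("nflank must be >= 0")
  idx <- match(top_ids, map$marker_id)
  if (anyNA(idx)) stop_blupga("top marker absent from map: %s",
                              paste(top_ids[is.na(idx)][1]))
  keep <- integer(0)
  for (i in idx) {
    chrom <- map$chromosome[i]
    lo <- i; hi <- i
    while (lo > 1 && map$chromosome[lo - 1] == chrom && (i - lo) < nflank) lo <- lo - 1
    while (hi < nrow(map) && map$chromosome[hi + 1] == chrom && (hi - i) < nflank) hi <- hi + 1
    keep <- c(keep, lo:hi)
  }
  keep <- sort(unique(keep))
  data.frame(marker_id = map$marker_id[keep],
             is_top = map$marker_id[keep] %in% top_ids,
             stringsAsFactors = FALSE)
}

#' Assemble the selected-SNP weight vector for S
#'
#' Combines top-SNP selection, flank expansion and D construction: every
#' selected marker (top or flank) carries its own estimated effect into
#' the diagonal weights.
#'
#' @param marker_effects named effects in map order
#' @param map a [marker_map]
#' @param top_pct,nflank selection parameters
#' @param transform passed to [build_D]
#' @return named weight vector (mean 1) suitable for [build_S]
#' @export
selected_weights <- function(marker_effects, map, top_pct, nflank = 0L,
                             transform = "abs") {
  top <- select_top_snps(marker_effects, top_pct)
  sel <- expand_flanks(top, map, nflank)
  build_D(marker_effects[sel$marker_id], transform)
}

#' Default BLUP|GA hyperparameter grid
#'
#' Cartesian grid over `omega`, `top_pct` and `nflank`. All omega = 0 cells
#' describe the same GBLUP model, so they collapse to a single row.
#' Defaults span the parameter ranges reported as optimal in practice
#' (top fractions from 0.01% to 5%, omega up to 0.8, flanks 0/3/5).
#'
#' @param omega,top_pct,nflank value lists overriding the defaults
#' @return data.frame with one row per distinct grid cell
#' @export
default_grid <- function(omega = c(0, 0.02, 0.04, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8),
                         top_pct = c(0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05),
                         nflank = c(0L, 3L, 5L)) {
  if (any(omega < 0 | omega > 1)) stop_blupga("omega values must lie in [0, 1]")
  if (any(top_pct <= 0 | top_pct > 1)) stop_blupga("top_pct values must lie in (0, 1]")
  g <- expand.grid(nflank = as.integer(nflank), top_pct = top_pct,
                   omega = omega, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("omega", "top_pct", "nflank")]
  zero <- g$omega == 0
  if (any(zero)) {
    g <- rbind(data.frame(omega = 0, top_pct = top_pct[1], nflank = as.integer(nflank[1])),
               g[!zero, ])
  }
  g <- g[order(g$omega, g$top_pct, g$nflank), ]
  rownames(g) <- NULL
  g
}
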