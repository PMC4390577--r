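#' Center genotype dosages for relationship-matrix construction
#'
#' Dosages are adjusted by twice the allele frequency in each column. The
#' package follows the convention of fixing p = 0.5 for every SNP when
#' building relationship matrices (the choice of p does not affect
#' prediction accuracy), so the centered matrix is simply `dosage - 1` and
#' the normalization constant is `c = 2 * sum(p_i * (1 - p_i)) = m / 2`
#' over the m columns used.
#'
#' @param geno a [geno_matrix]
#' @param marker_subset character vector of marker IDs (default all)
#' @return list with `M` (centered matrix), `scale_constant`, `marker_ids`
#' @export
center_genotypes <- function(geno, marker_subset = NULL) {
  if (is.null(marker_subset)) marker_subset <- geno$marker_ids
  if (!length(marker_subset)) stop_blupga("marker subset is empty")
  miss <- setdiff(marker_subset, geno$marker_ids)
  if (length(miss)) stop_blupga("markers not in genotypes: %s",
                                paste(utils::head(miss, 5), collapse = ", "))
  M <- geno$dosages[, marker_subset, drop = FALSE] - 1
  list(M = M, scale_constant = length(marker_subset) / 2,
       marker_ids = marker_subset)
}

new_relmat <- function(values, label) {
  structure(values, label = label, class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d x %d\n",
              attr(x, "label") %||% "?", nrow(x), ncol(x)))
  invisible(x)
}

#' Build the genomic relationship matrix G
#'
#' `G = M M' / c` with `M` the centered dosage matrix over all markers and
#' `c = m / 2` under the fixed p = 0.5 convention.
#'
#' @param geno a [geno_matrix] with at least 2 individuals
#' @return symmetric PSD matrix of class `relmat`, label `"G"`
#' @export
build_G <- function(geno) {
  if (nrow(geno$dosages) < 2) stop_blupga("need at least 2 individuals")
  cg <- center_genotypes(geno)
  G <- tcrossprod(cg$M) / cg$scale_constant
  new_relmat((G + t(G)) / 2, "G")
}

#' Build the diagonal SNP-weight matrix D
#'
#' The diagonal of D carries the estimated marker effects of the selected
#' SNPs, transformed to be sign-safe (absolute values by default, squares
#' as an option) and rescaled so that `mean(diag(D)) == 1`, keeping S on
#' the same scale as G.
#'
#' @param selected_effects named numeric vector of estimated effects for
#'   the selected markers
#' @param transform `"abs"` (default) or `"square"`
#' @return named numeric vector of weights with mean exactly 1
#' @export
build_D <- function(selected_effects, transform = c("abs", "square")) {
  transform <- match.arg(transform)
  if (!length(selected_effects)) stop_blupga("no selected effects")
  w <- switch(transform, abs = abs(selected_effects), square = selected_effects^2)
  mw <- mean(w)
  if (mw == 0) stop_blupga("all selected effects are zero; cannot rescale D")
  w / mw
}

#' Build the genetic-architecture matrix S
#'
#' `S = M1 D M1' / c1` where `M1` is the centered genotype matrix of the
#' selected SNPs, `D` the diagonal weight matrix from [build_D], and
#' `c1 = m1 / 2` sums `2 p (1 - p)` over the m1 selected columns (p = 0.5).
#' With all markers selected and unit weights, S reduces to G exactly.
#'
#' @param geno a [geno_matrix]
#' @param weights named weight vector from [build_D]; names select the SNPs
#' @return symmetric PSD matrix of class `relmat`, label `"S"`
#' @export
build_S <- function(geno, weights) {
  if (!length(weights)) stop_blupga("no selected markers")
  if (is.null(names(weights))) stop_blupga("weights must be named by marker ID")
  if (any(weights < 0)) stop_blupga("D weights must be non-negative")
  cg <- center_genotypes(geno, names(weights))
  MW <- sweep(cg$M, 2, weights, `*`)
  S <- tcrossprod(MW, cg$M) / cg$scale_constant
  new_relmat((S + t(S)) / 2, "S")
}

#' Blend S and G into the trait-specific matrix T
#'
#' `T = omega * S + (1 - omega) * G`; omega is the overall weight on the
#' genetic-architecture part. omega = 0 recovers GBLUP, omega = 1 uses S
#' alone.
#'
#' @param S,G conformable relationship matrices over the same individuals
#'   in the same order
#' @param omega blend weight in `[0, 1]`
#' @return matrix of class `relmat`, label `"T"`
#' @export
build_T <- function(S, G, omega) {
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0 || omega > 1)
    stop_blupga("omega must be a single value in [0, 1]")
  if (!identical(dim(S), dim(G))) stop_blupga("S and G are not conformable")
  if (!is.null(rownames(S)) && !is.null(rownames(G)) &&
      !identical(rownames(S), rownames(G)))
    stop_blupga("S and G individual orderings differ")
  new_relmat(omega * unclass(S) + (1 - omega) * unclass(G), "T")
}

#' Distance between two relationship matrices
#'
#' The standard deviation of the element-wise differences `T_ij - G_ij`,
#' taken over the upper triangle including the diagonal (each distinct
#' element once), with the sample (n-1) denominator. Used as a diagnostic
#' predictor of the accuracy gain of BLUP|GA over GBLUP.
#'
#' @param T_mat,G_mat matrices of identical dimension and ordering
#' @return non-negative scalar
#' @export
matrix_distance_sigma <- function(T_mat, G_mat) {
  if (!identical(dim(T_mat), dim(G_mat))) stop_blupga("dimension mismatch")
  if (nrow(T_mat) < 2) stop_blupga("need n >= 2")
  d <- (unclass(T_mat) - unclass(G_mat))[upper.tri(T_mat, diag = TRUE)]
  stats::sd(d)
}
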