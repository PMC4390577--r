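#' Construct a genotype matrix object
#'
#' A thin validated container for an `n x m` allele-dosage matrix (0/1/2
#' coding, counting copies of the second allele) with individual IDs on rows
#' and marker IDs on columns. Fractional values in `[0, 2]` are allowed so
#' that mean-imputed dosages remain representable.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns
#' @param individual_ids,marker_ids unique character identifiers; defaults
#'   taken from `dimnames(dosages)`
#' @return an object of class `geno_matrix`
#' @export
geno_matrix <- function(dosages, individual_ids = rownames(dosages),
                        marker_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(dosages)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(individual_ids)) stop_blupga("duplicate individual IDs")
  if (anyDuplicated(marker_ids)) stop_blupga("duplicate marker IDs")
  if (length(individual_ids) != nrow(dosages) || length(marker_ids) != ncol(dosages))
    stop_blupga("ID lengths do not match dosage dimensions")
  if (anyNA(dosages)) stop_blupga("missing dosages must be imputed before construction")
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2)
    stop_blupga("dosages outside [0, 2] (found range %.3g..%.3g)", rng[1], rng[2])
  dimnames(dosages) <- list(individual_ids, marker_ids)
  structure(list(dosages = dosages, individual_ids = individual_ids,
                 marker_ids = marker_ids), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers\n",
              length(x$individual_ids), length(x$marker_ids)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

impute_mean <- function(dos) {
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    mu <- colMeans(dos, na.rm = TRUE)
    if (anyNA(mu)) stop_blupga("marker with all dosages missing cannot be imputed")
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
    message(sprintf("imputed %d missing genotype cells to marker means", n_imp))
  }
  dos
}

#' Read a genotype dosage file
#'
#' Two dialects are supported. `dosage-tsv`: a header row of marker IDs, a
#' first column of individual IDs, then tab-separated dosages. `plink-raw`:
#' PLINK 1.x `--recode A` output (header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by SNP columns; the IID column becomes the individual ID and
#' `_<allele>` suffixes are stripped from marker names). Missing cells
#' (`NA` or empty) are mean-imputed per marker at load time.
#'
#' @param path file path
#' @param dialect `"dosage-tsv"` or `"plink-raw"`
#' @return a [geno_matrix]
#' @export
read_genotypes <- function(path, dialect = c("dosage-tsv", "plink-raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_blupga("genotype file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ""),
                          data.table = FALSE, showProgress = FALSE)
  if (dialect == "dosage-tsv") {
    ids <- as.character(dt[[1]])
    dos <- as.matrix(dt[, -1, drop = FALSE])
    mids <- colnames(dt)[-1]
  } else {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% colnames(dt)[1:6]))
      stop_blupga("plink-raw header must start with %s", paste(need, collapse = " "))
    ids <- as.character(dt[["IID"]])
    dos <- as.matrix(dt[, -(1:6), drop = FALSE])
    mids <- sub("_[ACGT0-9]+$", "", colnames(dt)[-(1:6)])
  }
  if (!is.numeric(dos)) {
    bad <- which(!vapply(as.data.frame(dos), is.numeric, TRUE))[1]
    stop_blupga("non-numeric dosage in column '%s'", colnames(dos)[bad])
  }
  obs <- dos[!is.na(dos)]
  ## called dosages are 0/1/2; fractional values in [0, 2] are accepted so
  ## mean-imputed files round-trip
  if (length(obs) && (min(obs) < 0 || max(obs) > 2))
    stop_blupga("dosages must lie in 0..2 or be missing on input")
  geno_matrix(impute_mean(dos), ids, mids)
}

#' Write a genotype matrix as dosage-tsv
#'
#' @param geno a [geno_matrix]
#' @param path output path
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(individual_id = geno$individual_ids,
                   geno$dosages, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a marker map (PLINK .map compatible)
#'
#' Four whitespace-delimited columns: chromosome, marker_id, (ignored),
#' position. Rows are sorted by chromosome then position, and a 0-based
#' `rank` is assigned within each chromosome; flanking-SNP selection is
#' defined on this rank.
#'
#' @param path file path
#' @return a `data.frame` of class `marker_map` with columns
#'   `marker_id`, `chromosome`, `position`, `rank`
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop_blupga("map file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          showProgress = FALSE)
  if (ncol(dt) < 4) stop_blupga("marker map needs 4 columns (chrom, id, cm, pos)")
  marker_map(data.frame(marker_id = as.character(dt[[2]]),
                        chromosome = as.character(dt[[1]]),
                        position = as.integer(dt[[4]])))
}

#' Construct a marker map from a data frame
#'
#' @param df data frame with columns `marker_id`, `chromosome`, `position`
#' @return sorted, ranked `marker_map`
#' @export
marker_map <- function(df) {
  stopifnot(all(c("marker_id", "chromosome", "position") %in% names(df)))
  df <- df[, c("marker_id", "chromosome", "position")]
  df$marker_id <- as.character(df$marker_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  if (any(df$position < 0)) stop_blupga("map positions must be non-negative")
  if (anyDuplicated(df$marker_id)) stop_blupga("duplicate marker IDs in map")
  if (anyDuplicated(df[, c("chromosome", "position")]))
    stop_blupga("duplicate (chromosome, position) in map")
  df <- df[order(df$chromosome, df$position), , drop = FALSE]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$chromosome)[unique(df$chromosome)],
                           function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Check that genotypes, map and phenotypes refer to the same markers and
#' individuals
#'
#' Misalignment is always an error, never a silent reorder.
#'
#' @param geno a [geno_matrix]
#' @param map optional [marker_map]; must list exactly the genotyped markers
#'   in the genotype column order
#' @param phenotype_ids optional character vector; all must be genotyped
#' @return invisibly `TRUE`
#' @export
check_alignment <- function(geno, map = NULL, phenotype_ids = NULL) {
  if (!is.null(map)) {
    if (!identical(map$marker_id, geno$marker_ids))
      stop_blupga("marker map and genotype columns are not aligned (same IDs, same order required)")
  }
  if (!is.null(phenotype_ids)) {
    miss <- setdiff(phenotype_ids, geno$individual_ids)
    if (length(miss))
      stop_blupga("phenotyped individuals missing from genotypes: %s",
                  paste(utils::head(miss, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a phenotype table
#'
#' Delimited text with columns `individual_id`, `value` and optionally
#' `trait`. At most one value per (individual, trait).
#'
#' @param path file path
#' @return data.frame with columns `individual_id`, `trait`, `value`
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (!all(c("individual_id", "value") %in% names(dt)))
    stop_blupga("phenotype file needs columns individual_id, value")
  if (is.null(dt$trait)) dt$trait <- "trait1"
  dt$individual_id <- as.character(dt$individual_id)
  if (anyDuplicated(dt[, c("individual_id", "trait")]))
    stop_blupga("more than one phenotype per (individual, trait)")
  dt[, c("individual_id", "trait", "value")]
}

#' Write a prediction table
#'
#' @param table data.frame with `individual_id` and `gebv` columns
#'   (optionally `trait`)
#' @param path output path
#' @export
write_predictions <- function(table, path) {
  if (!all(c("individual_id", "gebv") %in% names(table)))
    stop_blupga("prediction table needs columns individual_id, gebv")
  data.table::fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}

#' Write / read a relationship matrix as delimited text
#'
#' Full symmetric matrix with an ID header row and ID first column;
#' round-trips losslessly at 17 significant digits.
#'
#' @param K symmetric matrix with dimnames
#' @param path file path
#' @export
write_matrix <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) stop_blupga("matrix must carry individual IDs as dimnames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  for (i in seq_len(nrow(K))) {
    writeLines(paste(c(ids[i], formatC(K[i, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  ids <- as.character(dt[[1]])
  K <- as.matrix(dt[, -1, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  K
}
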