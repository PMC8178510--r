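#' Genotype matrix container
#'
#' Bundles per-sample expected alt-allele dosages with variant metadata and
#' the per-call quality fields used by genotype QC. Dosages live in `[0, 2]`
#' (`NA` = missing call); `max_posterior` holds the maximum genotype
#' probability of each call as emitted by imputation software.
#'
#' @param dosages numeric matrix, samples x variants, entries in `[0, 2]` or
#'   `NA`. Column names (if any) must agree with `variants$id`.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `info_score`; one row per column of `dosages`.
#' @param sample_ids character vector, one per row of `dosages`.
#' @param max_posterior optional matrix, same shape as `dosages`, per-call
#'   maximum genotype probability in `[0, 1]`. Defaults to 1 (hard calls).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids,
                            max_posterior = NULL) {
  dosages <- as.matrix(dosages)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt", "info_score")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L) {
    stop("variants is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variants has ", nrow(variants), " rows but dosages has ",
         ncol(dosages), " columns")
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match rows of dosages")
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant IDs: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  }
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie within [0, 2]")
  }
  if (is.null(max_posterior)) {
    max_posterior <- matrix(1, nrow(dosages), ncol(dosages))
  }
  max_posterior <- as.matrix(max_posterior)
  if (!all(dim(max_posterior) == dim(dosages))) {
    stop("max_posterior must have the same shape as dosages")
  }
  dimnames(dosages) <- list(as.character(sample_ids), variants$id)
  dimnames(max_posterior) <- dimnames(dosages)
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = as.character(sample_ids),
         max_posterior = max_posterior),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:",
      paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$dosages)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variant
#'
#' @param g a [genotype_matrix()].
#' @param keep logical, integer or character index over variants.
#' @return A `genotype_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(g, keep) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(keep)) keep <- match(keep, g$variants$id)
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE],
                  g$sample_ids,
                  g$max_posterior[, keep, drop = FALSE])
}

#' Expression matrix container
#'
#' Samples x features expression on the log2 scale with an explicit missing
#' mask (`NA` values), feature coordinates for cis-window lookups, and a
#' present-call indicator (raw abundance strictly positive) used by
#' missingness filters and the screening funnel.
#'
#' @param values numeric matrix, samples x features, log2-scale expression;
#'   `NA` marks masked entries.
#' @param sample_ids,feature_ids row / column identifiers.
#' @param feature_coords optional data.frame with columns `feature_id`,
#'   `chrom`, `start`, `end`, `strand` (1-based inclusive coordinates).
#' @param present optional logical matrix, same shape as `values`; defaults
#'   to `values > 0` where non-missing.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_ids, feature_ids,
                              feature_coords = NULL, present = NULL) {
  values <- as.matrix(values)
  if (length(sample_ids) != nrow(values) ||
      length(feature_ids) != ncol(values)) {
    stop("sample_ids / feature_ids do not match the shape of values")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("non-finite expression values present (use NA for missing)")
  }
  if (!is.null(feature_coords)) {
    feature_coords <- as.data.frame(feature_coords, stringsAsFactors = FALSE)
    req <- c("feature_id", "chrom", "start", "end", "strand")
    miss <- setdiff(req, names(feature_coords))
    if (length(miss) > 0L) {
      stop("feature_coords is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    if (any(feature_coords$start > feature_coords$end)) {
      stop("feature_coords: start must be <= end")
    }
    if (any(feature_coords$start < 1L)) {
      stop("feature_coords are 1-based: start must be >= 1")
    }
  }
  if (is.null(present)) {
    present <- !is.na(values) & values > 0
  }
  present <- as.matrix(present)
  if (!all(dim(present) == dim(values))) {
    stop("present must have the same shape as values")
  }
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(feature_ids))
  dimnames(present) <- dimnames(values)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids),
         feature_coords = feature_coords, present = present),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$sample_ids), "samples x",
      length(x$feature_ids), "features (log2 scale)\n")
  cat("  masked entries:", sum(is.na(x$values)), "\n")
  if (!is.null(x$feature_coords)) cat("  feature coordinates: yes\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Covariate table container
#'
#' Per-sample age and sex together with per-(sample, feature) copy-number
#' and CpG-methylation categories, i.e. the adjustment covariates of the
#' cis-eQTL regression. CNV and CpG may be supplied as matrices (samples x
#' features, for feature-specific categories) or as plain vectors recycled
#' across features.
#'
#' @param sample_ids character vector.
#' @param age numeric, years.
#' @param sex 0/1 coded.
#' @param cnv categories in `{-1, 0, 1}`; vector or samples x features
#'   matrix.
#' @param cpg categories in `{0, 1, 2, 3}`; vector or samples x features
#'   matrix.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(sample_ids, age, sex, cnv, cpg) {
  n <- length(sample_ids)
  stopifnot(length(age) == n, length(sex) == n)
  if (!all(sex %in% c(0, 1, NA))) stop("sex must be coded 0/1")
  check_cat <- function(x, allowed, what) {
    v <- x[!is.na(x)]
    if (!all(v %in% allowed)) {
      stop(what, " categories must lie in {",
           paste(allowed, collapse = ", "), "}")
    }
    if (is.matrix(x) && nrow(x) != n) {
      stop(what, " matrix rows must match sample_ids")
    }
    x
  }
  cnv <- check_cat(cnv, -1:1, "cnv")
  cpg <- check_cat(cpg, 0:3, "cpg")
  structure(
    list(sample_ids = as.character(sample_ids), age = as.numeric(age),
         sex = as.numeric(sex), cnv = cnv, cpg = cpg),
    class = "covariate_table"
  )
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table:", length(x$sample_ids), "samples",
      "(age, sex, cnv, cpg)\n")
  invisible(x)
}

# Extract the per-sample covariate columns for one expression feature.
# Returns a data.frame(age, sex, cnv, cpg) aligned with cov$sample_ids,
# or NULL when cov is NULL (unadjusted model).
covariate_columns <- function(cov, feature_id) {
  if (is.null(cov)) return(NULL)
  pick <- function(x) {
    if (is.matrix(x)) {
      j <- if (!is.null(colnames(x)) && feature_id %in% colnames(x)) {
        feature_id
      } else {
        1L
      }
      x[, j]
    } else {
      x
    }
  }
  data.frame(age = cov$age, sex = cov$sex,
             cnv = as.numeric(pick(cov$cnv)),
             cpg = as.numeric(pick(cov$cpg)))
}
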