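#' Covariate-adjusted cis-eQTL scan
#'
#' Fits, for every (SNP, miRNA) pair whose feature anchor lies within
#' `window` bp of the SNP on the same chromosome, the multivariate linear
#' model
#'
#'   expression = b0 + b1 genotype + b2 age + b3 sex + b4 CNV + b5 CpG + e
#'
#' by ordinary least squares on pairwise-complete samples, and reports the
#' genotype coefficient with its t statistic and two-sided p-value. The
#' feature anchor is the transcription start: annotated start on the +
#' strand, end on the - strand. CNV and CpG enter as single numeric
#' ordinals (one coefficient each). Benjamini-Hochberg q-values are
#' computed jointly across all tested pairs; pairs, not SNPs, are the test
#' unit.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()] with `feature_coords`.
#' @param covariates a [covariate_table()], or `NULL` for the unadjusted
#'   model.
#' @param window cis window half-width in bp (default 1e6).
#' @return data.frame of class `cis_associations` with columns `snp_id`,
#'   `mirna_id`, `beta1`, `t_stat`, `p_value`, `q_value`, `n_used`,
#'   `distance`, ordered by p (ties: |t| descending, then snp_id,
#'   mirna_id). Skipped pairs (constant genotype, rank-deficient design)
#'   are recorded in attribute `"skipped"`.
#' @export
scan_cis <- function(genotypes, expression, covariates = NULL,
                     window = 1e6) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"), window > 0)
  if (is.null(expression$feature_coords)) {
    stop("expression must carry feature_coords for cis pairing")
  }
  shared <- intersect(genotypes$sample_ids, expression$sample_ids)
  if (!is.null(covariates)) {
    shared <- intersect(shared, covariates$sample_ids)
  }
  if (length(shared) < 10L) {
    stop("fewer than 10 samples shared across genotypes, expression",
         if (!is.null(covariates)) " and covariates")
  }
  gi <- match(shared, genotypes$sample_ids)
  ei <- match(shared, expression$sample_ids)
  ci <- if (is.null(covariates)) NULL else match(shared, covariates$sample_ids)

  fc <- expression$feature_coords
  anchor <- ifelse(fc$strand == "-", fc$end, fc$start)
  names(anchor) <- fc$feature_id

  rows <- list()
  skipped <- list()
  for (f in expression$feature_ids) {
    if (!f %in% fc$feature_id) next
    f_chrom <- fc$chrom[fc$feature_id == f]
    f_anchor <- anchor[[f]]
    snp_idx <- which(genotypes$variants$chrom == f_chrom &
                     abs(genotypes$variants$pos - f_anchor) <= window)
    if (length(snp_idx) == 0L) next
    y_all <- expression$values[ei, f]
    cc <- covariate_columns(covariates, f)
    if (!is.null(cc)) cc <- cc[ci, , drop = FALSE]
    for (s in snp_idx) {
      snp <- genotypes$variants$id[s]
      g <- genotypes$dosages[gi, s]
      fit <- fit_eqtl_pair(g, y_all, cc)
      if (is.character(fit)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          snp_id = snp, mirna_id = f, reason = fit,
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, mirna_id = f, beta1 = fit$beta, t_stat = fit$t,
        p_value = fit$p, n_used = fit$n,
        distance = genotypes$variants$pos[s] - f_anchor,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame(
    snp_id = character(0), mirna_id = character(0), beta1 = numeric(0),
    t_stat = numeric(0), p_value = numeric(0), n_used = integer(0),
    distance = numeric(0))
  if (nrow(out) > 0L) {
    out$q_value <- bh_fdr(out$p_value)
    ord <- order(out$p_value, -abs(out$t_stat), out$snp_id, out$mirna_id)
    out <- out[ord, c("snp_id", "mirna_id", "beta1", "t_stat", "p_value",
                      "q_value", "n_used", "distance")]
    rownames(out) <- NULL
  } else {
    out$q_value <- numeric(0)
  }
  class(out) <- c("cis_associations", "data.frame")
  attr(out, "skipped") <- do.call(rbind, skipped) %||%
    data.frame(snp_id = character(0), mirna_id = character(0),
               reason = character(0))
  attr(out, "window") <- window
  out
}

# OLS fit of one cis pair. Returns list(beta, t, p, n) for the genotype
# coefficient, or a character reason when the pair must be skipped.
fit_eqtl_pair <- function(g, y, covariate_cols = NULL) {
  x <- cbind(`(Intercept)` = 1, genotype = g)
  if (!is.null(covariate_cols)) {
    x <- cbind(x, as.matrix(covariate_cols))
  }
  ok <- stats::complete.cases(x) & !is.na(y)
  n <- sum(ok)
  if (n <= ncol(x)) return("too_few_samples")
  x <- x[ok, , drop = FALSE]
  yv <- y[ok]
  if (stats::var(x[, "genotype"]) == 0) return("constant_genotype")
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) return("collinear_covariates")
  coef <- qr.coef(qr_x, yv)
  res <- yv - x %*% coef
  df <- n - ncol(x)
  sigma2 <- sum(res^2) / df
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(x))),
                      error = function(e) NULL)
  if (is.null(xtx_inv)) return("collinear_covariates")
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  beta <- unname(coef["genotype"])
  tval <- beta / se
  list(beta = beta, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), n = n)
}
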