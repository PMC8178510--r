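#' First-stage (weak instrument) F statistic
#'
#' F = (n - 2) R^2 / (1 - R^2) for the regression of the exposure on the
#' instrument, with its upper-tail p-value on (1, n - 2) degrees of
#' freedom. A perfect first stage (R^2 = 1) is reported as `Inf`.
#'
#' @param g instrument dosage vector.
#' @param x exposure (miRNA expression) vector.
#' @return list with `f`, `p`, `r2`, `n`.
#' @export
weak_instrument_f <- function(g, x) {
  ok <- !is.na(g) & !is.na(x)
  n <- sum(ok)
  if (n < 10L) stop("fewer than 10 pairwise-complete samples")
  g <- g[ok]; x <- x[ok]
  if (stats::var(g) == 0) stop("instrument is constant")
  r2 <- stats::cor(g, x)^2
  f <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  list(f = f, p = p, r2 = r2, n = n)
}

#' Single-instrument Wald-ratio IV estimate
#'
#' Estimates the causal effect of an exposure (miRNA expression) on an
#' outcome (mRNA expression) using a genotype as instrumental variable:
#' beta = cov(g, y) / cov(g, x), which is identical to two-stage least
#' squares with one instrument. The standard error comes from the delta
#' method (IV sandwich with structural residuals y - b0 - beta x).
#' First-stage weak-instrument statistics are attached.
#'
#' A first-stage covariance below numerical tolerance (relative to the
#' scale of g and x) raises an undefined-instrument error; this is
#' deliberately distinct from a statistically weak but finite first stage,
#' which passes through with its small F.
#'
#' @param g instrument dosage vector (non-constant).
#' @param x exposure vector.
#' @param y outcome vector.
#' @return An object of class `iv_estimate`: list with `beta1_iv`, `se`,
#'   `p`, `first_stage_f`, `p_weak`, `n`.
#' @export
wald_iv <- function(g, x, y) {
  ok <- !is.na(g) & !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 10L) stop("fewer than 10 pairwise-complete samples")
  g <- g[ok]; x <- x[ok]; y <- y[ok]
  if (stats::var(g) == 0) stop("instrument is constant")
  gc <- g - mean(g); xc <- x - mean(x); yc <- y - mean(y)
  s_gx <- sum(gc * xc)
  s_gy <- sum(gc * yc)
  s_gg <- sum(gc^2)
  tol <- 1e-10 * sqrt(s_gg) * sqrt(sum(xc^2))
  if (abs(s_gx) <= tol) {
    stop("undefined instrument: covariance between instrument and ",
         "exposure is numerically zero")
  }
  beta <- s_gy / s_gx
  resid <- yc - beta * xc
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 * s_gg / s_gx^2)
  z <- beta / se
  fs <- weak_instrument_f(g, x)
  structure(
    list(beta1_iv = beta, se = se,
         p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         first_stage_f = fs$f, p_weak = fs$p, n = n),
    class = "iv_estimate"
  )
}

#' Run IV regression over all (eSNP, mRNA) axes
#'
#' Applies [wald_iv()] to every combination of significant cis association
#' (eSNP instrument, eMiR exposure) and candidate mRNA outcome, attaching
#' Benjamini-Hochberg q-values of the weak-instrument p across all axes.
#'
#' @param cis data.frame with columns `snp_id`, `mirna_id` (the significant
#'   cis associations).
#' @param genotypes a [genotype_matrix()].
#' @param mirna,mrna [expression_matrix()] objects.
#' @param mrna_ids optional subset of mRNA features to test.
#' @return data.frame with one row per axis: `snp_id`, `mirna_id`,
#'   `mrna_id`, `beta1_iv`, `se`, `first_stage_f`, `p_weak`, `q_weak`,
#'   `n`.
#' @export
iv_scan <- function(cis, genotypes, mirna, mrna, mrna_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(mirna, "expression_matrix"),
            inherits(mrna, "expression_matrix"))
  if (is.null(mrna_ids)) mrna_ids <- mrna$feature_ids
  shared <- Reduce(intersect, list(genotypes$sample_ids, mirna$sample_ids,
                                   mrna$sample_ids))
  gi <- match(shared, genotypes$sample_ids)
  xi <- match(shared, mirna$sample_ids)
  yi <- match(shared, mrna$sample_ids)
  rows <- list()
  for (k in seq_len(nrow(cis))) {
    snp <- cis$snp_id[k]; mir <- cis$mirna_id[k]
    g <- genotypes$dosages[gi, match(snp, genotypes$variants$id)]
    x <- mirna$values[xi, mir]
    for (gene in mrna_ids) {
      y <- mrna$values[yi, gene]
      est <- tryCatch(wald_iv(g, x, y), error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, mirna_id = mir, mrna_id = gene,
        beta1_iv = est$beta1_iv, se = est$se,
        first_stage_f = est$first_stage_f, p_weak = est$p_weak,
        n = est$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame(
    snp_id = character(0), mirna_id = character(0),
    mrna_id = character(0), beta1_iv = numeric(0), se = numeric(0),
    first_stage_f = numeric(0), p_weak = numeric(0), n = integer(0))
  out$q_weak <- bh_fdr(out$p_weak)
  rownames(out) <- NULL
  out
}

#' Thresholds of the five-stage candidate funnel
#'
#' @param min_score minimum target-prediction integrated score (stage a).
#' @param min_present minimum present calls in the cohort (stage b).
#' @param mr_q weak-instrument FDR threshold (stage c).
#' @param de_q,de_lfc differential-expression FDR and |log2 fold change|
#'   thresholds (stage d).
#' @param surv_q survival-screen FDR threshold (stage e).
#' @return An object of class `funnel_thresholds`.
#' @export
funnel_thresholds <- function(min_score = 0.1, min_present = 100,
                              mr_q = 0.05, de_q = 0.01, de_lfc = 0.5,
                              surv_q = 0.05) {
  structure(list(min_score = min_score, min_present = min_present,
                 mr_q = mr_q, de_q = de_q, de_lfc = de_lfc,
                 surv_q = surv_q),
            class = "funnel_thresholds")
}

#' Screen candidate target genes through the five-criterion funnel
#'
#' Applies, in order: (a) target-prediction integrated score >= threshold;
#' (b) present calls >= threshold; (c) the locus is a significant genetic
#' instrument for the gene (any axis with weak-instrument BH-FDR below
#' threshold); (d) significant differential expression (FDR and |log2 fold
#' change|); (e) significant survival prediction (FDR). BH adjustment at
#' stages (c), (d) and (e) is recomputed within the genes entering that
#' stage, so each stage's multiplicity universe is the set of genes it
#' actually evaluates. A gene whose statistic is missing at a reached
#' stage fails that stage with reason `"missing"`.
#'
#' @param candidates data.frame `gene_id`, `integrated_score`,
#'   `present_calls`.
#' @param iv_results data.frame as returned by [iv_scan()] (`mrna_id`,
#'   `p_weak`, ...).
#' @param de_results data.frame `feature_id`, `log2fc`, `p` (per gene).
#' @param survival_results data.frame `feature_id`, `p` (per gene, e.g.
#'   from [survival_screen()]).
#' @param thresholds a [funnel_thresholds()].
#' @return An object of class `funnel_report`: list with `stages`
#'   (data.frame `stage`, `n_in`, `n_out`) and `genes` (per-gene flag
#'   table with `reason` for the first failure).
#' @export
run_funnel <- function(candidates, iv_results, de_results,
                       survival_results, thresholds = funnel_thresholds()) {
  stopifnot(inherits(thresholds, "funnel_thresholds"))
  genes <- data.frame(gene_id = as.character(candidates$gene_id),
                      integrated_score = candidates$integrated_score,
                      present_calls = candidates$present_calls,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  n0 <- nrow(genes)
  flags <- data.frame(gene_id = genes$gene_id,
                      score_pass = NA, present_pass = NA, mr_pass = NA,
                      de_pass = NA, surv_pass = NA,
                      de_log2fc = NA_real_, de_q = NA_real_,
                      surv_q = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)

  # (a) integrated score
  flags$score_pass <- !is.na(genes$integrated_score) &
    genes$integrated_score >= thresholds$min_score
  flags$reason[!flags$score_pass] <- ifelse(
    is.na(genes$integrated_score[!flags$score_pass]), "missing",
    "integrated_score")
  alive <- flags$score_pass

  # (b) present calls
  pp <- !is.na(genes$present_calls) &
    genes$present_calls >= thresholds$min_present
  flags$present_pass[alive] <- pp[alive]
  fail_b <- alive & !pp
  flags$reason[fail_b] <- ifelse(is.na(genes$present_calls[fail_b]),
                                 "missing", "present_calls")
  n_b_in <- sum(alive)
  alive <- alive & pp

  # (c) Mendelian randomization: BH over the axes of genes entering the
  # stage; gene passes when any of its axes is below the FDR threshold
  n_c_in <- sum(alive)
  iv_sub <- iv_results[iv_results$mrna_id %in% flags$gene_id[alive], ,
                       drop = FALSE]
  mr_pass_genes <- character(0)
  if (nrow(iv_sub) > 0L) {
    q <- bh_fdr(iv_sub$p_weak)
    mr_pass_genes <- unique(iv_sub$mrna_id[!is.na(q) & q < thresholds$mr_q])
  }
  has_iv <- flags$gene_id %in% unique(iv_results$mrna_id)
  mp <- flags$gene_id %in% mr_pass_genes
  flags$mr_pass[alive] <- mp[alive]
  fail_c <- alive & !mp
  flags$reason[fail_c] <- ifelse(has_iv[fail_c], "mr", "missing")
  alive <- alive & mp

  # (d) differential expression, BH within the entering genes
  n_d_in <- sum(alive)
  de_idx <- match(flags$gene_id, de_results$feature_id)
  de_p <- de_results$p[de_idx]
  de_lfc <- de_results$log2fc[de_idx]
  q_d <- rep(NA_real_, n0)
  q_d[alive] <- bh_fdr(de_p[alive])
  dp <- !is.na(q_d) & q_d < thresholds$de_q &
    !is.na(de_lfc) & abs(de_lfc) > thresholds$de_lfc
  flags$de_pass[alive] <- dp[alive]
  flags$de_log2fc[alive] <- de_lfc[alive]
  flags$de_q[alive] <- q_d[alive]
  fail_d <- alive & !dp
  flags$reason[fail_d] <- ifelse(is.na(de_p[fail_d]) | is.na(de_lfc[fail_d]),
                                 "missing", "de")
  alive <- alive & dp

  # (e) survival screen, BH within the entering genes
  n_e_in <- sum(alive)
  sv_idx <- match(flags$gene_id, survival_results$feature_id)
  sv_p <- survival_results$p[sv_idx]
  q_e <- rep(NA_real_, n0)
  q_e[alive] <- bh_fdr(sv_p[alive])
  sp <- !is.na(q_e) & q_e < thresholds$surv_q
  flags$surv_pass[alive] <- sp[alive]
  flags$surv_q[alive] <- q_e[alive]
  fail_e <- alive & !sp
  flags$reason[fail_e] <- ifelse(is.na(sv_p[fail_e]), "missing", "survival")
  alive <- alive & sp

  stages <- data.frame(
    stage = c("integrated_score", "present_calls", "mr", "de", "survival"),
    n_in = c(n0, n_b_in, n_c_in, n_d_in, n_e_in),
    n_out = c(n_b_in, n_c_in, n_d_in, n_e_in, sum(alive)),
    stringsAsFactors = FALSE
  )
  structure(list(stages = stages, genes = flags,
                 survivors = flags$gene_id[alive],
                 thresholds = thresholds),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("funnel_report:\n")
  print(x$stages, row.names = FALSE)
  cat("final survivors:", length(x$survivors), "\n")
  invisible(x)
}
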