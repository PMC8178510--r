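# Independent oracles used across the suite. These deliberately go through
# stats::lm / glm / survival rather than the package's own linear algebra.

# Full multiple-regression fit of one cis pair via stats::lm; returns the
# genotype coefficient, t and p as summary.lm computes them.
oracle_pair_fit <- function(g, y, covariate_cols = NULL) {
  df <- data.frame(y = y, g = g)
  if (!is.null(covariate_cols)) df <- cbind(df, covariate_cols)
  fit <- stats::lm(y ~ ., data = df)
  s <- summary(fit)$coefficients
  list(beta = s["g", "Estimate"], t = s["g", "t value"],
       p = s["g", "Pr(>|t|)"], n = sum(stats::complete.cases(df)))
}

# Explicit two-stage least squares: regress exposure on instrument, then
# outcome on the fitted exposure.
oracle_2sls <- function(g, x, y) {
  xhat <- stats::fitted(stats::lm(x ~ g))
  unname(stats::coef(stats::lm(y ~ xhat))[2L])
}

# Two-population diploid genotypes under the Balding-Nichols model.
balding_nichols <- function(n_per_pop, n_variants, fst = 0.1) {
  p_anc <- stats::runif(n_variants, 0.1, 0.9)
  shape <- (1 - fst) / fst
  pops <- lapply(1:2, function(k) {
    p_pop <- stats::rbeta(n_variants, shape * p_anc, shape * (1 - p_anc))
    sapply(p_pop, function(p) stats::rbinom(n_per_pop, 2L, p))
  })
  dos <- rbind(pops[[1L]], pops[[2L]])
  labels <- rep(c("POP1", "POP2"), each = n_per_pop)
  list(dosages = dos, labels = labels)
}

toy_genotype_matrix <- function(dosages, chrom = "1",
                                pos = seq_len(ncol(dosages)) * 1000L,
                                info = 1, ids = NULL,
                                max_posterior = NULL) {
  m <- ncol(dosages)
  genotype_matrix(
    dosages,
    data.frame(id = ids %||% sprintf("v%03d", seq_len(m)),
               chrom = rep_len(chrom, m), pos = pos, ref = "A", alt = "G",
               info_score = rep_len(info, m), stringsAsFactors = FALSE),
    sprintf("S%03d", seq_len(nrow(dosages))),
    max_posterior
  )
}

read_tsv_file <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                  data.table = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
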