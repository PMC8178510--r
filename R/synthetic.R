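#' Configuration for a synthetic cohort
#'
#' Collects every generative parameter of the simulated study: LD-structured
#' diploid genotypes, cis genotype-to-miRNA effects under the
#' covariate-adjusted linear model, miRNA-to-mRNA trans effects, confounding
#' by copy number / methylation / age / sex, tumor-vs-normal expression
#' shifts, and expression-linked exponential survival. All of these are
#' configuration, not constants: the defaults describe one plausible cohort,
#' and every test that depends on a condition sets it explicitly.
#'
#' @param n_samples,n_variants,n_mirna,n_mrna positive counts.
#' @param maf_range length-2 numeric in (0, 1); per-variant alt-allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_decay per-adjacent-variant haplotype correlation in `[0, 1)`
#'   (latent Gaussian autoregression; see Details).
#' @param cis_effects data.frame with columns `variant`, `mirna`, `beta`
#'   (indices and the genotype effect on miRNA expression per alt allele).
#' @param trans_effects data.frame with columns `mirna`, `mrna`, `beta`
#'   (the causal effect of miRNA on mRNA expression).
#' @param covariate_effects named numeric with entries `age`, `sex`, `cnv`,
#'   `cpg`: the covariate coefficients of the miRNA model, applied to every
#'   miRNA feature.
#' @param noise_sd Gaussian residual SD of both expression models; > 0.
#' @param tumor_shift list with elements `mirna` and `mrna`: per-feature
#'   log2 mean difference tumor minus normal (scalars are recycled).
#' @param survival_loghr numeric of length `n_mrna` (or scalar): per-feature
#'   log hazard ratio per SD of that mRNA's expression.
#' @param confounder_sd SD of a shared per-sample confounder added to both
#'   miRNA and mRNA values (0 disables; used to emulate the confounded
#'   regime instrumental-variable analysis is designed for).
#' @param tumor_fraction fraction of samples labeled tumor.
#' @param mirna_baseline,mrna_baseline intercepts on the log2(RPM+1) scale.
#' @param base_hazard baseline event rate per month of the exponential
#'   survival model. The uniform censoring horizon is set to `3.2 /
#'   base_hazard`, which gives approximately 30% censoring under the null.
#' @param seed root integer seed; all stage streams are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_variants, n_mirna, n_mrna,
                       maf_range = c(0.05, 0.5), ld_decay = 0.5,
                       cis_effects = NULL, trans_effects = NULL,
                       covariate_effects = c(age = 0.01, sex = 0.2,
                                             cnv = 0.5, cpg = -0.3),
                       noise_sd = 1, tumor_shift = list(mirna = 0, mrna = 0),
                       survival_loghr = 0, confounder_sd = 0,
                       tumor_fraction = 0.5,
                       mirna_baseline = 5, mrna_baseline = 8,
                       base_hazard = 0.04, seed = 1L) {
  counts <- c(n_samples = n_samples, n_variants = n_variants,
              n_mirna = n_mirna, n_mrna = n_mrna)
  if (any(counts < 1)) stop("all counts must be positive")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 1)")
  }
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  check_effects <- function(eff, cols, lims, what) {
    if (is.null(eff)) {
      return(stats::setNames(
        data.frame(integer(0), integer(0), numeric(0)), c(cols, "beta")))
    }
    eff <- as.data.frame(eff)
    if (!all(c(cols, "beta") %in% names(eff))) {
      stop(what, " must have columns ", paste(c(cols, "beta"), collapse = ", "))
    }
    for (k in seq_along(cols)) {
      bad <- which(eff[[cols[k]]] < 1 | eff[[cols[k]]] > lims[k])
      if (length(bad) > 0L) {
        stop("configuration error in ", what, " entry ", bad[1], ": ",
             cols[k], " index ", eff[[cols[k]]][bad[1]],
             " outside 1..", lims[k])
      }
    }
    eff
  }
  cis_effects <- check_effects(cis_effects, c("variant", "mirna"),
                               c(n_variants, n_mirna), "cis_effects")
  trans_effects <- check_effects(trans_effects, c("mirna", "mrna"),
                                 c(n_mirna, n_mrna), "trans_effects")
  ce <- covariate_effects
  if (!all(c("age", "sex", "cnv", "cpg") %in% names(ce))) {
    stop("covariate_effects must name age, sex, cnv and cpg")
  }
  if (!is.list(tumor_shift)) tumor_shift <- list(mirna = tumor_shift,
                                                 mrna = tumor_shift)
  structure(
    list(n_samples = as.integer(n_samples),
         n_variants = as.integer(n_variants),
         n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
         maf_range = as.numeric(maf_range), ld_decay = as.numeric(ld_decay),
         cis_effects = cis_effects, trans_effects = trans_effects,
         covariate_effects = ce, noise_sd = as.numeric(noise_sd),
         tumor_shift = tumor_shift,
         survival_loghr = rep_len(as.numeric(survival_loghr), n_mrna),
         confounder_sd = as.numeric(confounder_sd),
         tumor_fraction = as.numeric(tumor_fraction),
         mirna_baseline = as.numeric(mirna_baseline),
         mrna_baseline = as.numeric(mrna_baseline),
         base_hazard = as.numeric(base_hazard), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Draw n haplotypes (rows) over the given alt-allele frequencies with a
# latent Gaussian AR(1) chain: z_1 = e_1, z_j = r z_{j-1} + sqrt(1-r^2) e_j,
# allele_j = 1{z_j < qnorm(p_j)}. Marginals are exactly Bernoulli(p_j) for
# any r, while adjacent-variant allele correlation increases monotonically
# with r.
draw_haplotypes <- function(n, freqs, r) {
  m <- length(freqs)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (m > 1L && r > 0) {
    for (j in 2:m) {
      z[, j] <- r * z[, j - 1L] + sqrt(1 - r^2) * z[, j]
    }
  }
  thr <- stats::qnorm(freqs)
  (z < matrix(thr, n, m, byrow = TRUE)) + 0L
}

#' Generate a seeded synthetic cohort
#'
#' Forward-simulates the full generative structure the analysis assumes:
#' miRNA expression follows the covariate-adjusted linear model
#' (intercept + genotype effect + age, sex, CNV and CpG terms + Gaussian
#' noise), mRNA expression follows the miRNA-driven model (intercept +
#' miRNA effect + noise), survival is exponential with per-sample log
#' hazard equal to the configured per-feature log hazard ratios applied to
#' standardized mRNA expression, with independent uniform censoring.
#'
#' All randomness flows from `config$seed` through named per-stage streams
#' (`genotypes`, `covariates`, `groups`, `mirna`, `mrna`, `survival`), so
#' identical configurations yield bit-identical cohorts.
#'
#' @param config a [sim_config()].
#' @return An object of class `synthetic_cohort`: list with elements
#'   `genotypes` ([genotype_matrix()]), `mirna` and `mrna`
#'   ([expression_matrix()]), `covariates` ([covariate_table()]),
#'   `survival` (data.frame `sample_id`, `time`, `event`), `group_labels`
#'   (tumor/normal), and `truth` (the configured effect lists).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  geno <- with_stream(config$seed, "genotypes", {
    freqs <- stats::runif(config$n_variants, config$maf_range[1],
                          config$maf_range[2])
    h1 <- draw_haplotypes(n, freqs, config$ld_decay)
    h2 <- draw_haplotypes(n, freqs, config$ld_decay)
    list(dosages = h1 + h2, freqs = freqs)
  })
  variants <- data.frame(
    id = sprintf("snp%04d", seq_len(config$n_variants)),
    chrom = "1",
    pos = as.integer(seq_len(config$n_variants) * 10000L),
    ref = "A", alt = "G", info_score = 1,
    alt_freq = geno$freqs,
    stringsAsFactors = FALSE
  )
  genotypes <- genotype_matrix(geno$dosages, variants, samples)

  cov <- with_stream(config$seed, "covariates", {
    age <- pmin(pmax(stats::rnorm(n, 65, 8), 30), 90)
    sex <- stats::rbinom(n, 1L, 0.5)
    cnv <- matrix(sample(c(-1L, 0L, 1L), n * config$n_mirna, replace = TRUE,
                         prob = c(0.2, 0.6, 0.2)), n, config$n_mirna)
    cpg <- matrix(sample(0:3, n * config$n_mirna, replace = TRUE),
                  n, config$n_mirna)
    list(age = age, sex = sex, cnv = cnv, cpg = cpg)
  })

  groups <- with_stream(config$seed, "groups", {
    n_tumor <- round(n * config$tumor_fraction)
    g <- rep("normal", n)
    g[sample.int(n, n_tumor)] <- "tumor"
    g
  })
  is_tumor <- as.numeric(groups == "tumor")

  confounder <- if (config$confounder_sd > 0) {
    with_stream(config$seed, "confounder",
                stats::rnorm(n, 0, config$confounder_sd))
  } else {
    numeric(n)
  }

  ce <- config$covariate_effects
  mirna_ids <- sprintf("mir%03d", seq_len(config$n_mirna))
  mirna_vals <- with_stream(config$seed, "mirna", {
    eps <- matrix(stats::rnorm(n * config$n_mirna, 0, config$noise_sd),
                  n, config$n_mirna)
    v <- config$mirna_baseline +
      outer(cov$age, rep(ce[["age"]], config$n_mirna)) +
      outer(cov$sex, rep(ce[["sex"]], config$n_mirna)) +
      ce[["cnv"]] * cov$cnv + ce[["cpg"]] * cov$cpg + eps
    shift <- rep_len(config$tumor_shift$mirna, config$n_mirna)
    v <- v + outer(is_tumor, shift)
    for (k in seq_len(nrow(config$cis_effects))) {
      e <- config$cis_effects[k, ]
      v[, e$mirna] <- v[, e$mirna] + e$beta * genotypes$dosages[, e$variant]
    }
    v + confounder
  })
  # miRNA anchors spread across the simulated variant span so cis pairing
  # under a 1 Mb window arises naturally
  span <- max(variants$pos)
  mirna_anchor <- as.integer(round(seq(10000, span,
                                       length.out = config$n_mirna)))
  mirna <- expression_matrix(
    mirna_vals, samples, mirna_ids,
    feature_coords = data.frame(feature_id = mirna_ids, chrom = "1",
                                start = mirna_anchor,
                                end = mirna_anchor + 80L,
                                strand = "+", stringsAsFactors = FALSE)
  )

  mrna_ids <- sprintf("gene%04d", seq_len(config$n_mrna))
  mrna_vals <- with_stream(config$seed, "mrna", {
    eps <- matrix(stats::rnorm(n * config$n_mrna, 0, config$noise_sd),
                  n, config$n_mrna)
    v <- config$mrna_baseline + eps
    shift <- rep_len(config$tumor_shift$mrna, config$n_mrna)
    v <- v + outer(is_tumor, shift)
    for (k in seq_len(nrow(config$trans_effects))) {
      e <- config$trans_effects[k, ]
      v[, e$mrna] <- v[, e$mrna] + e$beta * mirna_vals[, e$mirna]
    }
    v + confounder
  })
  mrna_anchor <- as.integer(seq_len(config$n_mrna) * 20000L)
  mrna <- expression_matrix(
    mrna_vals, samples, mrna_ids,
    feature_coords = data.frame(feature_id = mrna_ids, chrom = "2",
                                start = mrna_anchor,
                                end = mrna_anchor + 2000L,
                                strand = "+", stringsAsFactors = FALSE)
  )

  survival <- with_stream(config$seed, "survival", {
    linpred <- numeric(n)
    active <- which(config$survival_loghr != 0)
    for (j in active) {
      z <- scale(mrna_vals[, j])[, 1L]
      linpred <- linpred + config$survival_loghr[j] * z
    }
    rate <- config$base_hazard * exp(linpred)
    t_event <- stats::rexp(n, rate)
    horizon <- 3.2 / config$base_hazard
    t_cens <- stats::runif(n, 0, horizon)
    data.frame(sample_id = samples,
               time = pmax(pmin(t_event, t_cens), 1e-6),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })

  covariates <- covariate_table(samples, cov$age, cov$sex,
                                `colnames<-`(cov$cnv, mirna_ids),
                                `colnames<-`(cov$cpg, mirna_ids))

  structure(
    list(genotypes = genotypes, mirna = mirna, mrna = mrna,
         covariates = covariates, survival = survival,
         group_labels = groups,
         truth = list(config = config, cis_effects = config$cis_effects,
                      trans_effects = config$trans_effects,
                      survival_loghr = config$survival_loghr)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$genotypes$sample_ids), "samples,",
      nrow(x$genotypes$variants), "variants,",
      length(x$mirna$feature_ids), "miRNAs,",
      length(x$mrna$feature_ids), "mRNAs\n")
  cat("  tumor:", sum(x$group_labels == "tumor"),
      " normal:", sum(x$group_labels == "normal"), "\n")
  cat("  planted cis effects:", nrow(x$truth$cis_effects),
      " trans effects:", nrow(x$truth$trans_effects), "\n")
  invisible(x)
}

#' Sample a 2x2 exposure-by-outcome table
#'
#' Draws binomial exposure counts in each arm with fixed case/control
#' margins; the result feeds the odds-ratio machinery used for
#' clinicopathological association tables.
#'
#' @param p_exposed_case,p_exposed_control exposure probabilities in (0, 1).
#' @param n_case,n_control arm sizes (> 0).
#' @param seed integer seed.
#' @return A 2x2 integer matrix with rows `exposed`/`unexposed` and columns
#'   `case`/`control`.
#' @export
generate_two_by_two <- function(p_exposed_case, p_exposed_control,
                                n_case, n_control, seed = 1L) {
  stopifnot(p_exposed_case > 0, p_exposed_case < 1,
            p_exposed_control > 0, p_exposed_control < 1,
            n_case > 0, n_control > 0)
  with_stream(seed, "two_by_two", {
    a <- stats::rbinom(1L, n_case, p_exposed_case)
    b <- stats::rbinom(1L, n_control, p_exposed_control)
    matrix(c(a, n_case - a, b, n_control - b), nrow = 2,
           dimnames = list(c("exposed", "unexposed"),
                           c("case", "control")))
  })
}
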