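#' QC thresholds for imputed genotypes
#'
#' Defaults follow the standard post-imputation filter set: imputation info
#' score > 0.7, MAF > 5%, per-call maximum genotype probability > 0.7,
#' Hardy-Weinberg equilibrium p > 1e-6, LD r2 > 0.5 for tag expansion, and
#' a 1 Mb cis window either side of a tag SNP.
#'
#' @param min_info,min_maf,min_posterior,min_hwe_p,min_ld_r2 numeric
#'   thresholds (all strict lower bounds).
#' @param cis_window window half-width in bp.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_info = 0.7, min_maf = 0.05,
                          min_posterior = 0.7, min_hwe_p = 1e-6,
                          min_ld_r2 = 0.5, cis_window = 1e6) {
  stopifnot(min_info >= 0, min_info <= 1, min_maf >= 0, min_maf < 0.5,
            min_posterior >= 0, min_posterior <= 1,
            min_hwe_p >= 0, min_hwe_p <= 1,
            min_ld_r2 >= 0, min_ld_r2 <= 1, cis_window > 0)
  structure(list(min_info = min_info, min_maf = min_maf,
                 min_posterior = min_posterior, min_hwe_p = min_hwe_p,
                 min_ld_r2 = min_ld_r2, cis_window = cis_window),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation computed from the estimated
#' allele frequency. Monomorphic variants carry no measurable departure and
#' return p = 1.
#'
#' @param counts integer triple (hom-ref, het, hom-alt).
#' @return p-value in `[0, 1]`.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0)) {
    stop("counts must be a non-negative triple (hom-ref, het, hom-alt)")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  p <- (2 * counts[3] + counts[2]) / (2 * n)  # alt-allele frequency
  if (p == 0 || p == 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# MAF from mean dosage over non-missing samples.
dosage_maf <- function(d) {
  f <- mean(d, na.rm = TRUE) / 2
  min(f, 1 - f)
}

# Best-guess genotype counts from dosages: nearest integer, ties to even
# (base R round()), missing dropped.
dosage_genotype_counts <- function(d) {
  g <- round(d[!is.na(d)])
  c(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Filter imputed variants on the four QC criteria
#'
#' Applies, in order of reporting: (a) info score, (b) MAF, (c) per-call
#' posterior probability, (d) HWE. Criterion (c) acts per call: dosages
#' whose maximum genotype probability does not exceed `min_posterior` are
#' set missing before MAF and HWE are computed, so a shaky call never fails
#' a whole variant. The returned matrix keeps input variant order; the
#' per-variant criterion values and pass flags are attached as attribute
#' `"qc_report"` (long format: variant, criterion, value, pass).
#'
#' @param g a [genotype_matrix()].
#' @param t a [qc_thresholds()].
#' @return Filtered `genotype_matrix` with a `qc_report` attribute.
#' @export
filter_variants <- function(g, t = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(t, "qc_thresholds"))
  dos <- g$dosages
  dos[g$max_posterior <= t$min_posterior] <- NA
  m <- ncol(dos)
  maf <- vapply(seq_len(m), function(j) dosage_maf(dos[, j]), numeric(1))
  hwe <- vapply(seq_len(m), function(j) {
    cnt <- dosage_genotype_counts(dos[, j])
    if (sum(cnt) == 0) return(NA_real_)
    hwe_test(cnt)
  }, numeric(1))
  info <- g$variants$info_score
  pass_info <- info > t$min_info
  pass_maf <- !is.na(maf) & maf > t$min_maf
  pass_hwe <- !is.na(hwe) & hwe > t$min_hwe_p
  keep <- pass_info & pass_maf & pass_hwe
  report <- data.frame(
    variant = rep(g$variants$id, 3L),
    criterion = rep(c("info_score", "maf", "hwe_p"), each = m),
    value = c(info, maf, hwe),
    pass = c(pass_info, pass_maf, pass_hwe),
    stringsAsFactors = FALSE
  )
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         g$variants[keep, , drop = FALSE],
                         g$sample_ids,
                         g$max_posterior[, keep, drop = FALSE])
  attr(out, "qc_report") <- report
  attr(out, "removed_by_criterion") <- c(
    info_score = sum(!pass_info), maf = sum(!pass_maf),
    hwe_p = sum(!pass_hwe)
  )
  out
}

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of unphased allele dosages
#' (pairwise-complete). Sign-invariant, so allele relabeling (d -> 2 - d)
#' leaves the value unchanged.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r2 in `[0, 1]`.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 pairwise-complete samples")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("LD undefined for a constant dosage vector")
  }
  stats::cor(a, b)^2
}

#' Expand tag SNPs to their LD neighborhood
#'
#' For each tag, collects the panel variants on the same chromosome within
#' `cis_window` bp and with LD r2 strictly above `min_ld_r2` to the tag
#' (the tag itself always qualifies). Overlapping windows are unioned with
#' no duplicates; each output variant is annotated with its source tag(s),
#' sorted alphabetically so the output is invariant to tag ordering.
#'
#' @param tags character vector of tag variant IDs (must exist in `panel`;
#'   absent tags are skipped with a warning and recorded).
#' @param panel a [genotype_matrix()].
#' @param t a [qc_thresholds()] supplying `cis_window` and `min_ld_r2`.
#' @return A `genotype_matrix` in panel order whose `variants` gains a
#'   `source_tag` column; skipped tags are attached as attribute
#'   `"skipped_tags"`.
#' @export
expand_tag_snps <- function(tags, panel, t = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_matrix"), inherits(t, "qc_thresholds"))
  idx <- match(tags, panel$variants$id)
  skipped <- tags[is.na(idx)]
  if (length(skipped) > 0L) {
    warning("tag(s) absent from panel, skipped: ",
            paste(skipped, collapse = ", "))
  }
  sources <- vector("list", nrow(panel$variants))
  for (k in which(!is.na(idx))) {
    i <- idx[k]
    tag_chrom <- panel$variants$chrom[i]
    tag_pos <- panel$variants$pos[i]
    tag_dos <- panel$dosages[, i]
    near <- which(panel$variants$chrom == tag_chrom &
                  abs(panel$variants$pos - tag_pos) <= t$cis_window)
    for (j in near) {
      in_ld <- if (j == i) TRUE else {
        r2 <- tryCatch(ld_r2(tag_dos, panel$dosages[, j]),
                       error = function(e) NA_real_)
        !is.na(r2) && r2 > t$min_ld_r2
      }
      if (in_ld) sources[[j]] <- c(sources[[j]], tags[k])
    }
  }
  keep <- which(lengths(sources) > 0L)
  out <- subset_variants(panel, keep)
  out$variants$source_tag <- vapply(
    sources[keep], function(s) paste(sort(unique(s)), collapse = ","),
    character(1))
  attr(out, "skipped_tags") <- skipped
  out
}

#' Assign ancestry by principal components of shared variants
#'
#' Merges cohort and reference dosages over their shared variants,
#' standardizes each variant (missing entries mean-imputed), fits a PCA,
#' and labels every cohort sample by majority vote of its 5 nearest
#' reference samples in the PC1-PC2 plane (vote ties broken by smallest
#' mean distance).
#'
#' @param cohort,reference [genotype_matrix()] objects sharing >= 50
#'   variant IDs.
#' @param reference_labels character population labels, one per reference
#'   sample.
#' @param k number of reference neighbors to vote (default 5).
#' @return data.frame `sample_id`, `population`, `PC1`, `PC2` for the
#'   cohort samples, with reference coordinates attached as attribute
#'   `"reference_coords"`.
#' @export
assign_ancestry <- function(cohort, reference, reference_labels, k = 5L) {
  stopifnot(inherits(cohort, "genotype_matrix"),
            inherits(reference, "genotype_matrix"))
  if (length(reference_labels) != length(reference$sample_ids)) {
    stop("reference_labels must cover all reference samples")
  }
  shared <- intersect(cohort$variants$id, reference$variants$id)
  if (length(shared) < 50L) {
    stop("insufficient overlap: only ", length(shared),
         " shared variants (need >= 50)")
  }
  x <- rbind(cohort$dosages[, shared, drop = FALSE],
             reference$dosages[, shared, drop = FALSE])
  # per-variant standardization with mean imputation of missing calls
  x <- apply(x, 2L, function(col) {
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mu) / s
  })
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)$x
  n_cohort <- length(cohort$sample_ids)
  cohort_pc <- pc[seq_len(n_cohort), , drop = FALSE]
  ref_pc <- pc[-seq_len(n_cohort), , drop = FALSE]
  labels <- character(n_cohort)
  for (i in seq_len(n_cohort)) {
    d <- sqrt((ref_pc[, 1] - cohort_pc[i, 1])^2 +
              (ref_pc[, 2] - cohort_pc[i, 2])^2)
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(reference_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(lb) {
        mean(d[nn][reference_labels[nn] == lb])
      }, numeric(1))
      top <- top[which.min(mean_d)]
    }
    labels[i] <- top
  }
  out <- data.frame(sample_id = cohort$sample_ids, population = labels,
                    PC1 = cohort_pc[, 1], PC2 = cohort_pc[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reference_coords") <- data.frame(
    sample_id = reference$sample_ids, population = reference_labels,
    PC1 = ref_pc[, 1], PC2 = ref_pc[, 2],
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
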