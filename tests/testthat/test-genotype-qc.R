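test_that("HWE chi-square test matches a brute-force computation", {
  # exact HWE proportions: no departure
  expect_equal(hwe_test(c(25, 50, 25)), 1.0)
  # monomorphic: no measurable departure
  expect_equal(hwe_test(c(100, 0, 0)), 1.0)
  # hand oracle at counts (50, 20, 30): alt freq 0.4 -> expected under HWE
  counts <- c(50, 20, 30)
  p_alt <- (2 * 30 + 20) / 200
  expected <- 100 * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  chi2 <- sum((counts - expected)^2 / expected)
  expect_equal(hwe_test(counts),
               pchisq(chi2, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(hwe_test(c(0, 0, 0)), "zero")
})

test_that("HWE p-values under equilibrium genotypes are approximately uniform", {
  set.seed(42)
  pv <- replicate(1000, {
    p <- runif(1, 0.2, 0.5)
    h <- rbinom(500, 1, p) + rbinom(500, 1, p)
    hwe_test(c(sum(h == 0), sum(h == 1), sum(h == 2)))
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variant filtering applies the four criteria and reports removals", {
  set.seed(1)
  n <- 200
  base <- function() rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  dos <- cbind(base(), base(), base(), base())
  # v2: fails info; v3: MAF 0.04; v4: gross HWE violation (all hets)
  dos[, 3] <- c(rep(1, 16), rep(0, n - 16))
  dos[, 4] <- rep(1, n)
  g <- toy_genotype_matrix(dos, info = c(0.9, 0.6, 0.95, 0.95))
  out <- filter_variants(g, qc_thresholds())
  expect_identical(out$variants$id, "v001")
  rep_tab <- attr(out, "qc_report")
  expect_false(rep_tab$pass[rep_tab$variant == "v002" &
                              rep_tab$criterion == "info_score"])
  expect_false(rep_tab$pass[rep_tab$variant == "v003" &
                              rep_tab$criterion == "maf"])
  expect_false(rep_tab$pass[rep_tab$variant == "v004" &
                              rep_tab$criterion == "hwe_p"])
  rm_counts <- attr(out, "removed_by_criterion")
  expect_equal(unname(rm_counts["info_score"]), 1)
})

test_that("filtering passes clean variants unchanged and is idempotent", {
  set.seed(2)
  dos <- sapply(1:5, function(i) rbinom(150, 2, 0.4))
  g <- toy_genotype_matrix(dos)
  out <- filter_variants(g)
  expect_identical(out$variants$id, g$variants$id)
  expect_identical(out$dosages, g$dosages)
  twice <- filter_variants(out)
  expect_identical(twice$dosages, out$dosages)
  expect_identical(twice$variants$id, out$variants$id)
})

test_that("low-posterior calls become missing before MAF and HWE", {
  set.seed(3)
  dos <- matrix(rbinom(100, 2, 0.4), ncol = 1)
  mp <- matrix(1, 100, 1)
  mp[1:10] <- 0.5
  g <- toy_genotype_matrix(dos, max_posterior = mp)
  out <- filter_variants(g)
  expect_true(all(is.na(out$dosages[1:10, 1])))
  expect_false(anyNA(out$dosages[11:100, 1]))
  rep_tab <- attr(out, "qc_report")
  f <- mean(dos[11:100, 1]) / 2
  expect_equal(rep_tab$value[rep_tab$criterion == "maf"], min(f, 1 - f))
})

test_that("LD r2 is a squared Pearson correlation with its invariances", {
  set.seed(4)
  a <- rbinom(20, 2, 0.4)
  b <- rbinom(20, 2, 0.4)
  expect_equal(ld_r2(a, a), 1.0)
  expect_equal(ld_r2(a, 2 - a), 1.0)
  # brute-force Pearson formula
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ld_r2(a, b), (num / den)^2, tolerance = 1e-12)
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_error(ld_r2(a, rep(1, 20)), "constant")
  expect_error(ld_r2(a, b[1:10]), "length")
})

test_that("tag expansion respects the r2 threshold, window and set union", {
  set.seed(5)
  n <- 400
  tag <- rbinom(n, 2, 0.4)
  # calibrate mixing weights so two neighbors bracket r2 = 0.5
  other <- rbinom(n, 2, 0.4)
  mix <- function(lam) lam * tag + (1 - lam) * other
  r2_at <- function(lam) ld_r2(tag, mix(lam))
  lam_lo <- uniroot(function(l) r2_at(l) - 0.49, c(0.01, 0.99))$root
  lam_hi <- uniroot(function(l) r2_at(l) - 0.51, c(0.01, 0.99))$root
  dos <- cbind(tag, mix(lam_lo), mix(lam_hi), rbinom(n, 2, 0.4))
  dos <- pmin(pmax(dos, 0), 2)
  g <- toy_genotype_matrix(dos, pos = c(1e6, 1.2e6, 1.4e6, 5e6))
  out <- expand_tag_snps("v001", g)
  # v002 sits at r2 < 0.5 (excluded), v003 just above (included),
  # v004 is beyond the 1 Mb window
  expect_setequal(out$variants$id, c("v001", "v003"))

  # a tag with no in-window neighbors returns only itself
  lone <- toy_genotype_matrix(cbind(tag, other), pos = c(1e6, 5e6))
  expect_identical(expand_tag_snps("v001", lone)$variants$id, "v001")

  # overlapping windows: union without duplicates, invariant to tag order
  twin <- toy_genotype_matrix(cbind(tag, tag, mix(lam_hi)),
                              pos = c(1e6, 1.1e6, 1.2e6))
  e12 <- expand_tag_snps(c("v001", "v002"), twin)
  e21 <- expand_tag_snps(c("v002", "v001"), twin)
  expect_false(anyDuplicated(e12$variants$id) > 0)
  expect_identical(e12$variants, e21$variants)
  expect_identical(e12$dosages, e21$dosages)

  expect_warning(expand_tag_snps(c("v001", "nope"), lone), "nope")
})

test_that("ancestry assignment separates Balding-Nichols populations", {
  set.seed(6)
  ref <- balding_nichols(100, 500, fst = 0.1)
  cohort_rows <- c(1:25, 101:125)  # known POP1 / POP2 members
  ref_g <- toy_genotype_matrix(ref$dosages)
  cohort_g <- genotype_matrix(ref$dosages[cohort_rows, ], ref_g$variants,
                              sprintf("C%03d", seq_along(cohort_rows)))
  res <- assign_ancestry(cohort_g, ref_g, ref$labels)
  truth <- ref$labels[cohort_rows]
  expect_gte(mean(res$population == truth), 0.95)

  # duplicated cohort sample: identical label and coordinates
  dup <- genotype_matrix(ref$dosages[c(1, 1), ], ref_g$variants,
                         c("D1", "D2"))
  res2 <- assign_ancestry(dup, ref_g, ref$labels)
  expect_identical(res2$population[1], res2$population[2])
  expect_equal(res2$PC1[1], res2$PC1[2])

  # reference sample scored against the reference keeps its own label
  self <- genotype_matrix(ref$dosages[1, , drop = FALSE], ref_g$variants,
                          "SELF")
  expect_identical(assign_ancestry(self, ref_g, ref$labels)$population,
                   ref$labels[1])

  small <- subset_variants(ref_g, 1:10)
  expect_error(assign_ancestry(subset_variants(cohort_g, 1:10), small,
                               ref$labels), "insufficient overlap")
})
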