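make_de_matrix <- function(vals, groups) {
  n <- nrow(vals)
  ex <- expression_matrix(vals, sprintf("S%04d", seq_len(n)),
                          sprintf("f%04d", seq_len(ncol(vals))),
                          present = matrix(TRUE, n, ncol(vals)))
  list(ex = ex, groups = groups)
}

test_that("the null type-I error rate of the DE test is nominal", {
  set.seed(50)
  n_feat <- 10000
  vals <- matrix(rnorm(60 * n_feat, 5), 60, n_feat)
  inp <- make_de_matrix(vals, rep(c("tumor", "normal"), each = 30))
  de <- differential_test(inp$ex, inp$groups, group_max_absent = 60)
  rate <- mean(de$p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("a planted tumor shift is estimated without bias", {
  set.seed(51)
  fc <- replicate(100, {
    vals <- cbind(c(rnorm(200, 5 + 1.04), rnorm(200, 5)))
    inp <- make_de_matrix(vals, rep(c("tumor", "normal"), each = 200))
    differential_test(inp$ex, inp$groups, group_max_absent = 400)$log2fc
  })
  expect_lt(abs(mean(fc) - 1.04), 0.05)
})

test_that("features absent in more than the per-group allowance are excluded", {
  set.seed(52)
  vals <- matrix(rnorm(40 * 2, 5), 40, 2)
  groups <- rep(c("tumor", "normal"), each = 20)
  ex <- expression_matrix(vals, sprintf("S%04d", 1:40), c("fa", "fb"))
  ex$present[groups == "normal", "fb"][1:11] <- FALSE
  de <- differential_test(ex, groups, group_max_absent = 10)
  expect_identical(de$feature_id, "fa")
  excl <- attr(de, "excluded")
  expect_identical(excl$feature_id, "fb")
  de2 <- differential_test(ex, groups, group_max_absent = 11)
  expect_setequal(de2$feature_id, c("fa", "fb"))
})

test_that("the Cox fit matches the survival package with Efron ties", {
  skip_if_not_installed("survival")
  set.seed(53)
  for (i in 1:5) {
    n <- 150
    z <- rbinom(n, 1, 0.5)
    time <- ceiling(rexp(n, 0.1 * exp(0.6 * z)) * 4) / 4  # forced ties
    event <- rbinom(n, 1, 0.75)
    mine <- cox_fit(z, time, event)
    ref <- survival::coxph(survival::Surv(time, event) ~ z,
                           ties = "efron")
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("a null group label gives hazard ratios near 1", {
  ok <- 0L
  for (s in 1:100) {
    set.seed(600 + s)
    n <- 500
    z <- rbinom(n, 1, 0.5)
    time <- rexp(n, 0.04)
    cens <- runif(n, 0, 80)
    fit <- cox_fit(z, pmin(time, cens), as.integer(time <= cens))
    if (fit$hr >= 0.8 && fit$hr <= 1.25) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("swapping group labels inverts the hazard ratio", {
  set.seed(54)
  n <- 300
  z <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(-0.7 * z))
  event <- rep(1L, n)
  a <- cox_fit(z, time, event)
  b <- cox_fit(1 - z, time, event)
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-6)
  expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-6)
})

test_that("Cox approaches the closed-form rate ratio without censoring", {
  set.seed(55)
  n <- 5000
  z <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.05 * ifelse(z == 1, 2, 1))
  fit <- cox_fit(z, time, rep(1L, n))
  expect_lt(abs(fit$hr - 2) / 2, 0.05)
})

test_that("complete separation is flagged and capped", {
  time <- c(1:10, 101:110)
  z <- rep(c(1, 0), each = 10)
  expect_warning(fit <- cox_fit(z, time, rep(1L, 20)), "separation")
  expect_true(fit$separation)
  expect_equal(abs(fit$beta), 15)
})

test_that("log-rank matches a hand-computed table and its degenerate cases", {
  # worked 10-sample dataset, hand computation of O-E and variance
  time <- c(3, 5, 7, 9, 11, 4, 6, 8, 10, 12)
  event <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 5)
  oe <- 0; v <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    n_j <- sum(time >= t0); n1 <- sum(time >= t0 & grp == "A")
    d <- sum(event == 1 & time == t0)
    d1 <- sum(event == 1 & time == t0 & grp == "A")
    oe <- oe + d1 - d * n1 / n_j
    if (n_j > 1) {
      v <- v + d * (n1 / n_j) * (1 - n1 / n_j) * (n_j - d) / (n_j - 1)
    }
  }
  res <- km_logrank(grp, time, event)
  expect_equal(res$chi_square, oe^2 / v, tolerance = 1e-6)

  skip_if_not_installed("survival")
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(res$chi_square, unname(ref$chisq), tolerance = 1e-6)
})

test_that("identical groups give log-rank statistic 0 and p = 1", {
  time <- rep(c(2, 4, 6, 8, 10), 2)
  event <- rep(c(1, 1, 0, 1, 1), 2)
  grp <- rep(c("A", "B"), each = 5)
  res <- km_logrank(grp, time, event)
  expect_equal(res$chi_square, 0)
  expect_equal(res$p, 1)
})

test_that("the KM estimate without censoring is the empirical survival function", {
  set.seed(56)
  time <- sort(sample(1:100, 20))
  res <- km_logrank(rep(c("A", "B"), each = 10), time, rep(1L, 20))
  a <- res$km_curves[res$km_curves$group == "A", ]
  ta <- time[1:10]
  for (k in seq_len(nrow(a))) {
    expect_equal(a$survival[k], mean(ta > a$time[k]))
  }
})

test_that("the median-split survival screen recovers a protective gene", {
  set.seed(57)
  n <- 400
  vals <- matrix(rnorm(n * 3, 8), n, 3)
  rate <- 0.04 * exp(log(0.46) * (vals[, 2] > median(vals[, 2])))
  t_ev <- rexp(n, rate)
  cens <- runif(n, 0, 80)
  surv <- data.frame(sample_id = sprintf("S%04d", 1:n),
                     time = pmin(t_ev, cens),
                     event = as.integer(t_ev <= cens))
  ex <- expression_matrix(vals, surv$sample_id, c("g1", "g2", "g3"))
  scr <- survival_screen(ex, surv)
  expect_lt(scr$hr[scr$feature_id == "g2"], 0.6)
  expect_lt(scr$q[scr$feature_id == "g2"], 0.05)
  expect_gt(min(scr$p[scr$feature_id != "g2"]), 0.001)
})

test_that("2x2 odds ratios reproduce the published clinicopathological values", {
  expect_equal(round(or_2x2(c(16, 4, 6, 13))$or, 3), 8.667)
  expect_equal(or_2x2(c(16, 4, 8, 11))$or, 5.50)
  expect_equal(or_2x2(c(1, 1, 1, 1))$or, 1.0)
})

test_that("odds ratios have the table symmetries and match logistic regression", {
  set.seed(58)
  tab <- matrix(c(16, 4, 6, 13), 2, 2, byrow = TRUE)
  base <- or_2x2(tab)
  # swapping both rows and both columns leaves the OR unchanged
  expect_equal(or_2x2(tab[2:1, 2:1])$or, base$or)
  # swapping one row inverts it
  expect_equal(or_2x2(tab[2:1, ])$or, 1 / base$or)

  for (i in 1:50) {
    cells <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    res <- or_2x2(cells)
    df <- data.frame(
      outcome = rep(c(1, 1, 0, 0), times = c(cells[1, 1], cells[2, 1],
                                             cells[1, 2], cells[2, 2])),
      exposed = rep(c(1, 0, 1, 0), times = c(cells[1, 1], cells[2, 1],
                                             cells[1, 2], cells[2, 2])))
    fit <- glm(outcome ~ exposed, family = binomial, data = df,
               control = glm.control(epsilon = 1e-12))
    expect_equal(res$or, exp(unname(coef(fit)[2])), tolerance = 1e-6)
    expect_equal(res$se, summary(fit)$coefficients[2, 2], tolerance = 1e-4)
    if (res$p > 1e-8) {
      expect_equal(res$p, summary(fit)$coefficients[2, 4], tolerance = 1e-4)
    }
  }
})

test_that("zero cells are flagged unless the Haldane correction is requested", {
  res <- or_2x2(c(5, 0, 3, 7))
  expect_true(res$zero_cell)
  expect_true(is.infinite(res$or))
  expect_true(is.na(res$p))
  res2 <- or_2x2(c(5, 0, 3, 7), haldane = TRUE)
  expect_false(res2$zero_cell)
  expect_true(is.finite(res2$or))
  expect_error(or_2x2(c(0, 0, 0, 0)), "zero")
})

test_that("all printed clinicopathological odds ratios are reproduced to 3 decimals", {
  path <- system.file("extdata", "ndufs1_luad_clinico_2x2.tsv",
                      package = "eqtlmr")
  tab <- clinico_association(path)
  printed <- c(`Age` = 1.091, `Sex` = 1.671, `Stage` = 4.121,
               `T stage` = 1.429, `N stage` = 5.500,
               `Differentiation` = 0.225, `ki67` = 2.571,
               `Tumor maximum diameter` = 4.000,
               `Lymphatic and vascular invasion` = 8.667,
               `Nerve invasion` = 2.182)
  expect_equal(round(tab$or[match(names(printed), tab$characteristic)], 3),
               unname(printed))
})
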