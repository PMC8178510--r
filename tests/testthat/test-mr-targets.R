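test_that("a noiseless causal chain returns the exact Wald ratio", {
  set.seed(30)
  g <- rbinom(100, 2, 0.4)
  x <- as.numeric(g)
  y <- 2 * x
  est <- wald_iv(g, x, y)
  expect_equal(est$beta1_iv, 2.0, tolerance = 1e-12)
  expect_true(is.infinite(est$first_stage_f))
})

test_that("the IV estimate removes confounding bias that OLS keeps", {
  set.seed(31)
  n <- 5000
  g <- rbinom(n, 2, 0.3)
  u <- rnorm(n)
  x <- 0.5 * g + u + rnorm(n)
  y <- 0.5 * x + u + rnorm(n)
  naive <- unname(coef(lm(y ~ x))[2])
  expect_gt(naive - 0.5, 0.2)
  est <- wald_iv(g, x, y)
  expect_lt(abs(est$beta1_iv - 0.5), 0.05)
  # single-instrument 2SLS is the same estimator
  expect_equal(est$beta1_iv, oracle_2sls(g, x, y), tolerance = 1e-10)
})

test_that("an exactly orthogonal exposure raises an undefined-instrument error", {
  set.seed(32)
  g <- rbinom(50, 2, 0.4)
  x <- resid(lm(rnorm(50) ~ g))  # numerically zero covariance with g
  y <- rnorm(50)
  expect_error(wald_iv(g, x, y), "undefined instrument")
  # a weak-but-finite first stage passes through instead
  x2 <- 0.01 * g + rnorm(50)
  expect_s3_class(wald_iv(g, x2, y), "iv_estimate")
})

test_that("first-stage F follows its closed form and null distribution", {
  set.seed(33)
  # construct exposure with sample R^2 exactly 0.2 at n = 227
  n <- 227
  g <- rbinom(n, 2, 0.3)
  e <- resid(lm(rnorm(n) ~ g))
  gc <- g - mean(g)
  x <- sqrt(0.2) * gc / sqrt(sum(gc^2)) + sqrt(0.8) * e / sqrt(sum(e^2))
  fs <- weak_instrument_f(g, x)
  expect_equal(fs$r2, 0.2, tolerance = 1e-10)
  expect_equal(fs$f, 56.25, tolerance = 1e-8)

  # null simulation: p uniform, mean F near 1
  stats <- replicate(1000, {
    gg <- rbinom(100, 2, 0.3)
    ff <- weak_instrument_f(gg, rnorm(100))
    c(ff$f, ff$p)
  })
  ks <- suppressWarnings(stats::ks.test(stats[2, ], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(stats[1, ]) - 1), 0.25)

  # perfect first stage diverges
  expect_true(is.infinite(weak_instrument_f(g, as.numeric(g))$f))
})

test_that("2SLS and the Wald ratio agree to 1e-10 on random data", {
  set.seed(34)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(g) == 0) next
    x <- runif(1, -1, 1) * g + rnorm(n)
    y <- runif(1, -1, 1) * x + rnorm(n)
    expect_equal(wald_iv(g, x, y)$beta1_iv, oracle_2sls(g, x, y),
                 tolerance = 1e-10)
  }
})

test_that("recoding the instrument (g -> 2 - g) changes neither estimate nor F", {
  set.seed(35)
  g <- rbinom(80, 2, 0.4)
  x <- 0.6 * g + rnorm(80)
  y <- 0.4 * x + rnorm(80)
  a <- wald_iv(g, x, y)
  b <- wald_iv(2 - g, x, y)
  expect_equal(a$beta1_iv, b$beta1_iv, tolerance = 1e-12)
  expect_equal(a$first_stage_f, b$first_stage_f, tolerance = 1e-9)
})

test_that("IV is closer to the truth than OLS under confounding (median over seeds)", {
  errs <- t(sapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    u <- rnorm(n)
    x <- 0.5 * g + u + rnorm(n)
    y <- 0.5 * x + u + rnorm(n)
    c(iv = abs(wald_iv(g, x, y)$beta1_iv - 0.5),
      ols = abs(unname(coef(lm(y ~ x))[2]) - 0.5))
  }))
  expect_lt(median(errs[, "iv"]), median(errs[, "ols"]))
})

make_funnel_fixture <- function() {
  # 300 genes with a fully known pass/fail pattern at every stage
  genes <- sprintf("g%03d", 1:300)
  score <- rep(1, 300); score[1:40] <- 0.05          # fail (a)
  present <- rep(150, 300); present[41:80] <- 99     # fail (b)
  p_weak <- rep(1e-12, 300); p_weak[81:140] <- 0.9   # fail (c)
  de_p <- rep(1e-12, 300); de_p[141:200] <- 0.9      # fail (d)
  de_lfc <- rep(1, 300); de_lfc[141:200] <- 0.1
  sv_p <- rep(1e-12, 300); sv_p[201:260] <- 0.9      # fail (e)
  list(
    candidates = data.frame(gene_id = genes, integrated_score = score,
                            present_calls = present),
    iv = data.frame(snp_id = "s1", mirna_id = "m1", mrna_id = genes,
                    p_weak = p_weak),
    de = data.frame(feature_id = genes, log2fc = de_lfc, p = de_p),
    sv = data.frame(feature_id = genes, p = sv_p),
    expected = c(300, 260, 220, 160, 100, 40)
  )
}

test_that("the five-criterion funnel reproduces a planted pass/fail pattern", {
  fx <- make_funnel_fixture()
  fr <- run_funnel(fx$candidates, fx$iv, fx$de, fx$sv)
  expect_equal(fr$stages$n_in, fx$expected[1:5])
  expect_equal(fr$stages$n_out, fx$expected[2:6])
  expect_true(all(diff(fr$stages$n_out) <= 0))
  expect_equal(length(fr$survivors), 40L)

  # single-gene threshold semantics
  one <- fr$genes[fr$genes$gene_id == "g001", ]
  expect_false(one$score_pass)
  expect_identical(one$reason, "integrated_score")
  two <- fr$genes[fr$genes$gene_id == "g050", ]
  expect_identical(two$reason, "present_calls")
})

test_that("the funnel is invariant to candidate order and fails missing statistics", {
  fx <- make_funnel_fixture()
  set.seed(36)
  shuffled <- fx$candidates[sample(nrow(fx$candidates)), ]
  a <- run_funnel(fx$candidates, fx$iv, fx$de, fx$sv)
  b <- run_funnel(shuffled, fx$iv, fx$de, fx$sv)
  expect_identical(a$stages, b$stages)
  expect_identical(a$genes, b$genes)

  # drop the DE row of a gene that reaches stage (d): it must fail "missing"
  de2 <- fx$de[fx$de$feature_id != "g300", ]
  c <- run_funnel(fx$candidates, fx$iv, de2, fx$sv)
  g300 <- c$genes[c$genes$gene_id == "g300", ]
  expect_false(g300$de_pass)
  expect_identical(g300$reason, "missing")
})

test_that("borderline integrated scores and present calls follow the stated thresholds", {
  cands <- data.frame(gene_id = c("a", "b", "c", "d"),
                      integrated_score = c(0.09, 0.1, 1, 1),
                      present_calls = c(500, 500, 99, 100))
  iv <- data.frame(snp_id = "s", mirna_id = "m", mrna_id = cands$gene_id,
                   p_weak = 1e-10)
  de <- data.frame(feature_id = cands$gene_id, log2fc = 1, p = 1e-10)
  sv <- data.frame(feature_id = cands$gene_id, p = 1e-10)
  fr <- run_funnel(cands, iv, de, sv)
  expect_false(fr$genes$score_pass[fr$genes$gene_id == "a"])
  expect_true(fr$genes$score_pass[fr$genes$gene_id == "b"])
  expect_false(fr$genes$present_pass[fr$genes$gene_id == "c"])
  expect_identical(fr$survivors, c("b", "d"))
})
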