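#' Differential expression between tumor and normal samples
#'
#' Per-feature Welch two-sample t-test on log2 expression (a paired test is
#' available for matched designs). Features absent (no present call) in
#' more than `group_max_absent` samples in either group are excluded
#' before testing; log2 fold change is mean(tumor) - mean(normal);
#' q-values are Benjamini-Hochberg across the retained features. A feature
#' is called differentially expressed when |log2fc| exceeds
#' `log2(fc_threshold)` and q falls below `q_threshold`.
#'
#' @param expr an [expression_matrix()].
#' @param groups character/factor per sample with levels containing
#'   `"tumor"` and `"normal"`.
#' @param fc_threshold linear-scale fold-change threshold (default 2; the
#'   mRNA funnel stage passes `2^0.5`).
#' @param q_threshold FDR threshold for the DE call (default 0.01).
#' @param group_max_absent maximum tolerated absent samples per group
#'   (default 10).
#' @param paired if `TRUE`, a paired t-test on samples in matched order.
#' @return data.frame of class `de_results`: `feature_id`, `log2fc`,
#'   `t_stat`, `p`, `q`, `n_tumor`, `n_normal`, `called`; excluded
#'   features with reasons in attribute `"excluded"`.
#' @export
differential_test <- function(expr, groups, fc_threshold = 2,
                              q_threshold = 0.01, group_max_absent = 10,
                              paired = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  groups <- as.character(groups)
  if (length(groups) != length(expr$sample_ids)) {
    stop("groups must align with expression samples")
  }
  it <- groups == "tumor"; inr <- groups == "normal"
  if (sum(it) < 2L || sum(inr) < 2L) {
    stop("both groups need at least 2 samples")
  }
  rows <- list(); excluded <- list()
  for (f in expr$feature_ids) {
    v <- expr$values[, f]
    pres <- expr$present[, f]
    absent_t <- sum(!pres[it]); absent_n <- sum(!pres[inr])
    if (absent_t > group_max_absent || absent_n > group_max_absent) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        feature_id = f, reason = "absent_in_group",
        stringsAsFactors = FALSE)
      next
    }
    vt <- v[it & !is.na(v)]; vn <- v[inr & !is.na(v)]
    if (length(vt) < 2L || length(vn) < 2L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        feature_id = f, reason = "group_all_missing",
        stringsAsFactors = FALSE)
      next
    }
    tt <- if (paired) {
      ok <- !is.na(v[it]) & !is.na(v[inr])
      stats::t.test(v[it][ok], v[inr][ok], paired = TRUE)
    } else {
      stats::t.test(vt, vn, var.equal = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = f, log2fc = mean(vt) - mean(vn),
      t_stat = unname(tt$statistic), p = tt$p.value,
      n_tumor = length(vt), n_normal = length(vn),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% data.frame(
    feature_id = character(0), log2fc = numeric(0), t_stat = numeric(0),
    p = numeric(0), n_tumor = integer(0), n_normal = integer(0))
  out$q <- bh_fdr(out$p)
  out$called <- abs(out$log2fc) > log2(fc_threshold) & out$q < q_threshold
  rownames(out) <- NULL
  class(out) <- c("de_results", "data.frame")
  attr(out, "excluded") <- do.call(rbind, excluded) %||%
    data.frame(feature_id = character(0), reason = character(0))
  out
}

#' Cox proportional-hazards fit for a single covariate
#'
#' Newton-Raphson maximization of the partial likelihood with Efron
#' handling of tied event times. For a 0/1 group covariate the hazard
#' ratio is high vs low. Monotone likelihood (complete separation) is
#' detected by a diverging coefficient, which is capped at |beta| = 15
#' with a warning and flagged.
#'
#' @param covariate numeric per-sample covariate (e.g. a 0/1 high-vs-low
#'   expression indicator).
#' @param time,event survival follow-up (> 0) and event indicator (1 =
#'   death, 0 = censored).
#' @return An object of class `cox_result`: list with `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `loglik`, `n`, `n_event`, `separation`.
#' @export
cox_fit <- function(covariate, time, event) {
  ok <- !is.na(covariate) & !is.na(time) & !is.na(event)
  z <- as.numeric(covariate[ok]); time <- time[ok]; event <- event[ok]
  if (any(time <= 0)) stop("survival times must be > 0")
  if (sum(event) < 2L) stop("fewer than 2 events")
  if (stats::var(z) == 0) stop("covariate is constant")
  n <- length(z)

  # sort by descending time so risk-set sums are cumulative sums
  ord <- order(time, decreasing = TRUE)
  z <- z[ord]; time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  # index of the last sorted element still at risk at each event time
  risk_idx <- vapply(ev_times, function(t0) sum(time >= t0), integer(1))
  dead_at <- lapply(ev_times, function(t0) which(event == 1 & time == t0))

  loglik_grad <- function(beta) {
    eta <- beta * z
    w <- exp(eta)
    cw0 <- cumsum(w); cw1 <- cumsum(w * z); cw2 <- cumsum(w * z^2)
    ll <- 0; u <- 0; info <- 0
    for (k in seq_along(ev_times)) {
      m <- risk_idx[k]
      dead <- dead_at[[k]]
      d <- length(dead)
      s0 <- cw0[m]; s1 <- cw1[m]; s2 <- cw2[m]
      wd <- w[dead]; zd <- z[dead]
      s0d <- sum(wd); s1d <- sum(wd * zd); s2d <- sum(wd * zd^2)
      ll <- ll + sum(eta[dead])
      u <- u + sum(zd)
      for (l in seq_len(d) - 1L) {
        a0 <- s0 - (l / d) * s0d
        a1 <- s1 - (l / d) * s1d
        a2 <- s2 - (l / d) * s2d
        ll <- ll - log(a0)
        u <- u - a1 / a0
        info <- info + a2 / a0 - (a1 / a0)^2
      }
    }
    list(ll = ll, u = u, info = info)
  }

  beta <- 0; separation <- FALSE
  for (iter in 1:30) {
    lg <- loglik_grad(beta)
    if (lg$info <= 0) break
    step <- lg$u / lg$info
    beta_new <- beta + step
    if (abs(beta_new) > 15) {
      separation <- TRUE
      beta <- sign(beta_new) * 15
      warning("monotone partial likelihood (complete separation); ",
              "coefficient capped at |beta| = 15")
      break
    }
    beta <- beta_new
    if (abs(step) < 1e-9) break
  }
  lg <- loglik_grad(beta)
  se <- if (lg$info > 0) 1 / sqrt(lg$info) else NA_real_
  zstat <- beta / se
  structure(
    list(beta = beta, se = se, hr = exp(beta),
         ci_low = exp(beta - 1.959963984540054 * se),
         ci_high = exp(beta + 1.959963984540054 * se),
         p = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE),
         loglik = lg$ll, n = n, n_event = sum(event),
         separation = separation),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result: HR = %.4f (95%% CI %.4f-%.4f), p = %.3g, n = %d (%d events)\n",
              x$hr, x$ci_low, x$ci_high, x$p, x$n, x$n_event))
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank chi-square (observed minus expected events in group 1, with
#' the hypergeometric variance at each distinct event time).
#'
#' @param group_labels per-sample labels with exactly two distinct values.
#' @param time,event follow-up and event indicator as in [cox_fit()].
#' @return list with `chi_square`, `p`, and `km_curves` (data.frame
#'   `group`, `time`, `n_risk`, `n_event`, `survival`).
#' @export
km_logrank <- function(group_labels, time, event) {
  group_labels <- as.character(group_labels)
  lv <- sort(unique(group_labels))
  if (length(lv) != 2L) stop("exactly two groups are required")
  if (sum(event) < 1L) stop("at least one event is required")
  g1 <- group_labels == lv[1]

  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t0 in ev_times) {
    at_risk <- time >= t0
    n_j <- sum(at_risk); n1_j <- sum(at_risk & g1)
    d_j <- sum(event == 1 & time == t0)
    d1_j <- sum(event == 1 & time == t0 & g1)
    e1_j <- d_j * n1_j / n_j
    o_minus_e <- o_minus_e + (d1_j - e1_j)
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) *
        (n_j - d_j) / (n_j - 1)
    }
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  p <- if (v > 0) stats::pchisq(chi2, 1, lower.tail = FALSE) else 1

  curves <- lapply(lv, function(lb) {
    sel <- group_labels == lb
    tt <- time[sel]; ee <- event[sel]
    times <- sort(unique(tt[ee == 1]))
    surv <- 1; rows <- list()
    for (t0 in times) {
      n_r <- sum(tt >= t0); d <- sum(ee == 1 & tt == t0)
      surv <- surv * (1 - d / n_r)
      rows[[length(rows) + 1L]] <- data.frame(
        group = lb, time = t0, n_risk = n_r, n_event = d,
        survival = surv, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  curves <- do.call(rbind, curves) %||%
    data.frame(group = character(0), time = numeric(0),
               n_risk = integer(0), n_event = integer(0),
               survival = numeric(0))
  list(chi_square = chi2, p = p, km_curves = curves)
}

#' Median-split survival screen over expression features
#'
#' Dichotomizes each feature at the cohort median (high = strictly above),
#' fits [cox_fit()] on the high-vs-low indicator, and attaches
#' Benjamini-Hochberg q-values across features.
#'
#' @param expr an [expression_matrix()].
#' @param survival data.frame `sample_id`, `time`, `event`.
#' @param features optional subset of feature IDs.
#' @return data.frame `feature_id`, `hr`, `ci_low`, `ci_high`, `p`, `q`,
#'   `n`; features whose fit failed are dropped with a reason in attribute
#'   `"failed"`.
#' @export
survival_screen <- function(expr, survival, features = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(features)) features <- expr$feature_ids
  idx <- match(survival$sample_id, expr$sample_ids)
  rows <- list(); failed <- list()
  for (f in features) {
    v <- expr$values[idx, f]
    med <- stats::median(v, na.rm = TRUE)
    high <- as.numeric(v > med)
    fit <- tryCatch(cox_fit(high, survival$time, survival$event),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      failed[[length(failed) + 1L]] <- data.frame(
        feature_id = f, reason = fit, stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = f, hr = fit$hr, ci_low = fit$ci_low,
      ci_high = fit$ci_high, p = fit$p, n = fit$n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% data.frame(
    feature_id = character(0), hr = numeric(0), ci_low = numeric(0),
    ci_high = numeric(0), p = numeric(0), n = integer(0))
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "failed") <- do.call(rbind, failed) %||%
    data.frame(feature_id = character(0), reason = character(0))
  out
}

#' Odds ratio and Wald p-value of a 2x2 table
#'
#' Cross-product odds ratio of a 2x2 table with rows = exposure (e.g.
#' high/low expression) and columns = outcome levels (numerator level
#' first): OR = (a d) / (b c). The Wald p-value uses the log-OR standard
#' error sqrt(1/a + 1/b + 1/c + 1/d) and equals the Wald test of a
#' single-binary-predictor logistic regression. Zero cells yield OR 0,
#' `Inf` or `NaN` with `zero_cell = TRUE` and no p-value unless the
#' Haldane-Anscombe 0.5 correction is requested.
#'
#' @param counts 2x2 matrix, or length-4 vector (a, b, c, d) in row-major
#'   order.
#' @param haldane apply the +0.5 continuity correction (default `FALSE`).
#' @return list with `or`, `log_or`, `se`, `p`, `zero_cell`.
#' @export
or_2x2 <- function(counts, haldane = FALSE) {
  if (is.matrix(counts)) {
    if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2")
    x <- as.numeric(t(counts))
  } else {
    if (length(counts) != 4L) stop("counts must have 4 cells")
    x <- as.numeric(counts)
  }
  if (any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("table total is zero")
  zero <- any(x == 0)
  if (zero && haldane) {
    x <- x + 0.5
    zero <- FALSE
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  or <- (a * d) / (b * c)
  if (zero) {
    return(list(or = or, log_or = log(or), se = NA_real_, p = NA_real_,
                zero_cell = TRUE))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  list(or = or, log_or = log(or), se = se,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       zero_cell = FALSE)
}

#' Clinicopathological association report from 2x2 counts
#'
#' Reads a long-format table of per-characteristic counts (columns
#' `characteristic`, `level`, `high`, `low`, and optionally
#' `numerator_level`) and computes, per characteristic, the odds ratio of
#' high vs low expression with the designated outcome level as numerator
#' (default: the first listed level) plus its Wald p-value. The 2x2 is
#' laid out as rows = expression group (high, low), columns = (numerator
#' level, other level).
#'
#' @param counts data.frame or path to a TSV in the layout above.
#' @return data.frame `characteristic`, `a`, `b`, `c`, `d`, `or`, `p`
#'   (cells in row-major 2x2 order).
#' @export
clinico_association <- function(counts) {
  if (is.character(counts)) counts <- read_tsv(counts)
  req <- c("characteristic", "level", "high", "low")
  if (!all(req %in% names(counts))) {
    stop("counts needs columns ", paste(req, collapse = ", "))
  }
  out <- list()
  for (ch in unique(counts$characteristic)) {
    sub <- counts[counts$characteristic == ch, , drop = FALSE]
    if (nrow(sub) != 2L) stop("characteristic ", ch, " must have 2 levels")
    num_level <- if ("numerator_level" %in% names(sub) &&
                     !all(is.na(sub$numerator_level))) {
      sub$numerator_level[!is.na(sub$numerator_level)][1]
    } else {
      sub$level[1]
    }
    i <- match(num_level, sub$level)
    if (is.na(i)) stop("numerator level ", num_level, " not found for ", ch)
    j <- setdiff(1:2, i)
    tab <- matrix(c(sub$high[i], sub$high[j],
                    sub$low[i], sub$low[j]), 2L, 2L, byrow = TRUE,
                  dimnames = list(c("high", "low"),
                                  sub$level[c(i, j)]))
    res <- or_2x2(tab)
    out[[length(out) + 1L]] <- data.frame(
      characteristic = ch, a = tab[1, 1], b = tab[1, 2],
      c = tab[2, 1], d = tab[2, 2], or = res$or, p = res$p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
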