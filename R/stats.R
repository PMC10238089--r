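#' Welch's t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch–Satterthwaite
#' fractional degrees of freedom and a two-tailed p-value. Hedges' g is
#' computed from the pooled SD with the small-sample correction
#' `J = 1 - 3 / (4*(n1+n2) - 9)`.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list of class `group_stat`: `statistic`, `df`, `p`, `tail`,
#'   `effect_size` (named), `n`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 == 0 && s2 == 0) stop("undefined: both variances are zero", call. = FALSE)
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  g <- hedges_g_summary(m1, s1, n1, m2, s2, n2)
  group_stat(t, df, p, "two", c("hedges_g" = g), c(n1, n2))
}

group_stat <- function(statistic, df, p, tail, effect_size, n) {
  structure(list(statistic = statistic, df = df, p = p, tail = tail,
                 effect_size = effect_size, n = n),
            class = "group_stat")
}

hedges_g_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) return(NA_real_)
  d <- (m1 - m2) / sp
  d * (1 - 3 / (4 * (n1 + n2) - 9))
}

#' Welch's two-sample t-test on raw samples
#'
#' Equals [welch_t_summary()] applied to the samples' own moments; the tail
#' argument selects a one-sided (`"one"`, testing `mean(x) > mean(y)`) or
#' two-sided p-value.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param tail `"two"` (default) or `"one"`.
#' @return a `group_stat`.
#' @export
welch_t <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  res <- welch_t_summary(mean(x), stats::sd(x), length(x),
                         mean(y), stats::sd(y), length(y))
  if (tail == "one") {
    res$p <- stats::pt(res$statistic, res$df, lower.tail = FALSE)
    res$tail <- "one"
  }
  res
}

#' One-sample and paired t-tests
#'
#' `one_sample_t` tests `mean(x) = mu`; `paired_t` is the one-sample test on
#' the differences `x - y`. Cohen's d is `mean/sd` of the (differenced)
#' sample. One-tailed tests reject for large positive t.
#'
#' @param x,y numeric samples.
#' @param mu null mean.
#' @param tail `"two"` or `"one"` (positive direction).
#' @return a `group_stat`.
#' @export
one_sample_t <- function(x, mu = 0, tail = c("two", "one")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("undefined: sample has zero variance", call. = FALSE)
  t <- (mean(x) - mu) / (s / sqrt(n))
  df <- n - 1
  p <- if (tail == "two") 2 * stats::pt(-abs(t), df)
       else stats::pt(t, df, lower.tail = FALSE)
  group_stat(t, df, p, tail, c(cohens_d = (mean(x) - mu) / s), n)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(x, y, tail = c("two", "one")) {
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  one_sample_t(x - y, mu = 0, tail = tail)
}

#' Hedges' g between two samples
#'
#' Pooled-SD standardized mean difference with the small-sample correction
#' `J = 1 - 3/(4*(n1+n2) - 9)`.
#'
#' @param x,y numeric samples.
#' @return scalar effect size.
#' @export
hedges_g <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2", call. = FALSE)
  g <- hedges_g_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y))
  if (is.na(g)) stop("undefined: zero pooled variance", call. = FALSE)
  g
}

#' Fisher z transform of a correlation
#'
#' @param r correlation with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("'r' must satisfy |r| < 1", call. = FALSE)
  atanh(r)
}

#' Bootstrap mediation analysis
#'
#' Linear mediator model `M ~ group` and outcome model `Y ~ group + M`; the
#' average causal mediation effect (ACME) is the product of the group-to-
#' mediator and mediator-to-outcome coefficients, the average direct effect
#' (ADE) is the group coefficient of the outcome model, and the total effect
#' their sum. Inference is by nonparametric bootstrap over subjects with
#' percentile confidence intervals; a resample missing a group is redrawn
#' (at most 10 retries).
#'
#' @param group binary (0/1 or two-level) vector per subject.
#' @param mediator,outcome numeric vectors per subject.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list of class `mediation_result` with `acme`, `ade`, `total`,
#'   their bootstrap CIs and p-values, `n_boot`, `seed`.
#' @export
mediation_bootstrap <- function(group, mediator, outcome, n_boot = 5000,
                                seed = 1, conf = 0.95) {
  g <- as.numeric(factor(group)) - 1
  n <- length(g)
  if (n < 10) stop("need at least 10 subjects", call. = FALSE)
  if (length(unique(g)) != 2) stop("both groups must be represented", call. = FALSE)
  est <- function(gi, mi, yi) {
    a <- stats::coef(stats::lm(mi ~ gi))[["gi"]]
    fy <- stats::coef(stats::lm(yi ~ gi + mi))
    b <- fy[["mi"]]; ade <- fy[["gi"]]
    c(acme = a * b, ade = ade, total = a * b + ade)
  }
  point <- est(g, mediator, outcome)
  boots <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, names(point)))
  withr::with_seed(seed, {
    for (i in seq_len(n_boot)) {
      for (try in seq_len(10)) {
        ii <- sample.int(n, n, replace = TRUE)
        if (length(unique(g[ii])) == 2) break
        if (try == 10) stop("could not draw a resample with both groups", call. = FALSE)
      }
      boots[i, ] <- est(g[ii], mediator[ii], outcome[ii])
    }
  })
  alpha <- 1 - conf
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  pval <- apply(boots, 2, function(b) {
    2 * min(mean(b <= 0), mean(b >= 0))
  })
  structure(list(acme = point[["acme"]], ade = point[["ade"]],
                 total = point[["total"]], ci = ci, p = pval,
                 n_boot = n_boot, seed = seed),
            class = "mediation_result")
}
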