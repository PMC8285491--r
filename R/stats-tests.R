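#' Hypothesis-test result container
#'
#' A uniform light-weight record of a test outcome used throughout the
#' package: method, statistic, normal/t deviate where applicable, two-sided
#' p-value, effective n (after dropping zeros/missings) and any multiplicity
#' correction applied.
#'
#' @param method test name.
#' @param statistic named statistic value.
#' @param z normal or t deviate (NA if not applicable).
#' @param p two-sided p-value.
#' @param n effective sample size.
#' @param correction `"none"` or `"bonferroni"`.
#' @param note optional flag (e.g. degenerate input).
#' @return Object of class `dyadrank_test`.
#' @export
test_result <- function(method, statistic, z = NA_real_, p, n,
                        correction = "none", note = NULL) {
  structure(list(method = method, statistic = statistic, z = z, p = p,
                 n = as.integer(n), correction = correction, note = note),
            class = "dyadrank_test")
}

#' @export
print.dyadrank_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g", x$method, names(x$statistic) %||% "stat",
              x$statistic))
  if (!is.na(x$z)) cat(sprintf(", z = %.3f", x$z))
  cat(sprintf(", p = %.4g (two-sided), n = %d", x$p, x$n))
  if (x$correction != "none") cat(" [", x$correction, "-adjusted]", sep = "")
  if (!is.null(x$note)) cat("\n  note:", x$note)
  cat("\n")
  invisible(x)
}

# exact null distribution of the signed-rank statistic W+ for given ranks
# (average ranks allowed: works on doubled ranks, which are integers).
# Returns list(support2 = 0:S in doubled units, prob).
.signrank_exact <- function(ranks) {
  r2 <- as.integer(round(ranks * 2))
  total <- sum(r2)
  prob <- numeric(total + 1L)
  prob[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), prob[seq_len(total + 1L - r)])
    prob <- (prob + shifted) / 2
  }
  list(support2 = 0:total, prob = prob)
}

#' Wilcoxon signed-rank test (exact for small samples)
#'
#' Paired-sample signed-rank test on differences `x` (or `x - y`). Zero
#' differences are dropped before ranking (the conventional treatment). For
#' n <= `exact_max` (default 15) the p-value is exact, computed from the full
#' null distribution of the signed-rank sum with average ranks for ties; for
#' larger n a normal approximation with tie correction and continuity
#' correction is used. A z-deviate is always reported for comparability with
#' z-style reporting of this test in the literature. The exact p-value
#' depends on the differences only through the rank order of their
#' magnitudes and their signs, so it is invariant to monotone transforms of
#' the magnitudes.
#'
#' @param x numeric vector of differences, or first sample if `y` is given.
#' @param y optional second sample (test on `x - y`).
#' @param exact_max largest n for which the exact distribution is used.
#' @return [test_result()] with statistic `W` (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 15L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(test_result("Wilcoxon signed-rank", c(W = NA_real_), z = 0, p = 1,
                       n = 0L, note = "all differences zero (degenerate)"))
  }
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    dist <- .signrank_exact(ranks)
    w2 <- round(2 * w)
    p_le <- sum(dist$prob[dist$support2 <= w2 + 1e-9])
    p_ge <- sum(dist$prob[dist$support2 >= w2 - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  test_result("Wilcoxon signed-rank", c(W = w), z = z, p = p, n = n)
}

#' Paired t-test
#'
#' Wrapper with the package's uniform result container. Degenerate input
#' (constant differences) is flagged rather than an error.
#'
#' @param x,y paired samples.
#' @return [test_result()] with statistic `t`.
#' @export
paired_t <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2L || sd(d) == 0) {
    return(test_result("Paired t", c(t = NA_real_), p = NA_real_,
                       n = length(d),
                       note = "degenerate: constant or insufficient differences"))
  }
  ht <- t.test(x, y, paired = TRUE)
  test_result("Paired t", c(t = unname(ht$statistic)), z = unname(ht$statistic),
              p = ht$p.value, n = length(d))
}

#' Kruskal-Wallis rank-sum test
#'
#' @param groups list of numeric vectors (one per group).
#' @return [test_result()] with the chi-squared statistic.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  ht <- kruskal.test(groups)
  test_result("Kruskal-Wallis", c(chisq = unname(ht$statistic)),
              p = ht$p.value, n = sum(lengths(groups)))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups named list of numeric vectors.
#' @return List with the omnibus [test_result()] (`F`) and the Tukey table
#'   (`diff`, confidence bounds, adjusted p per group pair).
#' @export
one_way_anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), lengths(groups))))
  fit <- aov(y ~ g, data = df)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(anova = test_result("One-way ANOVA", c(F = sm[["F value"]][1]),
                           p = sm[["Pr(>F)"]][1], n = nrow(df)),
       tukey = as.data.frame(tk))
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors (pairwise-complete observations used).
#' @return [test_result()] with statistic `r`.
#' @export
pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  ht <- cor.test(x[ok], y[ok], method = "pearson")
  test_result("Pearson correlation", c(r = unname(ht$estimate)),
              z = unname(ht$statistic), p = ht$p.value, n = sum(ok))
}

#' Kolmogorov-Smirnov normality gate
#'
#' Tests a sample against a normal distribution with moments estimated from
#' the sample, as a helper for choosing parametric vs nonparametric
#' comparisons.
#'
#' @param x numeric vector.
#' @param alpha significance level for the `normal` verdict.
#' @return [test_result()] with statistic `D`; `note` carries the verdict.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 4L || sd(x) == 0) {
    return(test_result("Kolmogorov-Smirnov normality", c(D = NA_real_),
                       p = NA_real_, n = length(x),
                       note = "insufficient or constant data"))
  }
  ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  test_result("Kolmogorov-Smirnov normality", c(D = unname(ht$statistic)),
              p = ht$p.value, n = length(x),
              note = if (ht$p.value < alpha) "non-normal" else "normal")
}

#' Bonferroni correction for a declared family of tests
#'
#' Adjusts p-values as `min(1, m * p)` where `m` is the family size
#' (defaults to the number of results supplied). Families must be declared
#' explicitly by the caller.
#'
#' @param results list of [test_result()] objects.
#' @param m family size.
#' @return The list with adjusted `p` and `correction = "bonferroni"`.
#' @export
bonferroni_family <- function(results, m = length(results)) {
  stopifnot(m >= 1L)
  lapply(results, function(r) {
    r$p <- min(1, m * r$p)
    r$correction <- "bonferroni"
    r
  })
}

#' Collect test results into a flat table
#'
#' @param results named list of [test_result()] objects.
#' @return Data frame: `test, statistic, value, z, p, correction, n`.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(test = nm, method = r$method,
               statistic = names(r$statistic) %||% "stat",
               value = unname(r$statistic), z = r$z, p = r$p,
               correction = r$correction, n = r$n, stringsAsFactors = FALSE)
  }))
}
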