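#' Pearson correlation with exact two-sided p-value
#'
#' Computes the Pearson product-moment correlation between two numeric
#' vectors together with the t-statistic and the exact two-sided p-value
#' from the t distribution with `n - 2` degrees of freedom. This is the
#' primitive behind every correlation screen in the package: gene shift vs
#' weight shift across diets, taxon abundance vs gene shift, taxon abundance
#' vs individual body weight.
#'
#' @param x,y Numeric vectors of equal length with no missing values.
#' @return A list of class `"correlation_result"` with elements `r`, `n`,
#'   `df`, `t_stat`, `p_two_sided` and `degenerate` (`TRUE` when `|r| = 1`,
#'   in which case `p_two_sided = 0` by convention; noiseless synthetic
#'   fixtures hit this case legitimately). For `n < 3` only `r` is defined
#'   and the p-value is `NA`.
#' @examples
#' pearson_cor(1:4, c(2, 4, 6, 8))$r   # 1
#' pearson_cor(c(1, 2, 3), c(3, 2, 1))$r  # -1
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  if (stats::var(x) == 0) stop("undefined correlation: x has zero variance")
  if (stats::var(y) == 0) stop("undefined correlation: y has zero variance")
  r <- stats::cor(x, y)
  # guard against |r| marginally exceeding 1 through floating point
  r <- max(-1, min(1, r))
  if (n < 3) {
    return(structure(list(r = r, n = n, df = n - 2L, t_stat = NA_real_,
                          p_two_sided = NA_real_, degenerate = abs(r) == 1),
                     class = "correlation_result"))
  }
  pv <- pearson_pvalue(r, n)
  structure(list(r = r, n = as.integer(n), df = as.integer(n - 2),
                 t_stat = pv$t_stat, p_two_sided = pv$p,
                 degenerate = pv$degenerate),
            class = "correlation_result")
}

#' Two-sided p-value for a Pearson correlation coefficient
#'
#' Exact two-sided p-value for an observed Pearson r at a given number of
#' pairs, via the transformation `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `n - 2` degrees of freedom. At `df = 4` (six diets, the design used by
#' the cross-diet screens) this has the closed form
#' `p = 1 - (3/2)|r| + (1/2)|r|^3`.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Number of pairs, at least 3.
#' @return A list with `t_stat`, `p` and `degenerate`. `|r| = 1` returns
#'   `p = 0` with `degenerate = TRUE` instead of raising.
#' @examples
#' pearson_pvalue(0.83, 6)$p  # ~0.041, prints as 0.04
#' @export
pearson_pvalue <- function(r, n) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || abs(r) > 1)
    stop("r must be a single number in [-1, 1]")
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 3)
    stop("n must be a single integer >= 3")
  df <- n - 2
  if (abs(r) == 1) {
    return(list(t_stat = sign(r) * Inf, p = 0, degenerate = TRUE))
  }
  t_stat <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(t_stat = t_stat, p = p, degenerate = FALSE)
}

#' Ordinary least-squares line
#'
#' Simple linear regression of `y` on `x`, returning the quantities the
#' growth and taxon-regression stages need: slope, intercept, residual sum
#' of squares, the slope standard error, and R squared.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`; `x` must not be
#'   constant.
#' @return A list with `slope`, `intercept`, `rss`, `slope_se`, `r_squared`
#'   and `n`.
#' @export
ols_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::var(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sigma2 <- if (n > 2) rss / (n - 2) else NA_real_
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rss = rss,
       slope_se = if (is.na(sigma2)) NA_real_ else sqrt(sigma2 / sxx),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n = n)
}

#' ANCOVA comparison of two regression lines
#'
#' Nested-model analysis of covariance comparing two groups of (x, y)
#' points, as used to compare GF and FMT growth curves with age as the
#' covariate. Three models are fitted: separate lines, common slope with
#' group-specific elevations, and a single line. The slope-homogeneity F
#' compares separate lines against the common slope; the elevation F
#' compares the common slope against a single line, and is only meaningful
#' under slope homogeneity.
#'
#' @param xa,ya Covariate and response for group A.
#' @param xb,yb Covariate and response for group B.
#' @return A list of class `"ancova_result"` with the two group slopes,
#'   `F_slope`, `p_slope`, `df_slope`, `F_elev`, `p_elev`, `df_elev`, and
#'   the three residual sums of squares.
#' @export
ancova_compare <- function(xa, ya, xb, yb) {
  if (length(xa) != length(ya) || length(xb) != length(yb))
    stop("x and y lengths must match within each group")
  if (length(xa) < 3 || length(xb) < 3) stop("each group needs at least 3 points")
  x <- c(xa, xb)
  y <- c(ya, yb)
  g <- factor(rep(c("A", "B"), c(length(xa), length(xb))))
  n <- length(x)
  if (n - 4 < 1) stop("combined residual df must be at least 1")
  fit_sep <- stats::lm(y ~ x * g)     # separate slopes and intercepts
  fit_par <- stats::lm(y ~ x + g)     # common slope, separate elevations
  fit_one <- stats::lm(y ~ x)         # single line
  rss_sep <- sum(stats::residuals(fit_sep)^2)
  rss_par <- sum(stats::residuals(fit_par)^2)
  rss_one <- sum(stats::residuals(fit_one)^2)
  if (rss_sep <= 0) stop("degenerate fit: zero residual variance under the separate-lines model")
  F_slope <- (rss_par - rss_sep) / (rss_sep / (n - 4))
  F_elev <- (rss_one - rss_par) / (rss_par / (n - 3))
  cf <- stats::coef(fit_sep)
  structure(list(
    slope_A = unname(cf["x"]),
    slope_B = unname(cf["x"] + cf["x:gB"]),
    F_slope = F_slope,
    p_slope = stats::pf(F_slope, 1, n - 4, lower.tail = FALSE),
    df_slope = c(1L, as.integer(n - 4)),
    F_elev = F_elev,
    p_elev = stats::pf(F_elev, 1, n - 3, lower.tail = FALSE),
    df_elev = c(1L, as.integer(n - 3)),
    rss_separate = rss_sep, rss_common_slope = rss_par, rss_single_line = rss_one
  ), class = "ancova_result")
}

#' Welch two-sample t test
#'
#' Unpaired two-tailed t test with the Welch-Satterthwaite degrees of
#' freedom, used by the differential-expression screen on log2 expression.
#' Degenerate inputs (both groups with zero variance) are resolved by
#' convention instead of erroring, because noiseless synthetic fixtures hit
#' them: equal means give `p = 1`, unequal means give `p = 0`, both flagged.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return A list with `t_stat`, `df`, `p_two_sided` and `degenerate`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_stat = 0, df = NA_real_, p_two_sided = 1, degenerate = TRUE))
    }
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p_two_sided = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment. Thin validated wrapper around
#' [stats::p.adjust()]; idempotent on its own output and monotone in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons; defaults to `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Two-way ANOVA with type-II sums of squares
#'
#' Two-factor analysis of variance with interaction. Because gnotobiotic
#' cohorts are typically unbalanced (4 vs 7 mice per cell), type-II sums of
#' squares are used (via [car::Anova()]); for balanced layouts these reduce
#' to the classical decomposition.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible) of the same length as
#'   `values`, each with at least 2 levels. All cells of the crossed layout
#'   must be non-empty.
#' @return A data.frame with one row per effect (`factor_a`, `factor_b`,
#'   `interaction`, `residual`) and columns `ss`, `df`, `f`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (length(values) != length(a) || length(values) != length(b))
    stop("values and factors must have the same length")
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("each factor needs at least 2 levels")
  if (any(table(a, b) == 0))
    stop("unsupported layout: the two-way design has empty cells")
  if (stats::var(values) == 0) {
    # constant response: every effect explains nothing
    return(data.frame(effect = c("factor_a", "factor_b", "interaction", "residual"),
                      ss = 0,
                      df = c(nlevels(a) - 1L, nlevels(b) - 1L,
                             (nlevels(a) - 1L) * (nlevels(b) - 1L),
                             length(values) - nlevels(a) * nlevels(b)),
                      f = c(0, 0, 0, NA_real_), p = c(1, 1, 1, NA_real_)))
  }
  fit <- stats::lm(values ~ a * b)
  if (stats::df.residual(fit) < 1) stop("no residual degrees of freedom")
  tab <- car::Anova(fit, type = 2)
  out <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residual"),
    ss = tab[["Sum Sq"]],
    df = tab[["Df"]],
    f = c(tab[["F value"]][1:3], NA_real_),
    p = c(tab[["Pr(>F)"]][1:3], NA_real_),
    row.names = NULL
  )
  out
}

#' Tukey honest significant differences
#'
#' Pairwise comparisons of group means with p-values from the studentized
#' range distribution, as used for post-hoc diet comparisons.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor with at least 2 levels.
#' @return A data.frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, df = %d), two-sided p = %.4g%s\n",
              x$r, x$n, x$df,
              if (is.na(x$p_two_sided)) NA else x$p_two_sided,
              if (isTRUE(x$degenerate)) " [degenerate |r| = 1]" else ""))
  invisible(x)
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: slopes %.4f vs %.4f\n", x$slope_A, x$slope_B))
  cat(sprintf("  slope homogeneity: F(%d,%d) = %.4f, p = %.4g\n",
              x$df_slope[1], x$df_slope[2], x$F_slope, x$p_slope))
  cat(sprintf("  elevation (common slope): F(%d,%d) = %.4f, p = %.4g\n",
              x$df_elev[1], x$df_elev[2], x$F_elev, x$p_elev))
  invisible(x)
}
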