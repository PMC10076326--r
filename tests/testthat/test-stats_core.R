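test_that("pearson_cor matches the from-definition covariance formula", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(50)
    y <- 0.4 * x + rnorm(50)
    res <- pearson_cor(x, y)
    # independent oracle: direct evaluation of cov/(sd sd) from sums
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    r_def <- sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
    expect_equal(res$r, r_def, tolerance = 1e-12)
    expect_lte(abs(res$r), 1 + 1e-12)
  }
  expect_equal(pearson_cor(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1))$r, -1)
})

test_that("pearson_cor rejects degenerate inputs", {
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_cor(1:3, 1:4), "same length")
})

test_that("pearson p-value agrees with the df = 4 closed form", {
  # at n = 6: p = 1 - (3/2)|r| + (1/2)|r|^3
  for (r in seq(0, 0.99, by = 0.01)) {
    expect_equal(pearson_pvalue(r, 6)$p, 1 - 1.5 * r + 0.5 * r^3,
                 tolerance = 1e-10)
    expect_equal(pearson_pvalue(-r, 6)$p, pearson_pvalue(r, 6)$p)
  }
  expect_equal(pearson_pvalue(0, 6)$p, 1)
  deg <- pearson_pvalue(1, 6)
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(pearson_pvalue(0.5, 2), "n must")
})

test_that("ols_line fits exactly and matches the normal equations", {
  x <- 0:5
  fit <- ols_line(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_equal(ols_line(1:10, rep(4, 10))$slope, 0)
  set.seed(21)
  x <- rnorm(20); y <- 1.5 - 0.7 * x + rnorm(20)
  fit <- ols_line(x, y)
  # oracle: solve the 2x2 normal equations directly
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_error(ols_line(rep(2, 5), rnorm(5)), "constant")
})

# explicit RSS of the three nested ANCOVA models, fitted by normal equations
ancova_rss_oracle <- function(xa, ya, xb, yb) {
  x <- c(xa, xb); y <- c(ya, yb)
  g <- rep(c(0, 1), c(length(xa), length(xb)))
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  list(sep = rss(cbind(1, x, g, x * g)),
       par = rss(cbind(1, x, g)),
       one = rss(cbind(1, x)))
}

test_that("ancova_compare matches the nested-RSS oracle", {
  set.seed(30)
  xa <- rep(0:9, 1); ya <- 2 + 0.5 * xa + rnorm(10, 0, 0.1)
  xb <- xa;          yb <- 7 + 0.5 * xb + rnorm(10, 0, 0.1)  # parallel, offset 5
  res <- ancova_compare(xa, ya, xb, yb)
  o <- ancova_rss_oracle(xa, ya, xb, yb)
  n <- 20
  expect_equal(res$F_slope, (o$par - o$sep) / (o$sep / (n - 4)), tolerance = 1e-8)
  expect_equal(res$F_elev, (o$one - o$par) / (o$par / (n - 3)), tolerance = 1e-8)
  expect_gt(res$p_slope, 0.5)   # parallel lines: no slope difference
  expect_lt(res$p_elev, 0.01)   # but clearly separated elevations
})

test_that("ancova_compare is symmetric in group labels and null on copies", {
  set.seed(32)
  x <- runif(12, 0, 8)
  y <- 20 + 0.4 * x + rnorm(12, 0, 0.3)
  res_copy <- ancova_compare(x, y, x, y)
  expect_equal(res_copy$F_elev, 0, tolerance = 1e-10)
  expect_gt(res_copy$p_elev, 0.999)
  x2 <- runif(9, 0, 8); y2 <- 18 + 0.9 * x2 + rnorm(9, 0, 0.3)
  ab <- ancova_compare(x, y, x2, y2)
  ba <- ancova_compare(x2, y2, x, y)
  expect_equal(ab$F_slope, ba$F_slope, tolerance = 1e-12)
  expect_equal(ab$F_elev, ba$F_elev, tolerance = 1e-12)
})

test_that("elevation F equals the squared adjusted-mean-difference t", {
  # shared covariate design: F_elev is the square of the group-coefficient t
  # in the common-slope model
  set.seed(33)
  x <- rep(0:7, 2)
  y <- c(20 + 0.5 * (0:7), 23 + 0.5 * (0:7)) + rnorm(16, 0, 0.4)
  res <- ancova_compare(x[1:8], y[1:8], x[9:16], y[9:16])
  fit <- lm(y ~ x + g, data = data.frame(x = x, y = y,
                                         g = rep(c("A", "B"), each = 8)))
  t_adj <- summary(fit)$coefficients["gB", "t value"]
  expect_equal(res$F_elev, t_adj^2, tolerance = 1e-8)
})

test_that("welch_test matches the textbook formula and handles degeneracy", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- welch_test(x, y)
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_two_sided, 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-10)
  same <- welch_test(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_sided, 1)
  swapped <- welch_test(y, x)
  expect_equal(swapped$t_stat, -res$t_stat)
  expect_equal(swapped$p_two_sided, res$p_two_sided)
  flat_eq <- welch_test(c(2, 2), c(2, 2))
  expect_true(flat_eq$degenerate); expect_equal(flat_eq$p_two_sided, 1)
  flat_ne <- welch_test(c(2, 2), c(3, 3))
  expect_true(flat_ne$degenerate); expect_equal(flat_ne$p_two_sided, 0)
})

test_that("bh_adjust reproduces the step-up by hand and is monotone", {
  expect_equal(bh_adjust(0.04), 0.04)
  # by hand: 0.01*3/1, 0.02*3/2, 0.03*3/3, cumulative min from the largest
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(41)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))                           # never below raw p
  expect_true(all(diff(q[order(p)]) >= -1e-15))      # monotone in p
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_equal(bonferroni(0.03, 2), 0.06)
  expect_equal(bonferroni(c(0.4, 0.9), 3), c(1, 1))
})

test_that("two-way ANOVA decomposes a balanced layout like cell means", {
  a <- rep(c("x", "y"), each = 6)
  b <- rep(rep(c("p", "q", "r"), each = 2), 2)
  set.seed(51)
  v <- rnorm(12, mean = 5) + (a == "y") * 1.5 + (b == "r") * 2
  tab <- two_way_anova(v, a, b)
  # balanced-design oracle from cell/marginal means
  gm <- mean(v)
  ss_a <- sum(tapply(v, a, function(z) length(z) * (mean(z) - gm)^2))
  ss_b <- sum(tapply(v, b, function(z) length(z) * (mean(z) - gm)^2))
  cell <- tapply(v, list(a, b), mean)
  ss_cells <- 2 * sum((cell - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum(v^2) - sum(v)^2 / 12 - ss_cells
  expect_equal(tab$ss, c(ss_a, ss_b, ss_ab, ss_res), tolerance = 1e-10)
  expect_equal(sum(tab$ss), sum((v - gm)^2), tolerance = 1e-10)
  expect_equal(sum(tab$df), 12 - 1)
  flat <- two_way_anova(rep(3, 12), a, b)
  expect_equal(flat$f[1:3], c(0, 0, 0))
  expect_equal(flat$p[1:3], c(1, 1, 1))
  expect_error(two_way_anova(v[1:10], a[1:10], b[1:10]), "empty cells")
})

test_that("tukey_hsd separates distinct groups and not identical ones", {
  set.seed(61)
  g <- rep(c("a", "b", "c"), each = 8)
  v <- rnorm(24, 0, 0.5) + c(a = 0, b = 0, c = 4)[g]
  tk <- tukey_hsd(v, g)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  expect_gt(tk$p_adj[tk$comparison == "b-a"], 0.1)
  expect_lt(tk$p_adj[tk$comparison == "c-a"], 1e-4)
})
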