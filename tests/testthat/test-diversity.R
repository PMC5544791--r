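test_that("inverse Simpson matches its closed forms", {
  expect_equal(unname(inverse_simpson(rep(5, 4))), 4)
  expect_equal(unname(inverse_simpson(c(7, 0, 0))), 1)
  expect_equal(unname(inverse_simpson(c(0.5, 0.5, 0))), 2)
  # scale invariance and maximization at uniformity
  set.seed(5)
  x <- rexp(6)
  expect_equal(inverse_simpson(x), inverse_simpson(10 * x))
  expect_lte(unname(inverse_simpson(x)), 6)
  expect_error(inverse_simpson(c(0, 0)), "zero-sum")
})

test_that("diversity_table tags rows and preserves sample names", {
  m <- rbind(s1 = c(1, 1), s2 = c(2, 6))
  dt <- diversity_table(m, type = "taxonomic")
  expect_equal(dt$sample, c("s1", "s2"))
  expect_equal(dt$type, rep("taxonomic", 2))
  expect_equal(dt$D[1], 2)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(15)
  y <- c(rnorm(6), rnorm(7, 1))
  g <- rep(c("a", "b"), c(6, 7))
  r <- contrast_anova_tukey(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("balanced 3-group ANOVA and Tukey intervals match hand formulas", {
  y <- c(4, 5, 6, 5, 7, 8, 9, 8, 1, 2, 3, 2)
  g <- rep(c("a", "b", "c"), each = 4)
  r <- contrast_anova_tukey(y, g, alpha = 0.05)
  n <- 4; k <- 3; N <- 12
  means <- tapply(y, g, mean)
  ssb <- n * sum((means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  msw <- ssw / (N - k)
  f_hand <- (ssb / (k - 1)) / msw
  expect_equal(r$F, f_hand, tolerance = 1e-12)
  expect_equal(r$r_squared, ssb / (ssb + ssw), tolerance = 1e-12)
  # Tukey: diff +/- qtukey * sqrt(MSW / n); adjusted p from ptukey
  q_crit <- qtukey(0.95, k, N - k)
  hw <- q_crit * sqrt(msw / n)
  row_ba <- r$tukey[r$tukey$comparison == "b-a", ]
  expect_equal(row_ba$diff, unname(means["b"] - means["a"]),
               tolerance = 1e-12)
  expect_equal(row_ba$upr - row_ba$diff, hw, tolerance = 1e-10)
  p_hand <- ptukey(abs(row_ba$diff) / sqrt(msw / n), k, N - k,
                   lower.tail = FALSE)
  expect_equal(row_ba$p_adj, p_hand, tolerance = 1e-10)
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(25)
  y <- rnorm(18) + rep(c(0, 0.5, 1), each = 6)
  g <- rep(c("a", "b", "c"), each = 6)
  r <- contrast_anova_tukey(y, g)
  msw <- sum((y - tapply(y, g, mean)[g])^2) / 15
  for (pr in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    diff <- mean(y[g == pr[1]]) - mean(y[g == pr[2]])
    t_stat <- diff / sqrt(msw * (1 / 6 + 1 / 6))
    p_unadj <- 2 * pt(abs(t_stat), 15, lower.tail = FALSE)
    p_adj <- r$tukey$p_adj[r$tukey$comparison == paste(pr, collapse = "-")]
    expect_gte(p_adj + 1e-12, p_unadj)
  }
})

test_that("degenerate responses are rejected with diagnostics intact", {
  expect_error(contrast_anova_tukey(rep(c(1, 2), each = 3),
                                    rep(c("a", "b"), each = 3)),
               "zero residual variance")
  set.seed(35)
  r <- contrast_anova_tukey(rnorm(12), rep(c("a", "b"), each = 6))
  expect_true(is.finite(r$diagnostics$shapiro_p))
  expect_true(is.finite(r$diagnostics$spread_ratio))
})

test_that("beta dispersion ranks groups by their internal spread", {
  set.seed(45)
  tight <- matrix(rep(c(5, 5, 5, 5), each = 6), 6, 4) +
    matrix(rnorm(24, sd = 0.05), 6, 4)
  loose <- matrix(rep(c(5, 5, 5, 5), each = 6), 6, 4) +
    matrix(rnorm(24, sd = 2), 6, 4)
  m <- abs(rbind(tight, loose))
  rownames(m) <- paste0("s", 1:12)
  g <- rep(c("tight", "loose"), each = 6)
  r <- beta_dispersion_by_group(bray_curtis(m), g)
  expect_gt(r$group_means[["loose"]], r$group_means[["tight"]])
  # duplicated samples give zero dispersion
  dup <- rbind(m[1:3, ], m[1, ], m[1, ], m[1, ])
  rownames(dup) <- paste0("s", 1:6)
  r2 <- beta_dispersion_by_group(bray_curtis(dup),
                                 rep(c("var", "dup"), each = 3))
  expect_equal(unname(r2$group_means[["dup"]]), 0, tolerance = 1e-8)
  expect_error(beta_dispersion_by_group(bray_curtis(m), rep("one", 12)),
               "2 groups")
})
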