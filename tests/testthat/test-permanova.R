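test_that("equal pairwise distances give pseudo-F of exactly 1", {
  d <- matrix(0.6, 4, 4); diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  r <- permanova_blocked(d, c("a", "a", "b", "b"), n_perm = 9, seed = 1)
  expect_equal(r$F, 1)
})

test_that("a maximal observed F attains the minimal exact p under enumeration", {
  # Flipping every block swaps all labels and reproduces the same
  # bipartition, so the observed F is always tied at least once: the
  # smallest attainable p is 2 / (number of relabelings).
  # two blocks of 1 control + 1 restored: 4 relabelings, minimal p = 2/4
  pts <- c(0, 10, 0.5, 10.5)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  groups <- c("control", "restored", "control", "restored")
  blocks <- c("b1", "b1", "b2", "b2")
  r <- permanova_blocked(d, groups, blocks)
  expect_true(r$exact_enumeration)
  expect_equal(r$n_permutations_used, 4)
  expect_equal(r$p_value, 2 / 4)
  # three such blocks: 8 relabelings, maximal separation gives p = 2/8 = 1/4
  pts6 <- c(0, 10, 0.5, 10.5, 1, 11)
  d6 <- as.matrix(dist(pts6))
  rownames(d6) <- colnames(d6) <- paste0("s", 1:6)
  r6 <- permanova_blocked(d6, rep(c("control", "restored"), 3),
                          rep(c("b1", "b2", "b3"), each = 2))
  expect_equal(r6$n_permutations_used, 8)
  expect_equal(r6$p_value, 1 / 4)
})

test_that("exact enumeration matches an independent brute-force oracle", {
  set.seed(21)
  designs <- list(
    list(groups = c("a", "b", "a", "b"), blocks = c(1, 1, 2, 2)),
    list(groups = c("a", "b", "b", "a", "b", "b"), blocks = c(1, 1, 1, 2, 2, 2)),
    list(groups = rep(c("a", "b"), each = 3), blocks = rep(1, 6)),
    list(groups = c("a", "a", "b", "b", "a", "b", "b", "a"),
         blocks = rep(c(1, 2), each = 4)),
    list(groups = rep(c("a", "b"), 4), blocks = rep(1, 8)),
    list(groups = c("a", "a", "b", "a", "b", "b"), blocks = c(1, 1, 1, 2, 2, 2)))
  for (ds in designs) {
    n <- length(ds$groups)
    d <- random_euclidean_d(n, 3)
    rownames(d) <- colnames(d) <- paste0("s", 1:n)
    r <- permanova_blocked(d, ds$groups, ds$blocks)
    expect_true(r$exact_enumeration)
    expect_equal(r$p_value, oracle_exact_p(d, ds$groups, ds$blocks),
                 tolerance = 1e-12)
    expect_equal(r$F, oracle_F(d, ds$groups), tolerance = 1e-10)
  }
})

test_that("sampled p-values converge to the exact enumeration p", {
  set.seed(31)
  d <- random_euclidean_d(8, 2)
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  groups <- c("a", "a", "b", "b", "a", "a", "b", "b")
  blocks <- rep(c(1, 2), each = 4)
  exact <- permanova_blocked(d, groups, blocks)$p_value
  sampled <- permanova_blocked(d, groups, blocks, n_perm = 9999, seed = 8,
                               max_exact = 0)$p_value
  expect_lt(abs(sampled - exact), 0.02)
})

test_that("PERMANOVA on Euclidean distances reproduces one-way ANOVA F", {
  set.seed(41)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- sample((2 * k):12, 1)
    g <- sample(rep(letters[1:k], length.out = n))
    y <- rnorm(n)
    d <- as.matrix(dist(y))
    rownames(d) <- colnames(d) <- paste0("s", 1:n)
    f_aov <- anova(aov(y ~ factor(g)))[["F value"]][1]
    f_perm <- permanova_blocked(d, g, n_perm = 1, seed = 1, max_exact = 0)$F
    expect_equal(f_perm, f_aov, tolerance = 1e-10)
  }
})

test_that("pseudo-F agrees with vegan's adonis2 on random data", {
  set.seed(51)
  m <- matrix(rpois(120, 5) + 1, 12, 10)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(m)
  r <- permanova_blocked(d, g, n_perm = 99, seed = 2, max_exact = 0)
  va <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(r$F, va$F[1], tolerance = 1e-8)
  expect_equal(r$r_squared, va$R2[1], tolerance = 1e-8)
})

test_that("inflating between-group distances cannot decrease pseudo-F", {
  set.seed(61)
  g <- rep(c("a", "b"), each = 4)
  d <- random_euclidean_d(8, 3)
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  between <- outer(g, g, "!=")
  d_up <- d + 0.5 * between
  f0 <- permanova_blocked(d, g, n_perm = 1, seed = 1, max_exact = 0)$F
  f1 <- permanova_blocked(d_up, g, n_perm = 1, seed = 1, max_exact = 0)$F
  expect_gte(f1, f0)
})

test_that("degenerate and unshuffleable inputs are reported", {
  d0 <- matrix(0, 4, 4)
  rownames(d0) <- colnames(d0) <- paste0("s", 1:4)
  expect_error(permanova_blocked(d0, c("a", "a", "b", "b"), n_perm = 9,
                                 seed = 1), "identical")
  d <- random_euclidean_d(6, 2)
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  expect_warning(
    permanova_blocked(d, c("a", "a", "a", "b", "b", "a"),
                      blocks = c(1, 1, 1, 2, 2, 2), n_perm = 9, seed = 1),
    "unshuffleable")
  expect_error(permanova_blocked(d, rep("a", 6), n_perm = 9, seed = 1),
               "2 groups")
})
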