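test_that("filter_taxa keeps requested taxa and warns on unknowns", {
  tb <- tiny_traits()
  out <- filter_taxa(tb, c("a", "c"))
  expect_setequal(unique(out$taxon), c("a", "c"))
  expect_identical(filter_taxa(tb, c("a", "b", "c")), tb)
  expect_warning(out2 <- filter_taxa(tb, c("a", "nosuch")), "nosuch")
  expect_setequal(unique(out2$taxon), "a")
  expect_error(filter_taxa(tb, character(0)), "non-empty")
})

test_that("standardization divides by block sums and flags zero blocks", {
  s <- tiny_schema()
  std <- standardize_affinities(tiny_traits(), s)
  # taxon a, Size block had (3, 1, 0)
  expect_equal(unname(std$profile["a", c("Size.1", "Size.2", "Size.3")]),
               c(0.75, 0.25, 0))
  # taxon b has no Velocity affinity: all zero and flagged
  expect_equal(unname(std$profile["b", paste0("Velocity.", 1:4)]),
               rep(0, 4))
  expect_true(std$zero_features["b", "Velocity"])
  expect_false(std$zero_features["a", "Velocity"])
  # single positive trait in a feature standardizes to 1
  expect_equal(unname(std$profile["c", "Velocity.4"]), 1)
})

test_that("rank aggregation averages member profiles then re-standardizes", {
  s <- trait_schema(list(F1 = c("x", "y")))
  m <- rbind(t1 = c(x = 1, y = 0), t2 = c(x = 0, y = 1))
  std <- standardize_affinities(m, s)
  agg <- aggregate_to_rank(std, c(t1 = "fam", t2 = "fam"))
  expect_equal(unname(agg$profile["fam", ]), c(0.5, 0.5))
  # a member with an all-zero block is absorbed by re-standardization
  m2 <- rbind(t1 = c(x = 0, y = 0), t2 = c(x = 1, y = 0))
  agg2 <- aggregate_to_rank(standardize_affinities(m2, s),
                            c(t1 = "fam", t2 = "fam"))
  expect_equal(unname(agg2$profile["fam", ]), c(1, 0))
  # single-member aggregation is the identity
  agg3 <- aggregate_to_rank(std, c(t1 = "f1", t2 = "f2"))
  expect_equal(unname(agg3$profile["f1", ]), unname(std$profile["t1", ]))
  expect_error(aggregate_to_rank(std, c(missing_taxon = "fam")),
               "no member taxa")
})

test_that("trait-abundance array weights profiles by ln(x + 1)", {
  s <- trait_schema(list(F1 = c("x", "y")))
  std <- standardize_affinities(rbind(t1 = c(x = 1, y = 1)), s)
  ab <- matrix(c(0, exp(1) - 1), 2, 1,
               dimnames = list(c("s1", "s2"), "t1"))
  arr <- build_trait_abundance_array(std, ab)
  expect_equal(unname(arr["s1", "t1", ]), c(0, 0))    # ln(0 + 1) = 0
  expect_equal(unname(arr["s2", "t1", "x"]), 0.5)     # 0.5 * ln(e) = 0.5
  expect_error(build_trait_abundance_array(std, -ab), "negative")
})

test_that("taxa without trait data are dropped with a warning", {
  s <- tiny_schema()
  std <- standardize_affinities(tiny_traits(), s)
  ab <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"),
                                          c("a", "b", "zz")))
  expect_warning(arr <- build_trait_abundance_array(std, ab), "zz")
  expect_equal(dimnames(arr)[[2]], c("a", "b"))
})

test_that("community profiles renormalize per feature and flag empty features", {
  s <- trait_schema(list(F1 = c("x", "y")))
  std <- standardize_affinities(rbind(t1 = c(x = 1, y = 0),
                                      t2 = c(x = 0, y = 1)), s)
  w <- exp(2) - 1  # equal weights for both taxa
  ab <- matrix(w, 1, 2, dimnames = list("s1", c("t1", "t2")))
  prof <- community_trait_profile(build_trait_abundance_array(std, ab), s)
  expect_equal(unname(prof["s1", ]), c(0.5, 0.5))
  # a single present taxon reproduces its own standardized profile
  ab1 <- matrix(c(5, 0), 1, 2, dimnames = list("s1", c("t1", "t2")))
  prof1 <- community_trait_profile(build_trait_abundance_array(std, ab1), s)
  expect_equal(unname(prof1["s1", ]), unname(std$profile["t1", ]))
  # empty sample errors, naming it
  ab0 <- matrix(c(0, 0, 3, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("empty", "ok"), c("t1", "t2")))
  expect_error(community_trait_profile(
    build_trait_abundance_array(std, ab0), s), "empty")
})

test_that("non-flagged feature blocks conserve unit mass through the chain", {
  set.seed(101)
  for (rep in 1:5) {
    schema <- trait_schema(list(A = paste0("A.", 1:3), B = paste0("B.", 1:2),
                                C = paste0("C.", 1:4)))
    n_taxa <- 6; n_samp <- 5
    raw <- matrix(sample(0:5, n_taxa * 9, replace = TRUE), n_taxa, 9,
                  dimnames = list(paste0("t", 1:n_taxa), schema$codes))
    raw[2, schema$features$B] <- 0  # deliberate all-zero block
    ab <- matrix(rpois(n_samp * n_taxa, 4) + 1, n_samp, n_taxa,
                 dimnames = list(paste0("s", 1:n_samp),
                                 paste0("t", 1:n_taxa)))
    std <- standardize_affinities(raw, schema)
    for (f in names(schema$features)) {
      sums <- rowSums(std$profile[, schema$features[[f]], drop = FALSE])
      expect_true(all(abs(sums[!std$zero_features[, f]] - 1) < 1e-12))
      expect_true(all(sums[std$zero_features[, f]] == 0))
    }
    prof <- community_trait_profile(build_trait_abundance_array(std, ab),
                                    schema)
    zf <- attr(prof, "zero_features")
    for (f in names(schema$features)) {
      sums <- rowSums(prof[, schema$features[[f]], drop = FALSE])
      expect_true(all(abs(sums[!zf[, f]] - 1) < 1e-12))
    }
  }
})

test_that("standardized profiles are invariant to within-feature scaling", {
  s <- tiny_schema()
  raw <- rivertraits:::fuzzy_to_matrix(tiny_traits(), s)
  scaled <- raw
  scaled["a", s$features$Size] <- scaled["a", s$features$Size] * 7.5
  expect_equal(standardize_affinities(scaled, s)$profile,
               standardize_affinities(raw, s)$profile)
})

test_that("row permutations of taxa or samples permute outputs identically", {
  set.seed(7)
  s <- tiny_schema()
  std <- standardize_affinities(tiny_traits(), s)
  ab <- matrix(rpois(12, 5) + 1, 4, 3,
               dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  prof <- community_trait_profile(build_trait_abundance_array(std, ab), s)
  perm_s <- c(3, 1, 4, 2)
  prof_p <- community_trait_profile(
    build_trait_abundance_array(std, ab[perm_s, ]), s)
  expect_equal(prof_p, prof[perm_s, ], ignore_attr = TRUE)
  perm_t <- c("c", "a", "b")
  prof_t <- community_trait_profile(
    build_trait_abundance_array(std, ab[, perm_t]), s)
  expect_equal(unclass(prof_t), unclass(prof), ignore_attr = TRUE)
})

test_that("the abundance-weighting steps equal a brute-force weighted mean", {
  set.seed(55)
  s <- trait_schema(list(A = paste0("A.", 1:3), B = paste0("B.", 1:2)))
  for (rep in 1:10) {
    n_taxa <- sample(2:6, 1)
    raw <- matrix(sample(0:5, n_taxa * 5, replace = TRUE), n_taxa, 5,
                  dimnames = list(paste0("t", 1:n_taxa), s$codes))
    counts <- rpois(n_taxa, 6) + 1
    ab <- matrix(counts, 1, n_taxa,
                 dimnames = list("s1", paste0("t", 1:n_taxa)))
    std <- standardize_affinities(raw, s)
    prof <- community_trait_profile(build_trait_abundance_array(std, ab), s)
    for (f in names(s$features)) {
      cols <- s$features[[f]]
      expected <- oracle_feature_profile(counts,
                                         std$profile[, cols, drop = FALSE])
      expect_equal(unname(prof["s1", cols]), unname(expected),
                   tolerance = 1e-12)
    }
  }
})
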