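test_that("design enumeration matches the sampling layout", {
  d <- generate_design(3, organic = c("A", "B", "C"), mineral = c("G", "S"),
                       replicates = 3)
  expect_equal(nrow(d), 72)
  expect_equal(sum(d$reach_type == "control"), 27)
  expect_equal(sum(d$reach_type == "restored"), 45)
  # control reaches carry only organic biotopes
  expect_true(all(d$biotope[d$reach_type == "control"] %in% c("A", "B", "C")))
  expect_setequal(unique(d$biotope[d$reach_type == "restored"]),
                  c("A", "B", "C", "G", "S"))
  # every sample sits in exactly one design cell
  expect_false(anyDuplicated(d$sample_id) > 0)
})

test_that("minimal design and invalid designs behave per contract", {
  d <- generate_design(1, organic = "A", mineral = character(0),
                       replicates = 1)
  expect_equal(nrow(d), 2)
  expect_equal(unique(d$biotope), "A")
  expect_error(generate_design(1, organic = "A", mineral = "A"),
               "overlap")
  expect_error(generate_design(1, organic = character(0), mineral = "G"),
               "organic")
})

test_that("generation is deterministic given the seed", {
  ds1 <- synthetic_dataset(seed = 42)
  ds2 <- synthetic_dataset(seed = 42)
  expect_identical(ds1$abundances, ds2$abundances)
  expect_identical(ds1$traits, ds2$traits)
  expect_identical(ds1$metadata, ds2$metadata)
  ds3 <- synthetic_dataset(seed = 43)
  expect_false(identical(ds1$abundances, ds3$abundances))
})

test_that("counts are nonnegative integers and truth records the effects", {
  ds <- synthetic_dataset(config = generator_config(delta = 0.5, phi = 2),
                          seed = 7)
  expect_true(all(ds$abundances >= 0))
  expect_true(all(ds$abundances == round(ds$abundances)))
  expect_equal(ds$truth$delta, 0.5)
  expect_equal(ds$truth$phi, 2)
  expect_equal(dim(ds$truth$biotope_affinity),
               c(40, length(unique(ds$metadata$biotope))))
  expect_setequal(colnames(ds$abundances), unique(ds$traits$taxon))
})

test_that("trait database respects the affinity scale and syndromes add correlation", {
  s <- default_trait_schema()
  tb <- generate_trait_database(10, s, n_syndromes = 2, seed = 11)
  expect_true(all(tb$affinity >= 0 & tb$affinity <= 5))
  expect_identical(tb, generate_trait_database(10, s, n_syndromes = 2,
                                               seed = 11))
  # every taxon has at least one positive affinity
  expect_setequal(unique(tb$taxon), sprintf("Fam%02d", 1:10))

  mean_cor <- function(n_syn) {
    tb <- generate_trait_database(12, s, n_syndromes = n_syn, seed = 99)
    m <- rivertraits:::fuzzy_to_matrix(tb, s)
    cm <- suppressWarnings(cor(t(m)))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }
  expect_gt(mean_cor(1), mean_cor(12))
})

test_that("single-trait grouping features force identical standardized profiles", {
  s1 <- trait_schema(list(Only = "Only.1"))
  tb <- fuzzy_trait_table(taxon = c("a", "b", "c"), trait_code = "Only.1",
                          affinity = c(5, 2, 1), schema = s1)
  std <- standardize_affinities(tb, s1)
  expect_true(all(std$profile == 1))
})

test_that("config validation enforces the stated invariants", {
  expect_error(generator_config(phi = 0.5), "phi")
  expect_error(generator_config(negbin_size = 0), "negbin_size")
  expect_error(generator_config(delta = Inf), "finite")
  expect_error(generator_config(affinity_scale_max = 4), "3 or 5")
})

test_that("datasets round-trip through the CSV writer and readers", {
  ds <- synthetic_dataset(design = generate_design(1, replicates = 3),
                          config = generator_config(n_taxa = 8), seed = 3)
  dir <- tempfile()
  paths <- write_synthetic_dataset(ds, dir)
  ab <- read_abundance_table(file.path(dir, "abundance.csv"))
  expect_equal(unname(ab), unname(ds$abundances))
  expect_equal(rownames(ab), rownames(ds$abundances))
  md <- read_metadata_table(file.path(dir, "metadata.csv"))
  expect_equal(md$sample_id, ds$metadata$sample_id)
  tr <- read_trait_table(file.path(dir, "traits.csv"),
                         schema = default_trait_schema())
  expect_equal(nrow(tr), nrow(ds$traits))
})
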