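# Synthetic study-like datasets: a paired control/restored reach design over
# organic and mineralogical biotopes, negative-binomial community counts
# with known location (delta) and dispersion (phi) effects, and a
# fuzzy-coded trait database built from syndrome templates. Every effect
# actually used is recorded in `truth` so downstream recovery tests have a
# ground truth.

#' Generate a paired control/restored sampling design
#'
#' Each site pair holds one control and one restored reach. Control reaches
#' carry only the organic biotopes (macrophyte/macroalgal habitats occur in
#' both reach types); restored reaches additionally carry the mineralogical
#' biotopes (bare substrate patches characteristic of restoration works).
#' Every (reach, biotope) cell receives `replicates` replicate samples.
#'
#' @param n_site_pairs number of paired control/restored sites (>= 1).
#' @param organic character vector of organic biotope labels (non-empty).
#' @param mineral character vector of mineralogical biotope labels (may be
#'   empty; must be disjoint from `organic`).
#' @param replicates replicate samples per biotope patch (default 3).
#' @return data frame of class `study_design`: one row per sample with
#'   columns `sample_id`, `site_pair`, `reach_type`, `biotope`,
#'   `biotope_class`, `replicate`; attributes `organic`, `mineral`,
#'   `replicates`.
#' @examples
#' d <- generate_design(3, organic = c("A", "B", "C"),
#'                      mineral = c("G", "S"), replicates = 3)
#' nrow(d)                       # 72 samples
#' table(d$reach_type)           # 27 control / 45 restored
#' @export
generate_design <- function(n_site_pairs = 3,
                            organic = c("macroalgae", "ranunculus",
                                        "sparganium"),
                            mineral = c("gravel", "sand", "gravel_sand"),
                            replicates = 3) {
  stopifnot(n_site_pairs >= 1, replicates >= 1)
  organic <- as.character(organic)
  mineral <- as.character(mineral)
  if (length(organic) == 0L)
    stop("invalid design: need at least one organic biotope", call. = FALSE)
  if (length(intersect(organic, mineral)))
    stop("invalid design: organic and mineral biotope labels overlap: ",
         paste(intersect(organic, mineral), collapse = ", "), call. = FALSE)
  rows <- list()
  for (p in seq_len(n_site_pairs)) {
    pair <- sprintf("pair%d", p)
    for (rt in c("control", "restored")) {
      bios <- if (rt == "control") organic else c(organic, mineral)
      for (b in bios) for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%s_r%d", pair, rt, b, r),
          site_pair = pair, reach_type = rt, biotope = b,
          biotope_class = if (b %in% organic) "organic" else "mineralogical",
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, organic = organic, mineral = mineral,
            replicates = replicates,
            class = c("study_design", "data.frame"))
}

#' Generator configuration for synthetic community counts
#'
#' Counts for taxon t in sample s are drawn negative-binomial with log-mean
#' `base_t + affinity_{t, biotope(s)} + delta * [restored] + eps_s`, where
#' `eps_s ~ N(0, sd_sample * (phi if restored else 1))` is a sample-level
#' random effect. `delta` shifts the multivariate location of restored
#' reaches; `phi >= 1` inflates among-sample heterogeneity there (the
#' quantity the dispersion analysis measures). Per-taxon baselines and
#' taxon x biotope affinity effects can be supplied explicitly or are drawn
#' from the hyperparameters at generation time and recorded in `truth`.
#'
#' @param n_taxa number of taxa (families) (default 40).
#' @param delta additive log-abundance location shift in restored reaches
#'   (default 0: no shift).
#' @param phi dispersion multiplier >= 1 for restored reaches (default 1:
#'   no effect).
#' @param negbin_size negative-binomial size (inverse overdispersion) > 0.
#' @param sd_sample standard deviation of the sample-level random effect on
#'   the log scale (default 0.4, about +/-50% abundance variation between
#'   replicate samples).
#' @param base_mean,base_sd normal hyperparameters for per-taxon baseline
#'   log-abundances (defaults log(8) and 1, a right-skewed family-abundance
#'   distribution).
#' @param affinity_sd standard deviation of taxon x biotope affinity
#'   effects on the log scale (default 0.8: biotopes hold distinct
#'   communities).
#' @param base_log_abundance,biotope_affinity optional explicit per-taxon
#'   baseline vector and taxon x biotope effect matrix overriding the
#'   hyperparameters.
#' @param affinity_scale_max maximum fuzzy affinity score for the generated
#'   trait database, 3 or 5 (default 5).
#' @param n_syndromes number of trait syndromes (shared affinity templates)
#'   among taxa (default 5).
#' @param seed RNG seed (required at generation).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_taxa = 40, delta = 0, phi = 1,
                             negbin_size = 5, sd_sample = 0.4,
                             base_mean = log(8), base_sd = 1,
                             affinity_sd = 0.8,
                             base_log_abundance = NULL,
                             biotope_affinity = NULL,
                             affinity_scale_max = 5, n_syndromes = 5,
                             seed = NULL) {
  stopifnot(n_taxa >= 1, phi >= 1, negbin_size > 0, sd_sample >= 0,
            affinity_sd >= 0, n_syndromes >= 1)
  if (!affinity_scale_max %in% c(3, 5))
    stop("affinity_scale_max must be 3 or 5", call. = FALSE)
  vals <- c(delta, phi, negbin_size, sd_sample, base_mean, base_sd,
            affinity_sd)
  if (any(!is.finite(vals)))
    stop("all effect parameters must be finite", call. = FALSE)
  structure(list(n_taxa = n_taxa, delta = delta, phi = phi,
                 negbin_size = negbin_size, sd_sample = sd_sample,
                 base_mean = base_mean, base_sd = base_sd,
                 affinity_sd = affinity_sd,
                 base_log_abundance = base_log_abundance,
                 biotope_affinity = biotope_affinity,
                 affinity_scale_max = affinity_scale_max,
                 n_syndromes = n_syndromes, seed = seed),
            class = "generator_config")
}

#' Generate synthetic community abundances for a design
#'
#' @param design a [generate_design()] result.
#' @param config a [generator_config()]; its `seed` must be set (or passed
#'   via `seed`).
#' @param seed overrides `config$seed`.
#' @return list of class `synthetic_dataset` with `abundances` (sample x
#'   taxon integer matrix), `metadata` (the design rows), `traits` (NULL
#'   until [generate_trait_database()] is attached; see
#'   [synthetic_dataset()]), and `truth` (the realized parameters).
#' @export
generate_abundances <- function(design, config = generator_config(),
                                seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  biotopes <- unique(design$biotope)
  taxa <- sprintf("Fam%02d", seq_len(config$n_taxa))
  with_seed(seed, {
    base <- config$base_log_abundance %||%
      stats::rnorm(config$n_taxa, config$base_mean, config$base_sd)
    aff <- config$biotope_affinity %||%
      matrix(stats::rnorm(config$n_taxa * length(biotopes), 0,
                          config$affinity_sd),
             nrow = config$n_taxa,
             dimnames = list(taxa, biotopes))
    if (is.null(rownames(aff))) dimnames(aff) <- list(taxa, biotopes)
    restored <- design$reach_type == "restored"
    eps <- stats::rnorm(nrow(design), 0,
                        config$sd_sample * ifelse(restored, config$phi, 1))
    counts <- matrix(0L, nrow(design), config$n_taxa,
                     dimnames = list(design$sample_id, taxa))
    for (s in seq_len(nrow(design))) {
      eta <- base + aff[, design$biotope[s]] +
        (if (restored[s]) config$delta else 0) + eps[s]
      counts[s, ] <- stats::rnbinom(config$n_taxa, mu = exp(eta),
                                    size = config$negbin_size)
    }
    truth <- config
    truth$seed <- seed
    truth$base_log_abundance <- base
    truth$biotope_affinity <- aff
    truth$sample_effects <- stats::setNames(eps, design$sample_id)
    structure(list(abundances = counts, metadata = as.data.frame(design),
                   traits = NULL, truth = truth),
              class = "synthetic_dataset")
  })
}

#' Generate a fuzzy-coded trait database
#'
#' Taxa are assigned to `n_syndromes` trait syndromes; each syndrome defines
#' an integer affinity template per grouping feature (one or two preferred
#' modalities scoring near the scale maximum) and member taxa perturb the
#' template by small integer noise, clipped to `[0, affinity_scale_max]`.
#' Every taxon is guaranteed at least one positive affinity.
#'
#' @param n_taxa number of taxa.
#' @param schema a [trait_schema()] (default [default_trait_schema()]).
#' @param n_syndromes number of shared templates (>= 1).
#' @param affinity_scale_max maximum score, 3 or 5.
#' @param seed RNG seed (required).
#' @param taxa optional taxon names (default `Fam01..`).
#' @return a [fuzzy_trait_table()] holding only the positive affinities.
#' @export
generate_trait_database <- function(n_taxa, schema = default_trait_schema(),
                                    n_syndromes = 5, affinity_scale_max = 5,
                                    seed = NULL, taxa = NULL) {
  stopifnot(n_syndromes >= 1, length(schema$features) >= 1)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  taxa <- taxa %||% sprintf("Fam%02d", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa)
  with_seed(seed, {
    templates <- lapply(seq_len(n_syndromes), function(s) {
      tpl <- stats::setNames(integer(length(schema$codes)), schema$codes)
      for (f in names(schema$features)) {
        cods <- schema$features[[f]]
        k <- min(length(cods), sample(1:2, 1))
        pref <- sample(cods, k)
        tpl[pref] <- affinity_scale_max - sample(0:1, k, replace = TRUE)
      }
      tpl
    })
    syndrome <- rep_len(seq_len(n_syndromes), n_taxa)
    rows <- vector("list", n_taxa)
    for (i in seq_len(n_taxa)) {
      aff <- templates[[syndrome[i]]] +
        sample(-1:1, length(schema$codes), replace = TRUE)
      aff <- pmin(pmax(aff, 0L), affinity_scale_max)
      if (all(aff == 0)) aff[schema$features[[1]][1]] <- affinity_scale_max
      pos <- aff > 0
      rows[[i]] <- data.frame(taxon = taxa[i], rank = "family",
                              trait_code = schema$codes[pos],
                              affinity = as.integer(aff[pos]),
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    fuzzy_trait_table(df$taxon, df$trait_code, df$affinity, rank = df$rank,
                      schema = schema)
  })
}

#' Generate a complete synthetic dataset
#'
#' Bundles [generate_design()], [generate_abundances()] and
#' [generate_trait_database()] under a single seed (child seeds are derived
#' deterministically for the count and trait sub-generators).
#'
#' @param design a [generate_design()] result (default: the packaged
#'   3-pair, 3-organic + 3-mineral, 3-replicate layout).
#' @param config a [generator_config()].
#' @param schema trait schema for the trait database.
#' @param seed master RNG seed (required).
#' @return a `synthetic_dataset` list: `abundances`, `metadata`, `traits`,
#'   `truth`.
#' @export
synthetic_dataset <- function(design = generate_design(),
                              config = generator_config(),
                              schema = default_trait_schema(),
                              seed = NULL) {
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  ds <- generate_abundances(design, config, seed = child_seed(seed, 1))
  ds$traits <- generate_trait_database(
    config$n_taxa, schema = schema, n_syndromes = config$n_syndromes,
    affinity_scale_max = config$affinity_scale_max,
    seed = child_seed(seed, 2), taxa = colnames(ds$abundances))
  ds$truth$seed <- seed
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic macroinvertebrate dataset\n")
  cat("  samples:", nrow(x$abundances), " taxa:", ncol(x$abundances), "\n")
  cat("  control/restored:",
      paste(table(x$metadata$reach_type), collapse = "/"), "\n")
  cat("  delta =", x$truth$delta, " phi =", x$truth$phi,
      " negbin size =", x$truth$negbin_size, "\n")
  if (!is.null(x$traits))
    cat("  trait rows:", nrow(x$traits), "\n")
  invisible(x)
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Writes `abundance.csv` (samples x taxa), `traits.csv` (long format with
#' grouping features), `metadata.csv`, and `truth.json`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @param schema trait schema used to annotate the trait table.
#' @return invisibly, the vector of file paths written.
#' @export
write_synthetic_dataset <- function(ds, dir,
                                    schema = default_trait_schema()) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- data.frame(sample_id = rownames(ds$abundances), ds$abundances,
                   check.names = FALSE, stringsAsFactors = FALSE)
  paths <- file.path(dir, c("abundance.csv", "traits.csv", "metadata.csv",
                            "truth.json"))
  utils::write.csv(ab, paths[1], row.names = FALSE)
  tr <- ds$traits
  tr$grouping_feature <- unname(schema$feature_of[tr$trait_code])
  utils::write.csv(tr[, c("taxon", "rank", "grouping_feature", "trait_code",
                          "affinity")], paths[2], row.names = FALSE)
  utils::write.csv(ds$metadata, paths[3], row.names = FALSE)
  truth <- ds$truth
  truth$biotope_affinity <- as.data.frame(truth$biotope_affinity)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}
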