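# The pipeline driver: runs the full appraisal sequence on a synthetic or
# file-based dataset and returns all stage outputs in one bundle.

#' Analysis configuration
#'
#' Either point the four `*_path` arguments at CSV inputs or leave them NULL
#' to run on a synthetic dataset generated from `design`/`generator`.
#'
#' @param abundance_path,trait_path,metadata_path,schema_path input CSVs
#'   (see [read_abundance_table()], [read_trait_table()],
#'   [read_metadata_table()], [load_trait_schema()]); `schema_path` defaults
#'   to the packaged schema.
#' @param design,generator synthetic-mode inputs: a [generate_design()] and
#'   a [generator_config()].
#' @param n_perm permutations for every permutation procedure (default 999).
#' @param seed master RNG seed (required; stage seeds derive from it).
#' @param alpha significance level for contrasts (default 0.05).
#' @param min_patches dominant-biotope threshold (default 3).
#' @param taxonomic,trait toggles for the two composition branches.
#' @param organic_subset rerun the reach contrast on organic-biotope samples
#'   only (default TRUE).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(abundance_path = NULL, trait_path = NULL,
                            metadata_path = NULL, schema_path = NULL,
                            design = generate_design(),
                            generator = generator_config(),
                            n_perm = 999, seed = NULL, alpha = 0.05,
                            min_patches = 3, taxonomic = TRUE, trait = TRUE,
                            organic_subset = TRUE) {
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1",
                                          call. = FALSE)
  file_mode <- !is.null(abundance_path)
  if (file_mode) {
    paths <- c(abundance_path, trait_path, metadata_path)
    if (any(vapply(paths, is.null, logical(1))))
      stop("file mode needs abundance, trait and metadata paths",
           call. = FALSE)
    missing <- paths[!file.exists(unlist(paths))]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  structure(list(abundance_path = abundance_path, trait_path = trait_path,
                 metadata_path = metadata_path, schema_path = schema_path,
                 design = design, generator = generator, n_perm = n_perm,
                 seed = seed, alpha = alpha, min_patches = min_patches,
                 taxonomic = taxonomic, trait = trait,
                 organic_subset = organic_subset, file_mode = file_mode),
            class = "analysis_config")
}

#' Run the full appraisal pipeline
#'
#' Executes, in order: the dominant-biotope filter; the ln(x+1) transform;
#' the trait-processing chain to community-weighted trait profiles;
#' Bray-Curtis + PCoA for the taxonomic and trait compositions; the
#' control/restored reach contrast by blocked PERMANOVA and multivariate
#' dispersion (full data and, optionally, organic-biotope samples only);
#' SIMPER for the reach contrast; biotope PERMANOVA; alpha diversity
#' (inverse Simpson) and beta diversity (dispersion per biotope) with
#' ANOVA + Tukey HSD contrasts; group-equalized IndVal over biotopes; and
#' the rarity/exclusivity audit. Identical config and seed give an
#' identical bundle.
#'
#' @param config an [analysis_config()].
#' @return list of class `report_bundle`, keyed by analysis name, with a
#'   `provenance` block (config, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  schema <- stage("schema", {
    if (is.null(config$schema_path)) default_trait_schema()
    else load_trait_schema(config$schema_path)
  })

  # --- inputs -------------------------------------------------------------
  if (config$file_mode) {
    abundances <- stage("read_abundance",
                        read_abundance_table(config$abundance_path))
    metadata <- stage("read_metadata",
                      read_metadata_table(config$metadata_path))
    traits <- stage("read_traits",
                    read_trait_table(config$trait_path, schema = schema))
  } else {
    ds <- stage("synthetic_data",
                synthetic_dataset(config$design, config$generator,
                                  schema = schema,
                                  seed = child_seed(seed, 0)))
    abundances <- ds$abundances
    metadata <- ds$metadata
    traits <- ds$traits
  }
  if (!"biotope_class" %in% names(metadata)) {
    vocab <- dominant_biotopes()
    metadata$biotope_class <- vocab$category[match(metadata$biotope,
                                                   vocab$biotope)]
  }

  # --- dominant-biotope filter -------------------------------------------
  metadata <- stage("dominant_biotope_filter",
                    filter_dominant_biotopes(metadata, config$min_patches))
  metadata <- align_metadata(metadata, abundances[metadata$sample_id, ,
                                                  drop = FALSE])
  abundances <- abundances[metadata$sample_id, , drop = FALSE]

  # --- compositions -------------------------------------------------------
  log_ab <- stage("log_transform", log_transform(abundances))
  keep_taxa <- colSums(abundances) > 0
  log_ab_pos <- log_ab[, keep_taxa, drop = FALSE]
  profiles <- NULL
  if (config$trait)
    profiles <- stage("trait_profiles",
                      trait_profiles(abundances[, keep_taxa, drop = FALSE],
                                     traits, schema))

  reach <- metadata$reach_type
  pair <- metadata$site_pair
  biotope <- metadata$biotope
  bundle <- list()

  branches <- list()
  if (config$taxonomic) branches$taxonomic <- log_ab_pos
  if (config$trait) branches$trait <- profiles

  for (nm in names(branches)) {
    dat <- branches[[nm]]
    d <- stage(paste0(nm, "_distance"), bray_curtis(dat))
    bundle[[paste0(nm, "_pcoa")]] <- stage(paste0(nm, "_pcoa"), pcoa(d))
    bundle[[paste0(nm, "_reach_permanova")]] <- stage(
      paste0(nm, "_reach_permanova"),
      permanova_blocked(d, reach, blocks = pair, n_perm = config$n_perm,
                        seed = child_seed(seed, 11)))
    bundle[[paste0(nm, "_reach_permdisp")]] <- stage(
      paste0(nm, "_reach_permdisp"), permdisp(d, reach))
    if (config$organic_subset) {
      org <- metadata$biotope_class == "organic"
      d_org <- stage(paste0(nm, "_organic_distance"),
                     bray_curtis(dat[org, , drop = FALSE]))
      bundle[[paste0(nm, "_organic_permanova")]] <- stage(
        paste0(nm, "_organic_permanova"),
        permanova_blocked(d_org, reach[org], blocks = pair[org],
                          n_perm = config$n_perm,
                          seed = child_seed(seed, 11)))
      bundle[[paste0(nm, "_organic_permdisp")]] <- stage(
        paste0(nm, "_organic_permdisp"), permdisp(d_org, reach[org]))
    }
    bundle[[paste0(nm, "_reach_simper")]] <- stage(
      paste0(nm, "_reach_simper"),
      simper(dat, reach, n_perm = config$n_perm,
             seed = child_seed(seed, 13)))
    bundle[[paste0(nm, "_biotope_permanova")]] <- stage(
      paste0(nm, "_biotope_permanova"),
      permanova_blocked(d, biotope, blocks = pair, n_perm = config$n_perm,
                        seed = child_seed(seed, 14)))
    # alpha diversity: taxonomic on ln(x+1) data; trait on the profile
    # renormalized to unit sum across all traits
    alpha_dat <- if (nm == "trait") dat / rowSums(dat) else dat
    alpha <- stage(paste0(nm, "_alpha"),
                   diversity_table(alpha_dat,
                                   type = if (nm == "trait") "trait"
                                   else "taxonomic"))
    bundle[[paste0(nm, "_alpha_diversity")]] <- alpha
    bundle[[paste0(nm, "_alpha_contrast")]] <- stage(
      paste0(nm, "_alpha_contrast"),
      contrast_anova_tukey(alpha$D, biotope, alpha = config$alpha))
    beta <- stage(paste0(nm, "_beta"), beta_dispersion_by_group(d, biotope))
    bundle[[paste0(nm, "_beta_diversity")]] <- beta
    bundle[[paste0(nm, "_beta_contrast")]] <- stage(
      paste0(nm, "_beta_contrast"),
      contrast_anova_tukey(beta$distances, biotope, alpha = config$alpha))
    bundle[[paste0(nm, "_indval")]] <- stage(
      paste0(nm, "_indval"),
      indval_combinations(dat, biotope, n_perm = config$n_perm,
                          seed = child_seed(seed, 15)))
  }

  bundle$rarity <- stage("rarity", classify_rare(abundances, metadata))
  bundle$metadata <- metadata
  bundle$provenance <- list(
    seed = seed, n_perm = config$n_perm, alpha = config$alpha,
    min_patches = config$min_patches, file_mode = config$file_mode,
    n_samples = nrow(abundances), n_taxa = ncol(abundances),
    package_version = as.character(utils::packageVersion("rivertraits")),
    config = unclass(config))
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle (", x$provenance$n_samples, " samples, ",
      x$provenance$n_taxa, " taxa, seed ", x$provenance$seed, ")\n",
      sep = "")
  for (nm in setdiff(names(x), c("metadata", "provenance"))) {
    obj <- x[[nm]]
    line <- if (inherits(obj, "permanova"))
      sprintf("F = %.3f, r2 = %.3f, p = %.4g", obj$F, obj$r_squared,
              obj$p_value)
    else if (inherits(obj, "permdisp"))
      sprintf("F = %.3f, r2 = %.3f, p = %.4g", obj$F, obj$r_squared,
              obj$p_value)
    else if (inherits(obj, "diversity_contrast"))
      sprintf("F = %.3f, r2 = %.3f, p = %.4g", obj$F, obj$r_squared,
              obj$p_value)
    else if (inherits(obj, "simper_table"))
      sprintf("%d significant of %d variables",
              sum(obj$p_value <= 0.05), nrow(obj))
    else if (inherits(obj, "indval"))
      sprintf("%d significant of %d items",
              sum(obj$p_value <= 0.05), nrow(obj))
    else if (inherits(obj, "rarity_report"))
      sprintf("%d rare, %d control-only, %d restored-only of %d taxa",
              sum(obj$rare), sum(obj$exclusive_control),
              sum(obj$exclusive_restored), nrow(obj))
    else if (inherits(obj, "pcoa"))
      sprintf("%d positive axes, %d negative eigenvalues",
              ncol(obj$coordinates), obj$n_negative)
    else next
    cat(sprintf("  %-28s %s\n", nm, line))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Statistics go to `summary.json`; per-sample dispersion distances, SIMPER
#' tables, IndVal tables, diversity values and the rarity report go to CSVs.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summary <- list(provenance = bundle$provenance[
    c("seed", "n_perm", "alpha", "min_patches", "n_samples", "n_taxa",
      "package_version")])
  for (nm in setdiff(names(bundle), c("metadata", "provenance"))) {
    obj <- bundle[[nm]]
    if (inherits(obj, c("permanova", "permdisp", "diversity_contrast"))) {
      summary[[nm]] <- list(F = obj$F, r_squared = obj$r_squared,
                            p_value = obj$p_value)
      if (inherits(obj, "permdisp")) {
        p <- file.path(dir, paste0(nm, "_distances.csv"))
        utils::write.csv(data.frame(sample = names(obj$distances),
                                    distance = obj$distances,
                                    row.names = NULL), p, row.names = FALSE)
        paths <- c(paths, p)
      }
    } else if (inherits(obj, c("simper_table", "indval", "rarity_report")) ||
               is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(obj), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "metadata.csv")
  utils::write.csv(bundle$metadata, p, row.names = FALSE)
  invisible(c(paths, p))
}
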