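#' Construct a functional-trait schema
#'
#' A trait schema is the fixed vocabulary of a fuzzy-coded trait database: an
#' ordered set of *grouping features* (trait categories such as maximum
#' potential size or substrate preference), each holding an ordered set of
#' *traits* (modalities) identified by unique codes such as `"Velocity.3"`.
#' Affinity mass is standardized within each grouping feature, so the schema
#' drives every normalization step downstream.
#'
#' @param features named list mapping each grouping feature to the character
#'   vector of trait codes it contains.
#' @param labels optional data frame with columns `grouping_feature`, `trait`,
#'   `code` giving human-readable modality names.
#' @return An object of class `trait_schema`: a list with elements
#'   `features` (named list of code vectors), `codes` (all codes, in schema
#'   order), `feature_of` (named vector mapping code to grouping feature) and
#'   `labels`.
#' @seealso [load_trait_schema()], [default_trait_schema()]
#' @export
trait_schema <- function(features, labels = NULL) {
  if (!is.list(features) || length(features) == 0L || is.null(names(features)))
    stop("`features` must be a non-empty named list", call. = FALSE)
  if (any(!nzchar(names(features))))
    stop("every grouping feature needs a name", call. = FALSE)
  if (anyDuplicated(names(features)))
    stop("duplicate grouping feature names", call. = FALSE)
  features <- lapply(features, as.character)
  if (any(lengths(features) == 0L))
    stop("every grouping feature must contain at least one trait",
         call. = FALSE)
  codes <- unlist(features, use.names = FALSE)
  dup <- codes[duplicated(codes)]
  if (length(dup))
    stop("duplicate trait codes across the schema: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  feature_of <- rep(names(features), lengths(features))
  names(feature_of) <- codes
  structure(
    list(features = features, codes = codes, feature_of = feature_of,
         labels = labels),
    class = "trait_schema")
}

#' Load a trait schema from a CSV file
#'
#' The file must contain columns `grouping_feature` and `code` (and optionally
#' `trait` with modality labels), one row per trait modality, ordered as the
#' schema should be ordered.
#'
#' @param path path to the schema CSV.
#' @return A [trait_schema()] object.
#' @export
load_trait_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot parse schema file: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L) stop("schema file is empty", call. = FALSE)
  need <- c("grouping_feature", "code")
  if (!all(need %in% names(df)))
    stop("schema file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  feats <- split(df$code, factor(df$grouping_feature,
                                 levels = unique(df$grouping_feature)))
  trait_schema(as.list(feats),
               labels = if ("trait" %in% names(df))
                 df[, c("grouping_feature", "trait", "code")] else NULL)
}

#' The packaged trait schema
#'
#' Thirteen grouping features spanning biological traits (size, life cycle,
#' voltinism, aquatic stages, reproduction, dispersal, resistance,
#' respiration, locomotion, food, feeding group) and two ecological
#' preferences (substrate, velocity), with their 76 trait modalities, as used
#' for European freshwater macroinvertebrate fuzzy-coded trait databases.
#'
#' @return A [trait_schema()] with 13 grouping features.
#' @export
default_trait_schema <- function() {
  load_trait_schema(system.file("extdata", "trait_schema.csv",
                                package = "rivertraits", mustWork = TRUE))
}

#' The dominant-biotope vocabulary
#'
#' The six widely occurring in-channel habitat categories used as sampling
#' units: three organic biotopes (macroalgae and two submerged macrophytes,
#' a fine-leaved *Ranunculus* type and a broad-leaved *Sparganium* type) and
#' three mineralogical biotopes (gravel, sand, and a gravel-in-sand mixture).
#' Organic biotopes occur in both control and restored reaches; bare
#' mineralogical patches are characteristic of restored reaches.
#'
#' @return data frame with columns `biotope` and `category`
#'   (`"organic"`/`"mineralogical"`).
#' @export
dominant_biotopes <- function() {
  utils::read.csv(system.file("extdata", "dominant_biotopes.csv",
                              package = "rivertraits", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("Trait schema:", length(x$features), "grouping features,",
      length(x$codes), "traits\n")
  for (f in names(x$features))
    cat("  ", f, " (", length(x$features[[f]]), ")\n", sep = "")
  invisible(x)
}
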