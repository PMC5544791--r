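# CSV readers for the three input tables. Comma-separated, UTF-8, header
# row mandatory; sample IDs are opaque strings.

#' Read a sample x taxon abundance table
#'
#' Expects sample IDs in the first column and taxon names in the header.
#' Rejects duplicate sample IDs and non-numeric or negative cells, naming
#' the offending coordinates.
#'
#' @param path CSV path.
#' @return integer matrix with sample IDs as rownames.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("abundance table needs sample IDs plus >= 1 taxon",
                          call. = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  taxa <- names(df)[-1]
  m <- matrix(NA_real_, nrow(df), length(taxa), dimnames = list(ids, taxa))
  for (j in seq_along(taxa)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & nzchar(df[[j + 1]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric cell at row ", (which(is.na(v)))[1], ", column '",
           taxa[j], "'", call. = FALSE)
    neg <- which(v < 0)
    if (length(neg))
      stop("negative count at row ", neg[1], ", column '", taxa[j], "'",
           call. = FALSE)
    m[, j] <- v
  }
  if (any(m != round(m)))
    stop("abundance table must contain integer counts", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Read a long-format fuzzy trait table
#'
#' Columns: `taxon`, `rank` (optional), `trait_code`, `affinity`
#' (`grouping_feature` is accepted and ignored; the schema is authoritative).
#'
#' @param path CSV path.
#' @param schema optional [trait_schema()] used to validate codes.
#' @return a [fuzzy_trait_table()].
#' @export
read_trait_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "trait_code", "affinity")
  if (!all(need %in% names(df)))
    stop("trait table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  fuzzy_trait_table(df$taxon, df$trait_code, df$affinity,
                    rank = if ("rank" %in% names(df)) df$rank else
                      NA_character_,
                    schema = schema)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `site_pair`, `reach_type` (`control`/`restored`),
#' `biotope`, `replicate`; an optional `biotope_class` column
#' (`organic`/`mineralogical`) is kept when present.
#'
#' @param path CSV path.
#' @return data frame, one row per sample.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_pair", "reach_type", "biotope", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$reach_type), c("control", "restored"))
  if (length(bad))
    stop("reach_type must be control/restored; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}
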