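# Rarity classification, exclusivity audit, and the dominant-biotope filter.

#' Classify rare and reach-exclusive taxa
#'
#' A taxon is "rare" when it comprises less than 1% of the entire community
#' population (strict inequality); exclusivity records whether a taxon was
#' only ever sampled in control or only in restored reaches.
#'
#' @param abundances sample x taxon count matrix.
#' @param metadata data frame with one row per sample (matching the row
#'   order or `sample_id` of `abundances`), containing a `reach_type` column
#'   with values `"control"`/`"restored"`.
#' @param rare_threshold share of total community abundance below which a
#'   taxon is rare (default 0.01).
#' @return data frame of class `rarity_report`: one row per taxon with
#'   `total`, `share`, `rare`, `n_samples`, `exclusive_control`,
#'   `exclusive_restored`.
#' @export
classify_rare <- function(abundances, metadata, rare_threshold = 0.01) {
  m <- as_numeric_matrix(abundances, "abundances")
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  metadata <- align_metadata(metadata, m)
  total <- colSums(m)
  grand <- sum(total)
  if (grand == 0) stop("empty community (all counts zero)", call. = FALSE)
  present <- m > 0
  in_control <- colSums(present[metadata$reach_type == "control", ,
                                drop = FALSE]) > 0
  in_restored <- colSums(present[metadata$reach_type == "restored", ,
                                 drop = FALSE]) > 0
  out <- data.frame(
    taxon = colnames(m) %||% paste0("taxon", seq_len(ncol(m))),
    total = total,
    share = total / grand,
    rare = total / grand < rare_threshold,
    n_samples = colSums(present),
    exclusive_control = in_control & !in_restored,
    exclusive_restored = in_restored & !in_control,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("rarity_report", "data.frame"))
}

#' Filter metadata to dominant biotopes
#'
#' A biotope counts as dominant within a reach only when it provided at
#' least `min_patches` replicate samples there (one sample per distinct
#' patch); rarer biotopes are dropped from that reach. Exclusions are
#' recorded in the `exclusions` attribute.
#'
#' @param metadata sample metadata with columns `site_pair`, `reach_type`,
#'   `biotope`.
#' @param min_patches minimum replicate samples per (reach, biotope)
#'   (default 3).
#' @return the filtered metadata, with attribute `exclusions` (a data frame
#'   of dropped reach/biotope combinations and their sample counts).
#' @export
filter_dominant_biotopes <- function(metadata, min_patches = 3) {
  stopifnot(is.data.frame(metadata), min_patches >= 1)
  need <- c("site_pair", "reach_type", "biotope")
  if (!all(need %in% names(metadata)))
    stop("metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cnt <- stats::aggregate(list(n_samples = rep(1L, nrow(metadata))),
                          by = metadata[, need], FUN = sum)
  excl <- cnt[cnt$n_samples < min_patches, , drop = FALSE]
  rownames(excl) <- NULL
  key_meta <- do.call(paste, c(metadata[, need], sep = "\r"))
  key_drop <- do.call(paste, c(excl[, need], sep = "\r"))
  keep <- !(key_meta %in% key_drop)
  if (!any(keep))
    stop("all biotopes excluded by the dominant-biotope filter",
         call. = FALSE)
  out <- metadata[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exclusions = excl)
}

# Align a metadata frame to abundance-matrix rows (by sample_id when
# available, otherwise by position).
align_metadata <- function(metadata, m) {
  stopifnot(is.data.frame(metadata))
  if (!is.null(rownames(m)) && "sample_id" %in% names(metadata)) {
    idx <- match(rownames(m), metadata$sample_id)
    if (anyNA(idx))
      stop("samples missing from metadata: ",
           paste(rownames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
    metadata <- metadata[idx, , drop = FALSE]
  } else if (nrow(metadata) != nrow(m)) {
    stop("metadata rows do not match abundance rows", call. = FALSE)
  }
  metadata
}
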