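# SIMPER: decomposition of the average between-group Bray-Curtis
# dissimilarity into additive per-variable contributions, with a
# label-permutation test per variable.

# Average per-variable contribution over all between-group sample pairs.
# data: samples x variables; i1, i2: row indices of the two groups.
simper_contributions <- function(data, i1, i2) {
  p <- ncol(data)
  contrib <- numeric(p)
  for (j in i1) {
    xj <- data[j, ]
    for (k in i2) {
      xk <- data[k, ]
      denom <- sum(xj + xk)
      contrib <- contrib + abs(xj - xk) / denom
    }
  }
  contrib / (length(i1) * length(i2))
}

#' SIMPER dissimilarity decomposition between two groups
#'
#' For each pair of samples taken one from each group, the contribution of
#' variable i to their Bray-Curtis dissimilarity is
#' `|x_ij - x_ik| / sum_m(x_mj + x_mk)`; contributions are averaged over all
#' between-group pairs and sum exactly to the mean between-group
#' dissimilarity. Per-variable significance is assessed by permuting group
#' labels and counting permuted average contributions at least as large as
#' observed, `p = (1 + count) / (1 + n_perm)`.
#'
#' @param data sample x variable nonnegative matrix (e.g. ln(x+1)-transformed
#'   abundances or trait profiles).
#' @param groups group label per sample. With more than two levels all
#'   pairwise contrasts are run and returned as a named list.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed (required).
#' @return For a two-level contrast, an object of class `simper_table`: a data
#'   frame (one row per variable, ordered by decreasing contribution) with
#'   `average` contribution, `share`, `cumulative` share, group means and
#'   standard deviations, and `p_value`; attribute `overall` holds the mean
#'   between-group dissimilarity.
#' @export
simper <- function(data, groups, n_perm = 999, seed = NULL) {
  m <- as_numeric_matrix(data, "data")
  if (any(m < 0)) stop("SIMPER requires nonnegative data", call. = FALSE)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  if (length(lev) > 2L) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    out <- lapply(pairs, function(pr) {
      keep <- groups %in% pr
      simper(m[keep, , drop = FALSE], groups[keep], n_perm = n_perm,
             seed = seed)
    })
    names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    return(out)
  }
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  obs <- simper_contributions(m, i1, i2)
  ge <- with_seed(seed, {
    cnt <- integer(length(obs))
    n1 <- length(i1)
    for (r in seq_len(n_perm)) {
      ord <- sample(nrow(m))
      perm <- simper_contributions(m, ord[seq_len(n1)], ord[-seq_len(n1)])
      cnt <- cnt + (perm >= obs - 1e-12)
    }
    cnt
  })
  pval <- (1 + ge) / (1 + n_perm)
  vars <- colnames(m) %||% paste0("V", seq_along(obs))
  overall <- sum(obs)
  ord <- order(obs, decreasing = TRUE)
  df <- data.frame(
    variable = vars,
    average = obs,
    share = if (overall > 0) obs / overall else rep(0, length(obs)),
    mean_1 = colMeans(m[i1, , drop = FALSE]),
    sd_1 = apply(m[i1, , drop = FALSE], 2, stats::sd),
    mean_2 = colMeans(m[i2, , drop = FALSE]),
    sd_2 = apply(m[i2, , drop = FALSE], 2, stats::sd),
    p_value = pval,
    stringsAsFactors = FALSE, row.names = NULL)[ord, ]
  df$cumulative <- cumsum(df$share)
  rownames(df) <- NULL
  names(df)[names(df) == "mean_1"] <- paste0("mean_", lev[1])
  names(df)[names(df) == "sd_1"] <- paste0("sd_", lev[1])
  names(df)[names(df) == "mean_2"] <- paste0("mean_", lev[2])
  names(df)[names(df) == "sd_2"] <- paste0("sd_", lev[2])
  structure(df, overall = overall, groups = lev, n_perm = n_perm,
            class = c("simper_table", "data.frame"))
}

#' @export
print.simper_table <- function(x, n = 10, ...) {
  cat("SIMPER contrast ", attr(x, "groups")[1], " vs ", attr(x, "groups")[2],
      ": mean between-group dissimilarity = ",
      sprintf("%.4f", attr(x, "overall")), "\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more variables\n", sep = "")
  invisible(x)
}
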