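# Group-equalized indicator value analysis over group combinations.
#
# For each item (taxon or trait) and each non-empty proper subset C of the
# groups: A (specificity) is the share of the group-equalized mean value
# concentrated in C; B (fidelity) is the fraction of samples in C where the
# item occurs. The statistic sqrt(A * B) is maximized over combinations and
# its significance assessed by permuting sample group memberships.

#' Group-equalized indicator value (IndVal) analysis over combinations
#'
#' For item i and group combination C: `A = sum_{g in C} mean_g(i) /
#' sum_{all g} mean_g(i)` (within-group means, so unequal group sizes do not
#' bias specificity) and `B = Pr(item present | sample in C)` with presence
#' meaning value > 0. The indicator statistic is `sqrt(A * B)`; the reported
#' combination maximizes it. The full group set is excluded from the
#' combination space (an item indicating every group indicates nothing).
#' Significance per item: group memberships are permuted and the permuted
#' maximum statistic compared to the observed one,
#' `p = (1 + count) / (1 + n_perm)`. Items with zero total value are excluded
#' and reported in the `excluded` attribute.
#'
#' @param data sample x item nonnegative matrix (abundances or trait
#'   profiles).
#' @param groups group label per sample (>= 2 groups, e.g. biotopes).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed (required).
#' @param max_order largest combination size examined (default: number of
#'   groups minus 1, i.e. all proper subsets).
#' @return object of class `indval`: data frame with one row per item
#'   (`item`, `combination`, `A`, `B`, `stat`, `p_value`), attribute
#'   `excluded` naming zero-total items.
#' @export
indval_combinations <- function(data, groups, n_perm = 999, seed = NULL,
                                max_order = NULL) {
  m <- as_numeric_matrix(data, "data")
  if (any(m < 0)) stop("IndVal requires nonnegative data", call. = FALSE)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  excluded <- colnames(m)[colSums(m) == 0]
  if (length(excluded))
    message("excluding item(s) with zero total value: ",
            paste(excluded, collapse = ", "))
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) == 0L) stop("no items with positive values", call. = FALSE)

  G <- length(lev)
  max_order <- max_order %||% (G - 1L)
  max_order <- min(max_order, G - 1L)
  # combination membership matrix (combos x groups)
  combos <- unlist(lapply(seq_len(max_order), function(k)
    utils::combn(G, k, simplify = FALSE)), recursive = FALSE)
  M <- matrix(FALSE, length(combos), G)
  for (i in seq_along(combos)) M[i, combos[[i]]] <- TRUE
  combo_names <- vapply(combos, function(ix) paste(lev[ix], collapse = "+"),
                        character(1))

  stat_fun <- function(glab) {
    gi <- factor(glab, levels = lev)
    ng <- as.integer(table(gi))
    means <- rowsum(m, gi) / ng                  # G x items, within-group means
    npres <- rowsum((m > 0) + 0, gi)             # G x items, presence counts
    A <- (M %*% means) / rep(colSums(means), each = nrow(M))
    B <- (M %*% npres) / as.numeric(M %*% ng)
    sqrt(A * B)                                  # combos x items
  }
  s_obs <- stat_fun(groups)
  best <- apply(s_obs, 2, which.max)
  stat <- s_obs[cbind(best, seq_len(ncol(s_obs)))]
  ge <- with_seed(seed, {
    cnt <- integer(ncol(m))
    for (r in seq_len(n_perm)) {
      sp <- apply(stat_fun(sample(groups)), 2, max)
      cnt <- cnt + (sp >= stat - 1e-12)
    }
    cnt
  })
  res <- data.frame(item = colnames(m),
                    combination = combo_names[best],
                    A = A_of(s_obs, M, m, groups, lev, best),
                    B = B_of(m, groups, lev, M, best),
                    stat = stat,
                    p_value = (1 + ge) / (1 + n_perm),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, excluded = excluded, n_perm = n_perm,
            class = c("indval", "data.frame"))
}

# A and B at the chosen combination (recomputed explicitly for reporting).
A_of <- function(s_obs, M, m, groups, lev, best) {
  gi <- factor(groups, levels = lev)
  means <- rowsum(m, gi) / as.integer(table(gi))
  A <- (M %*% means) / rep(colSums(means), each = nrow(M))
  A[cbind(best, seq_len(ncol(A)))]
}

B_of <- function(m, groups, lev, M, best) {
  gi <- factor(groups, levels = lev)
  npres <- rowsum((m > 0) + 0, gi)
  ng <- as.integer(table(gi))
  B <- (M %*% npres) / as.numeric(M %*% ng)
  B[cbind(best, seq_len(ncol(B)))]
}

#' @export
print.indval <- function(x, n = 10, alpha = 0.05, ...) {
  cat("Group-equalized IndVal over group combinations (",
      attr(x, "n_perm"), " permutations)\n", sep = "")
  ord <- order(x$p_value, -x$stat)
  print.data.frame(utils::head(x[ord, ], n), digits = 3)
  cat("  ", sum(x$p_value <= alpha), " of ", nrow(x),
      " items significant at alpha = ", alpha, "\n", sep = "")
  ex <- attr(x, "excluded")
  if (length(ex)) cat("  excluded (zero total):",
                      paste(ex, collapse = ", "), "\n")
  invisible(x)
}
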