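# Distance-based permutational multivariate analysis of variance with
# permutations restricted within blocks (strata), after the standard
# one-factor decomposition of squared inter-point distances.

# Sums of squares and pseudo-F from a squared-distance matrix and group
# labels. SS_total = sum_{i<j} d2_ij / N; SS_within = sum_g sum_{i<j in g}
# d2_ij / n_g.
permanova_stats <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ug <- unique(groups)
  a <- length(ug)
  ss_within <- 0
  for (g in ug) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(F = f, r_squared = ss_between / ss_total,
       ss_total = ss_total, ss_within = ss_within, ss_between = ss_between,
       df_between = a - 1, df_within = n - a)
}

# All distinct permutations of a label multiset, one arrangement per row.
multiset_perms <- function(x) {
  n <- length(x)
  if (n <= 1L) return(matrix(x, nrow = 1L))
  x <- sort(x)
  rows <- list()
  last <- NULL
  for (i in seq_len(n)) {
    if (!is.null(last) && x[i] == last) next
    last <- x[i]
    sub <- multiset_perms(x[-i])
    rows[[length(rows) + 1L]] <- cbind(x[i], sub, deparse.level = 0)
  }
  do.call(rbind, rows)
}

# Number of distinct within-block relabelings of `groups` given `blocks`.
count_relabelings <- function(groups, blocks) {
  out <- 1
  for (b in unique(blocks)) {
    tab <- table(groups[blocks == b])
    nb <- sum(tab)
    out <- out * exp(lgamma(nb + 1) - sum(lgamma(tab + 1)))
    if (out > 1e12) return(Inf)
  }
  round(out)
}

#' Blocked (restricted-permutation) PERMANOVA
#'
#' One-factor permutational multivariate analysis of variance on a distance
#' matrix, with group labels permuted independently *within* blocks (strata),
#' e.g. within each paired control/restored site. The pseudo-F partitions
#' squared inter-point distances into between- and within-group sums of
#' squares; on Euclidean distances of univariate data it reduces exactly to
#' the classical one-way ANOVA F.
#'
#' When the number of distinct within-block relabelings is at most
#' `max_exact` the permutation null is enumerated exhaustively and the
#' p-value is the exact proportion `count / total` (the observed labeling
#' included); otherwise `n_perm` random relabelings give
#' `p = (1 + count) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix (samples in rows/columns).
#' @param groups group label per sample (>= 2 groups).
#' @param blocks block label per sample, or `NULL` for unrestricted
#'   permutation (a single block).
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed (required whenever random permutations are used).
#' @param max_exact relabeling-count threshold below which the null is
#'   enumerated exactly (default 10000).
#' @return object of class `permanova` with `F`, `r_squared`, `p_value`,
#'   `n_permutations_used`, `exact_enumeration`, degrees of freedom and the
#'   sums of squares.
#' @examples
#' set.seed(1)
#' x <- matrix(rpois(40, 8), nrow = 8)
#' d <- bray_curtis(log_transform(x))
#' permanova_blocked(d, groups = rep(c("control", "restored"), 4),
#'                   blocks = rep(1:2, each = 4), n_perm = 199, seed = 42)
#' @export
permanova_blocked <- function(d, groups, blocks = NULL, n_perm = 999,
                              seed = NULL, max_exact = 10000) {
  d <- validate_dist_matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(blocks)) blocks <- rep("all", n)
  blocks <- as.character(blocks)
  stopifnot(length(blocks) == n)
  if (any(table(blocks) < 2L))
    stop("every block must contain at least 2 samples", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d2 <- d^2
  if (sum(d2) == 0)
    stop("degenerate input: all samples identical (SS_total = 0)",
         call. = FALSE)
  one_group_blocks <- vapply(unique(blocks), function(b)
    length(unique(groups[blocks == b])) == 1L, logical(1))
  if (any(one_group_blocks))
    warning("block(s) containing a single group (labels unshuffleable): ",
            paste(unique(blocks)[one_group_blocks], collapse = ", "),
            call. = FALSE)

  obs <- permanova_stats(d2, groups)
  ftol <- 1e-8 * max(1, abs(obs$F))
  n_exact <- count_relabelings(groups, blocks)
  block_idx <- split(seq_len(n), blocks)

  if (is.finite(n_exact) && n_exact <= max_exact) {
    # exhaustive enumeration: cross product of per-block distinct relabelings
    perms_by_block <- lapply(block_idx, function(idx)
      multiset_perms(groups[idx]))
    counts <- vapply(perms_by_block, nrow, integer(1))
    total <- prod(counts)
    grid <- as.matrix(expand.grid(lapply(counts, seq_len)))
    ge <- 0L
    lab <- character(n)
    for (r in seq_len(total)) {
      for (bi in seq_along(block_idx))
        lab[block_idx[[bi]]] <- perms_by_block[[bi]][grid[r, bi], ]
      if (permanova_stats(d2, lab)$F >= obs$F - ftol) ge <- ge + 1L
    }
    p <- ge / total
    used <- total
    exact <- TRUE
  } else {
    if (is.null(seed))
      stop("`seed` is required for random permutations", call. = FALSE)
    ge <- with_seed(seed, {
      cnt <- 0L
      lab <- groups
      for (r in seq_len(n_perm)) {
        for (idx in block_idx) lab[idx] <- groups[sample(idx)]
        if (permanova_stats(d2, lab)$F >= obs$F - ftol) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + ge) / (1 + n_perm)
    used <- n_perm
    exact <- FALSE
  }
  structure(list(F = obs$F, r_squared = obs$r_squared, p_value = p,
                 n_permutations_used = used, exact_enumeration = exact,
                 df = c(between = obs$df_between, within = obs$df_within),
                 ss = c(total = obs$ss_total, between = obs$ss_between,
                        within = obs$ss_within),
                 groups = groups, blocks = blocks),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("Blocked PERMANOVA (", length(unique(x$groups)), " groups, ",
      length(unique(x$blocks)), " block(s))\n", sep = "")
  cat(sprintf("  pseudo-F = %.4g on %d and %d df,  r2 = %.4f\n",
              x$F, x$df[["between"]], x$df[["within"]], x$r_squared))
  cat(sprintf("  p = %.4g  (%s, %d permutations)\n", x$p_value,
              if (x$exact_enumeration) "exact enumeration" else "sampled",
              x$n_permutations_used))
  invisible(x)
}
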