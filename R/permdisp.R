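# Multivariate dispersion: distance of each sample to its group centroid in
# principal-coordinate space, with ANOVA-based significance. Used both for
# the control/restored heterogeneity contrast and as a beta-diversity
# measure per biotope.

#' Multivariate dispersion analysis (distance to group centroids)
#'
#' Embeds the distance matrix by [pcoa()] (retaining imaginary axes for
#' negative eigenvalues), computes each sample's distance to its group
#' centroid as the square root of (squared real-axis distance minus squared
#' imaginary-axis distance), and tests homogeneity of dispersion among
#' groups by a classical one-way ANOVA on these distances. Negative
#' corrected squared distances (a floating-point artifact of strongly
#' non-Euclidean dissimilarities) are clamped to zero with a warning.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample; >= 2 groups with >= 2 samples each.
#' @param permutation_test additionally compute a permutation p-value for
#'   the ANOVA F by shuffling group labels (off by default; the ANOVA p is
#'   the primary significance measure).
#' @param n_perm,seed permutation settings when `permutation_test = TRUE`.
#' @return object of class `permdisp` with `distances` (per sample),
#'   `group_means`, `F`, `p_value`, `r_squared`, `df`, and optionally
#'   `p_permutation`.
#' @examples
#' set.seed(2)
#' x <- matrix(rpois(60, 6), nrow = 12)
#' d <- bray_curtis(log_transform(x))
#' permdisp(d, rep(c("a", "b"), each = 6))
#' @export
permdisp <- function(d, groups, permutation_test = FALSE, n_perm = 999,
                     seed = NULL) {
  d <- validate_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  ord <- pcoa(d)
  z <- centroid_distances(ord, groups)
  if (all(z == 0))
    stop("degenerate input: zero dispersion in every group", call. = FALSE)
  fit <- stats::aov(z ~ factor(groups))
  an <- stats::anova(fit)
  out <- list(distances = stats::setNames(z, rownames(d)),
              group_means = tapply(z, groups, mean),
              F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
              r_squared = an[["Sum Sq"]][1] / sum(an[["Sum Sq"]]),
              df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
              groups = groups)
  if (permutation_test) {
    if (is.null(seed)) stop("`seed` required for the permutation test",
                            call. = FALSE)
    fobs <- out$F
    ge <- with_seed(seed, {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        gp <- sample(groups)
        fp <- stats::anova(stats::aov(z ~ factor(gp)))[["F value"]][1]
        if (fp >= fobs - 1e-12) cnt <- cnt + 1L
      }
      cnt
    })
    out$p_permutation <- (1 + ge) / (1 + n_perm)
  }
  structure(out, class = "permdisp")
}

# Distance of each sample to its group centroid in PCoA space, correcting
# squared real-axis distances by the imaginary-axis component.
centroid_distances <- function(ord, groups) {
  re <- ord$coordinates
  im <- ord$imaginary
  n <- nrow(re)
  z2 <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cr <- colMeans(re[idx, , drop = FALSE])
    d2r <- rowSums(sweep(re[idx, , drop = FALSE], 2, cr)^2)
    d2i <- 0
    if (ncol(im) > 0) {
      ci <- colMeans(im[idx, , drop = FALSE])
      d2i <- rowSums(sweep(im[idx, , drop = FALSE], 2, ci)^2)
    }
    z2[idx] <- d2r - d2i
  }
  if (any(z2 < -1e-8))
    warning("negative corrected squared distances clamped to zero",
            call. = FALSE)
  sqrt(pmax(z2, 0))
}

#' @export
print.permdisp <- function(x, ...) {
  cat("Multivariate dispersion (distance to group centroid)\n")
  gm <- x$group_means
  for (g in names(gm))
    cat(sprintf("  %-12s mean distance = %.4f\n", g, gm[[g]]))
  cat(sprintf("  ANOVA F = %.4g on %d and %d df,  r2 = %.4f,  p = %.4g\n",
              x$F, x$df[["between"]], x$df[["within"]], x$r_squared,
              x$p_value))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p = %.4g\n", x$p_permutation))
  invisible(x)
}
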