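# Alpha diversity (inverse Simpson), beta diversity (dispersion per group),
# and one-way ANOVA + Tukey HSD contrasts of diversity values.

#' Inverse Simpson diversity
#'
#' `D = 1 / sum(p_i^2)` on the row-normalized proportions: the effective
#' number of equally common categories. Bounded between 1 (a single
#' category) and the number of nonzero categories (attained at uniformity),
#' and insensitive to the total, which suits trait profiles whose category
#' count is fixed by the schema.
#'
#' @param composition a nonnegative vector, or a sample x category matrix
#'   (one value per row).
#' @return numeric vector of diversity values.
#' @export
inverse_simpson <- function(composition) {
  m <- if (is.matrix(composition) || is.data.frame(composition))
    as_numeric_matrix(composition, "composition")
  else matrix(composition, nrow = 1)
  if (any(m < 0)) stop("negative entries", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    who <- rownames(m)[tot == 0] %||% which(tot == 0)
    stop("zero-sum composition for: ", paste(who, collapse = ", "),
         call. = FALSE)
  }
  d <- vegan::diversity(m, index = "invsimpson")
  stats::setNames(as.numeric(d), rownames(m))
}

#' Per-sample diversity table
#'
#' @param composition sample x category matrix (taxonomic abundances,
#'   typically ln(x+1)-transformed, or trait profiles renormalized to unit
#'   sum across all traits).
#' @param type tag recorded with the values, `"taxonomic"` or `"trait"`.
#' @return data frame with columns `sample`, `type`, `D`.
#' @export
diversity_table <- function(composition, type = c("taxonomic", "trait")) {
  type <- match.arg(type)
  d <- inverse_simpson(composition)
  data.frame(sample = names(d) %||% seq_along(d), type = type, D = as.numeric(d),
             stringsAsFactors = FALSE)
}

#' Beta diversity as multivariate dispersion per group
#'
#' Runs [permdisp()] with (typically) biotope as the grouping factor; the
#' per-sample distance to the group centroid measures among-sample
#' compositional heterogeneity within each habitat.
#'
#' @inheritParams permdisp
#' @return a [permdisp()] result.
#' @export
beta_dispersion_by_group <- function(d, groups, permutation_test = FALSE,
                                     n_perm = 999, seed = NULL) {
  permdisp(d, groups, permutation_test = permutation_test, n_perm = n_perm,
           seed = seed)
}

#' One-way ANOVA with Tukey HSD contrasts
#'
#' Fits a one-way linear model of a per-sample response (alpha- or
#' beta-diversity value) on a grouping factor, reports the classical ANOVA
#' F, p and r-squared, all pairwise Tukey Honest Significant Difference
#' comparisons at family-wise level `alpha`, and residual diagnostics
#' (Shapiro-Wilk normality p and the max/min ratio of per-group residual
#' spread), which are reported but not enforced.
#'
#' @param values numeric response, one per sample.
#' @param groups group label per sample (>= 2 groups, >= 2 samples each).
#' @param alpha family-wise error level for the Tukey intervals (default
#'   0.05).
#' @return object of class `diversity_contrast` with `F`, `p_value`,
#'   `r_squared`, `df`, `tukey` (data frame of pairwise mean differences,
#'   intervals and adjusted p), and `diagnostics`.
#' @export
contrast_anova_tukey <- function(values, groups, alpha = 0.05) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  if (an[["Mean Sq"]][2] <= .Machine$double.eps * max(1, mean(values)^2))
    stop("degenerate model: zero residual variance", call. = FALSE)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL,
                      stringsAsFactors = FALSE)
  names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  res <- stats::residuals(fit)
  spread <- tapply(res, g, function(r) stats::sd(r))
  diagnostics <- list(
    shapiro_p = tryCatch(stats::shapiro.test(res)$p.value,
                         error = function(e) NA_real_),
    spread_ratio = max(spread) / max(min(spread), .Machine$double.eps),
    normality_flag = NA, homogeneity_flag = NA)
  diagnostics$normality_flag <- is.na(diagnostics$shapiro_p) ||
    diagnostics$shapiro_p > 0.05
  diagnostics$homogeneity_flag <- diagnostics$spread_ratio < 3
  structure(list(F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 r_squared = an[["Sum Sq"]][1] / sum(an[["Sum Sq"]]),
                 df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
                 alpha = alpha, tukey = tukey, diagnostics = diagnostics,
                 group_means = tapply(values, g, mean)),
            class = "diversity_contrast")
}

#' @export
print.diversity_contrast <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g on %d and %d df, r2 = %.4f, p = %.4g\n",
              x$F, x$df[["between"]], x$df[["within"]], x$r_squared,
              x$p_value))
  cat("Tukey HSD (family-wise alpha =", x$alpha, "):\n")
  print.data.frame(x$tukey, digits = 4)
  invisible(x)
}
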