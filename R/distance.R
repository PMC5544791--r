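# Dissimilarity and ordination: ln(x+1) transform, Bray-Curtis, PCoA.

#' ln(x + 1) transform of a count matrix
#'
#' @param abundances nonnegative numeric matrix (samples x taxa).
#' @return matrix of the same shape with natural-log `log(x + 1)` entries.
#' @export
log_transform <- function(abundances) {
  m <- as_numeric_matrix(abundances, "abundances")
  if (any(m < 0)) stop("negative entries in abundance matrix", call. = FALSE)
  log1p(m)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), bounded in \[0, 1\] for
#' nonnegative data; a semi-metric (no triangle inequality). Computed via
#' [vegan::vegdist()] after validating that every sample has a positive
#' total (an all-zero sample has no defined dissimilarity).
#'
#' @param data sample x variable nonnegative matrix (transformed abundances
#'   or trait profiles).
#' @return symmetric `dist_matrix` (a base matrix with sample dimnames).
#' @export
bray_curtis <- function(data) {
  m <- as_numeric_matrix(data, "data")
  if (any(m < 0)) stop("Bray-Curtis requires nonnegative data", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    who <- rownames(m)[zero] %||% which(zero)
    stop("all-zero sample(s): ", paste(who, collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

validate_dist_matrix <- function(d) {
  d <- as_numeric_matrix(d, "distance matrix")
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigen-decomposes the Gower double-centered matrix of -d^2/2. Axes with
#' positive eigenvalues carry real coordinates scaled by sqrt(lambda); axes
#' with negative eigenvalues (which arise for semi-metric dissimilarities
#' such as Bray-Curtis) are retained as "imaginary" coordinates scaled by
#' sqrt(-lambda), because the multivariate dispersion analysis needs them to
#' correct squared distances to centroids. No Lingoes/Cailliez correction is
#' applied.
#'
#' @param d symmetric distance matrix.
#' @return object of class `pcoa` with elements `eigenvalues` (descending),
#'   `coordinates` (samples x positive axes), `imaginary` (samples x negative
#'   axes), `n_negative`, and `trace` (of the centered matrix).
#' @export
pcoa <- function(d) {
  d <- validate_dist_matrix(d)
  n <- nrow(d)
  D2 <- d^2
  # Gower centering: G = -(I - J/n) D2 (I - J/n) / 2
  rm_ <- rowMeans(D2); gm <- mean(D2)
  G <- -0.5 * (D2 - outer(rm_, rm_, function(a, b) a + b) + gm)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values), .Machine$double.eps)
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), length(neg))
  rownames(coords) <- rownames(imag) <- rownames(d)
  if (length(pos)) colnames(coords) <- paste0("Axis.", seq_along(pos))
  if (length(neg)) colnames(imag) <- paste0("NegAxis.", seq_along(neg))
  structure(list(eigenvalues = e$values, coordinates = coords,
                 imaginary = imag, n_negative = length(neg),
                 trace = sum(diag(G))),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat("Principal coordinates analysis\n")
  cat("  samples:", length(x$eigenvalues),
      " positive axes:", ncol(x$coordinates),
      " negative eigenvalues:", x$n_negative, "\n")
  rel <- x$eigenvalues[x$eigenvalues > 0] / sum(x$eigenvalues[x$eigenvalues > 0])
  cat("  first axes (% of positive eigenvalue mass):",
      paste0(round(100 * utils::head(rel, 3), 1), "%", collapse = ", "), "\n")
  invisible(x)
}
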