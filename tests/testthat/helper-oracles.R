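# Independent brute-force oracles, written against the definitions (explicit
# pair loops and exhaustive permutation), never calling the implementation
# paths they check.

# Bray-Curtis by direct evaluation of the formula.
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

# One-factor pseudo-F from a distance matrix, by explicit pair loops.
oracle_F <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      s <- 0
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx))
        s <- s + d[idx[ii], idx[jj]]^2
      ssw <- ssw + s / length(idx)
    }
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# All n! index permutations, one per row (plain recursion).
all_index_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_index_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n))
    out[[k]] <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
  do.call(rbind, out)
}

# Exact within-block permutation p-value by full enumeration (distinct
# relabelings; observed labeling included in the reference set).
oracle_exact_p <- function(d, groups, blocks) {
  n <- length(groups)
  bl <- split(seq_len(n), blocks)
  per_block <- lapply(bl, function(idx) {
    pm <- all_index_perms(length(idx))
    labs <- unique(apply(pm, 1, function(o)
      paste(groups[idx][o], collapse = "\r")))
    do.call(rbind, strsplit(labs, "\r", fixed = TRUE))
  })
  grid <- expand.grid(lapply(per_block, function(m) seq_len(nrow(m))))
  fobs <- oracle_F(d, groups)
  cnt <- 0L
  for (r in seq_len(nrow(grid))) {
    lab <- character(n)
    for (b in seq_along(bl)) lab[bl[[b]]] <- per_block[[b]][grid[[b]][r], ]
    if (oracle_F(d, lab) >= fobs - 1e-8 * max(1, abs(fobs))) cnt <- cnt + 1L
  }
  cnt / nrow(grid)
}

# Community trait profile for one sample and one grouping feature by the
# weighted-mean definition: sum_t w_t p_t / sum_t w_t, w_t = ln(n_t + 1).
oracle_feature_profile <- function(counts, profiles) {
  w <- log(counts + 1)
  num <- rep(0, ncol(profiles))
  for (t in seq_along(w)) num <- num + w[t] * profiles[t, ]
  if (sum(num) == 0) return(num)
  num / sum(num)
}

# A random Euclidean distance matrix from a point cloud.
random_euclidean_d <- function(n, p) {
  pts <- matrix(rnorm(n * p), n, p)
  as.matrix(stats::dist(pts))
}
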