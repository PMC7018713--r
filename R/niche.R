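# Niche analysis: community filtering, Hellinger transformation, Outlying
# Mean Index (OMI) ordination, abundance-weighted kernel niches and
# Schoener's D overlap.

#' Drop unique sequences seen in fewer than two libraries
#'
#' Metabarcoding pre-filter: a taxon (unique sequence) is retained only when
#' observed in at least two different samples.
#'
#' @param counts samples x taxa count matrix.
#' @param min_libraries minimum number of samples with a positive count.
#' @return the filtered count matrix (possibly with zero columns, with a
#'   warning).
#' @export
filter_unique_sequences <- function(counts, min_libraries = 2) {
  counts <- as.matrix(counts)
  keep <- colSums(counts > 0) >= min_libraries
  if (!any(keep)) warning("no taxa retained by the library filter",
                          call. = FALSE)
  counts[, keep, drop = FALSE]
}

#' Hellinger transformation
#'
#' Square root of within-sample relative abundances:
#' `y_ij -> sqrt(y_ij / sum_j y_ij)`. Each transformed row has unit sum of
#' squares.
#'
#' @param m samples x taxa matrix of non-negative counts or abundances with
#'   no all-zero row.
#' @return the transformed matrix.
#' @export
hellinger <- function(m) {
  m <- as.matrix(m)
  zero <- which(rowSums(m) == 0)
  if (length(zero)) stop("all-zero sample row: ", zero[1], call. = FALSE)
  out <- vegan::decostand(m, method = "hellinger")
  out <- unclass(out)
  attributes(out) <- attributes(out)[c("dim", "dimnames")]
  out
}

#' Outlying Mean Index niche analysis
#'
#' Measures each taxon's niche position and breadth in environmental space.
#' Descriptors are range-standardized to `[0, 1]` and centered on the
#' uniform sample mean (so the origin represents average conditions). With
#' `q_s` the taxon's abundance profile over samples, the marginality vector
#' is `m_s = sum_i q_s(i) x_i`; OMI is its squared norm, tolerance the
#' abundance-weighted variance of the projections on the marginality
#' direction, and residual tolerance the remainder of the taxon's inertia.
#' Niche axes are the eigenvectors of the taxon-weighted marginality
#' cross-product matrix, and `sum(eigenvalues) = sum_s w_s OMI_s` with
#' `w_s` the taxon's share of total abundance.
#'
#' @param y samples x taxa abundance matrix (e.g. [hellinger()]
#'   transformed); taxa with zero totals are excluded with a warning.
#' @param x samples x descriptors environment matrix.
#' @return a list of class `omi_result`: `taxa` (data frame with `omi`,
#'   `tolerance`, `residual`, `inertia`, `weight`), `marginality` (taxa x
#'   descriptors), `eigenvalues`, `axes` (descriptors x axes), `scores`
#'   (samples x axes), `env` (the standardized, centered descriptors).
#' @export
omi_analysis <- function(y, x) {
  y <- as.matrix(y); x <- as.matrix(x)
  stopifnot(nrow(y) == nrow(x))
  tot <- colSums(y)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0), " taxa with zero total abundance",
            call. = FALSE)
    y <- y[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!ncol(y)) stop("no taxa with positive abundance", call. = FALSE)
  X <- range_standardize(x)
  X <- sweep(X, 2, colMeans(X))
  Q <- sweep(y, 2, tot, "/")              # per-taxon sample profiles
  M <- t(Q) %*% X                          # marginality vectors (taxa x p)
  inertia <- colSums(t(X^2) %*% Q)         # sum_i q_s(i) ||x_i||^2
  omi <- rowSums(M^2)
  tolerance <- vapply(seq_len(ncol(y)), function(s) {
    if (omi[s] == 0) return(0)
    u <- M[s, ] / sqrt(omi[s])
    z <- X %*% u
    sum(Q[, s] * z^2) - sum(Q[, s] * z)^2
  }, numeric(1))
  residual <- inertia - omi - tolerance
  w <- tot / sum(tot)
  C <- t(M) %*% (w * M)
  eig <- eigen(C, symmetric = TRUE)
  k <- sum(eig$values > 1e-12 * max(eig$values, 0))
  k <- max(k, 1L)
  axes <- eig$vectors[, seq_len(k), drop = FALSE]
  # canonical sign: make the largest-magnitude loading of each axis positive
  for (a in seq_len(ncol(axes))) {
    top <- which.max(abs(axes[, a]))
    if (axes[top, a] < 0) axes[, a] <- -axes[, a]
  }
  rownames(axes) <- colnames(X)
  colnames(axes) <- paste0("OMI", seq_len(k))
  scores <- X %*% axes
  taxa <- data.frame(taxon = colnames(y), omi = omi, tolerance = tolerance,
                     residual = residual, inertia = inertia, weight = w,
                     row.names = NULL)
  structure(list(taxa = taxa, marginality = M,
                 eigenvalues = eig$values[seq_len(k)], axes = axes,
                 scores = scores, env = X),
            class = "omi_result")
}

#' @export
print.omi_result <- function(x, ...) {
  cat("<omi_result> ", nrow(x$taxa), " taxa, ",
      length(x$eigenvalues), " axes; first two eigenvalues ",
      paste(signif(x$eigenvalues[1:min(2, length(x$eigenvalues))], 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Permutation significance of per-taxon OMI
#'
#' Tests each taxon's niche marginality against the null hypothesis of no
#' association between its abundances and the environment, by recomputing
#' OMI after randomly permuting the sample rows of the abundance matrix.
#' `p = (hits + 1) / (n_perm + 1)` with hits counting permuted OMI values
#' at least as large as the observed one.
#'
#' @inheritParams omi_analysis
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data frame with `taxon`, `omi`, `p`.
#' @export
omi_significance <- function(y, x, n_perm = 199, seed = 1) {
  y <- as.matrix(y); x <- as.matrix(x)
  obs <- omi_analysis(y, x)
  set.seed(seed)
  hits <- numeric(nrow(obs$taxa))
  for (r in seq_len(n_perm)) {
    om_p <- omi_analysis(y[sample.int(nrow(y)), , drop = FALSE], x)
    hits <- hits + (om_p$taxa$omi >= obs$taxa$omi)
  }
  data.frame(taxon = obs$taxa$taxon, omi = obs$taxa$omi,
             p = (hits + 1) / (n_perm + 1))
}

#' Abundance-weighted kernel niche on two ordination axes
#'
#' Gaussian product-kernel density of the sample positions, weighted by a
#' taxon's abundances, on a shared g x g grid spanning the axis ranges
#' extended by 10% on each side. Bandwidths follow Silverman's rule of
#' thumb on the weighted samples (effective sample size
#' `(sum w)^2 / sum w^2`). Cell masses are normalized to sum to 1.
#'
#' @param scores n x 2 matrix of sample positions (e.g. the first two OMI
#'   axes).
#' @param weights non-negative abundances of one taxon over the samples
#'   (positive total).
#' @param grid number of grid points per axis.
#' @param expand range extension fraction per side.
#' @return a list of class `kernel_niche`: `x`, `y` (grid coordinates),
#'   `density` (g x g, sums to 1), `bandwidth`.
#' @export
kernel_niche <- function(scores, weights, grid = 100, expand = 0.1) {
  S <- as.matrix(scores)[, 1:2, drop = FALSE]
  stopifnot(length(weights) == nrow(S), all(weights >= 0))
  if (sum(weights) <= 0) stop("all-zero weights", call. = FALSE)
  w <- weights / sum(weights)
  n_eff <- 1 / sum(w^2)
  bw <- vapply(1:2, function(d) {
    mu <- sum(w * S[, d])
    sdw <- sqrt(sum(w * (S[, d] - mu)^2))
    h <- 1.06 * sdw * n_eff^(-1 / 5)
    # degenerate weighting (e.g. all mass on one sample): fall back to a
    # small fraction of the axis range so the density stays well defined
    spread <- diff(range(S[, d]))
    if (!is.finite(h) || h < 1e-6 * max(spread, 1)) {
      h <- max(0.05 * spread, 1e-6)
    }
    h
  }, numeric(1))
  gx <- .niche_grid(S[, 1], grid, expand)
  gy <- .niche_grid(S[, 2], grid, expand)
  Kx <- outer(gx, S[, 1], function(g, s) dnorm((g - s) / bw[1]))
  Ky <- outer(gy, S[, 2], function(g, s) dnorm((g - s) / bw[2]))
  dens <- Kx %*% (w * t(Ky))
  dens <- dens / sum(dens)
  structure(list(x = gx, y = gy, density = dens, bandwidth = bw),
            class = "kernel_niche")
}

.niche_grid <- function(v, grid, expand) {
  r <- range(v)
  pad <- expand * max(diff(r), 1e-9)
  seq(r[1] - pad, r[2] + pad, length.out = grid)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - sum|p_a - p_b| / 2` over the shared grid cells; 1 for identical
#' niches, 0 for disjoint ones.
#'
#' @param a,b [kernel_niche()] objects on identical grids.
#' @return the overlap in `[0, 1]`.
#' @export
schoener_d <- function(a, b) {
  if (!isTRUE(all.equal(a$x, b$x)) || !isTRUE(all.equal(a$y, b$y))) {
    stop("kernel niches are on different grids", call. = FALSE)
  }
  1 - sum(abs(a$density - b$density)) / 2
}

#' Pairwise niche-overlap matrix
#'
#' Schoener's D for every pair of kernel niches, plus an average-linkage
#' leaf ordering on `1 - D` for heatmap display.
#'
#' @param niches named list of [kernel_niche()] objects on a shared grid.
#' @return a list of class `overlap_matrix`: `D` (symmetric, unit
#'   diagonal), `order` (leaf order), `hclust`.
#' @export
overlap_matrix <- function(niches) {
  n <- length(niches)
  if (n < 2) stop("need at least two niches", call. = FALSE)
  ids <- names(niches)
  if (is.null(ids)) ids <- paste0("taxon", seq_len(n))
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- schoener_d(niches[[i]], niches[[j]])
    }
  }
  hc <- hclust(as.dist(1 - D), method = "average")
  structure(list(D = D, order = ids[hc$order], hclust = hc),
            class = "overlap_matrix")
}
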