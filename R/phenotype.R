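# Phenotype statistics: pairwise rank tests between ribotypes, range
# standardization, Bray-Curtis distances, principal coordinate analysis and
# descriptor fitting onto ordination axes.

#' Pairwise Mann-Whitney tests between groups
#'
#' Two-sided Wilcoxon rank-sum tests on `log(x + 1)` transformed values for
#' every pair of groups, using the tie-corrected normal approximation.
#' Raw and Holm-adjusted p values are both reported.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels (e.g. ribotypes), same length as `values`.
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @return data frame with `group_a`, `group_b`, `p`, `p_adjusted`.
#' @export
pairwise_group_tests <- function(values, groups, adjust = "holm") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  empty <- names(sizes)[sizes == 0]
  if (length(empty)) warning("skipping empty groups: ",
                             paste(empty, collapse = ", "), call. = FALSE)
  lv <- names(sizes)[sizes > 0]
  if (length(lv) < 2) stop("need at least two non-empty groups",
                           call. = FALSE)
  y <- log(values + 1)
  pairs <- combn(lv, 2)
  p <- apply(pairs, 2, function(gp) {
    suppressWarnings(
      wilcox.test(y[groups == gp[1]], y[groups == gp[2]],
                  exact = FALSE, correct = TRUE)$p.value)
  })
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], p = p,
             p_adjusted = p.adjust(p, method = adjust))
}

#' Range-standardize a matrix to [0, 1]
#'
#' Each column is rescaled as `(x - min) / (max - min)`.
#'
#' @param m numeric matrix or data frame with no constant column.
#' @return matrix with every column in `[0, 1]`.
#' @export
range_standardize <- function(m) {
  m <- as.matrix(m)
  rng <- apply(m, 2, range)
  const <- which(rng[2, ] - rng[1, ] == 0)
  if (length(const)) {
    nm <- colnames(m)[const[1]]
    stop("constant column cannot be range-standardized: ",
         if (is.null(nm)) const[1] else nm, call. = FALSE)
  }
  sweep(sweep(m, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
}

#' Bray-Curtis distance matrix
#'
#' `BC(i, j) = sum|x_ik - x_jk| / sum(x_ik + x_jk)` over descriptor columns.
#'
#' @param m non-negative matrix (rows = individuals) with no all-zero row.
#' @return symmetric distance matrix in `[0, 1]`.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative entries",
                       call. = FALSE)
  zero <- which(rowSums(m) == 0)
  if (length(zero)) stop("all-zero row: ", zero[1], call. = FALSE)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a distance matrix (Gower double-centering of
#' `-D^2/2`, eigen-decomposition, scores scaled by the square root of the
#' eigenvalues). Negative eigenvalues are dropped and their share of the
#' total absolute inertia reported.
#'
#' @param d symmetric distance matrix (n >= 2).
#' @return a list of class `pcoa_result`: `scores` (n x k), `eigenvalues`
#'   (positive, descending), `negative_inertia` (fraction in `[0, 1]`).
#' @export
pcoa <- function(d) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  # cmdscale warns when the doubly-centered matrix is rank deficient, which
  # is routine for semimetric distances; the dropped axes are reported via
  # negative_inertia instead
  fit <- suppressWarnings(cmdscale(as.dist(d), k = n - 1, eig = TRUE))
  ev <- fit$eig
  pos <- ev > sqrt(.Machine$double.eps) * max(abs(ev))
  scores <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  structure(list(scores = scores,
                 eigenvalues = ev[pos],
                 negative_inertia = sum(abs(ev[ev < 0])) / sum(abs(ev))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$scores), " points, ", ncol(x$scores),
      " axes; first two explain ",
      round(100 * sum(x$eigenvalues[1:min(2, length(x$eigenvalues))]) /
              sum(x$eigenvalues)),
      "% of positive inertia\n", sep = "")
  invisible(x)
}

#' Fit descriptors onto two ordination axes
#'
#' Least-squares fit of each (centered) descriptor on the first two
#' ordination axes: squared correlation `R^2 = 1 - RSS/TSS`, the fitted
#' direction as a unit coefficient vector, and a permutation p value
#' obtained by refitting row-permuted descriptors
#' (`p = (hits + 1) / (n_perm + 1)`).
#'
#' @param scores n x 2 matrix of sample scores.
#' @param descriptors n x p matrix or data frame of descriptors (no
#'   constant column).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return data frame with `descriptor`, `r2`, `dir1`, `dir2`, `p`.
#' @export
envfit_axes <- function(scores, descriptors, n_perm = 999, seed = 1) {
  S <- as.matrix(scores)[, 1:2, drop = FALSE]
  X <- as.matrix(descriptors)
  stopifnot(nrow(S) == nrow(X))
  S <- scale(S, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(S))  # orthonormal basis of the (centered) axis space
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(nrow(X)))
  out <- lapply(seq_len(ncol(X)), function(k) {
    y <- X[, k] - mean(X[, k])
    tss <- sum(y^2)
    if (tss == 0) {
      nm <- colnames(X)[k]
      stop("constant descriptor: ", if (is.null(nm)) k else nm,
           call. = FALSE)
    }
    r2_of <- function(yy) sum(crossprod(Q, yy)^2) / tss
    r2 <- r2_of(y)
    coefs <- qr.coef(qr(S), y)
    dir <- coefs / sqrt(sum(coefs^2))
    hits <- sum(apply(perms, 2, function(pm) r2_of(y[pm])) >= r2)
    data.frame(descriptor = if (is.null(colnames(X))) paste0("d", k)
               else colnames(X)[k],
               r2 = r2, dir1 = dir[1], dir2 = dir[2],
               p = (hits + 1) / (n_perm + 1))
  })
  do.call(rbind, out)
}
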