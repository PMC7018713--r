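# Distances on aligned 12-letter rows, neighbor-joining trees, and
# bootstrap support from alignment-column resampling.

#' Jukes-Cantor distance on the 12-letter alphabet
#'
#' Evolutionary distance between two aligned rows under a 12-state
#' Jukes-Cantor model: with `p` the fraction of differing letters over the
#' columns where both rows are ungapped,
#' `d = -(11/12) * log(1 - (12/11) * p)`.
#'
#' @param row_a,row_b integer code vectors of two aligned rows (0 = gap), or
#'   an `ss_alignment` plus two row indices/ids via `aln`, `i`, `j`.
#' @return the corrected distance (>= `p`); errors at saturation
#'   (`p >= 11/12`).
#' @export
jc12_distance <- function(row_a, row_b) {
  keep <- row_a != 0L & row_b != 0L
  if (!any(keep)) stop("no shared ungapped columns", call. = FALSE)
  p <- mean(row_a[keep] != row_b[keep])
  if (p >= 11 / 12) {
    stop("distance saturated (p = ", signif(p, 4),
         " >= 11/12); Jukes-Cantor correction undefined", call. = FALSE)
  }
  -(11 / 12) * log(1 - (12 / 11) * p)
}

#' Percent pairwise sequence identity
#'
#' Identity of two aligned rows computed on nucleotides only (the structural
#' state of the 12-letter code is ignored), over columns where both rows are
#' ungapped.
#'
#' @inheritParams jc12_distance
#' @return identity in percent.
#' @export
pairwise_identity <- function(row_a, row_b) {
  keep <- row_a != 0L & row_b != 0L
  if (!any(keep)) stop("no shared ungapped columns", call. = FALSE)
  100 * mean(.code_nt(row_a[keep]) == .code_nt(row_b[keep]))
}

#' All-pairs JC12 distance matrix of an alignment
#'
#' @param aln an `ss_alignment`.
#' @return a symmetric numeric matrix with row/column names from the
#'   alignment ids.
#' @export
aln_distance_matrix <- function(aln) {
  n <- nrow(aln$rows)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- jc12_distance(aln$rows[i, ], aln$rows[j, ])
    }
  }
  D
}

.check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration on a distance matrix. Negative
#' branch lengths produced by the algorithm are clamped to zero; the number
#' of clamped edges is recorded in the `n_clamped` attribute. On an additive
#' matrix the tree's path metric reproduces the input distances exactly.
#'
#' @param d a symmetric non-negative distance matrix (>= 3 taxa).
#' @return an [ape::nj()] style `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- .check_distance_matrix(d)
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 taxa",
                        call. = FALSE)
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

#' Bootstrap support for the alignment NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the JC12
#' distance matrix and NJ tree for each replicate, and maps bipartition
#' frequencies (in percent) onto the point-estimate tree.
#'
#' @param aln an `ss_alignment` with at least 4 rows.
#' @param n number of bootstrap replicates.
#' @param seed integer seed controlling column resampling.
#' @return the NJ tree with `node.label` set to support values in `[0, 100]`
#'   (root label `NA`).
#' @export
bootstrap_support <- function(aln, n = 100, seed = 1) {
  if (nrow(aln$rows) < 4) stop("need at least 4 taxa", call. = FALSE)
  build <- function(mat) {
    m <- nrow(mat)
    D <- matrix(0, m, m, dimnames = list(rownames(mat), rownames(mat)))
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        D[i, j] <- D[j, i] <- jc12_distance(mat[i, ], mat[j, ])
      }
    }
    nj_tree(D)
  }
  mat <- aln$rows
  rownames(mat) <- aln$ids
  phy <- build(mat)
  set.seed(seed)
  counts <- ape::boot.phylo(phy, mat, build, B = n, rooted = FALSE,
                            quiet = TRUE)
  phy$node.label <- 100 * counts / n
  phy$node.label[1] <- NA  # root of the unrooted representation
  phy
}
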