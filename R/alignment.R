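# Simultaneous sequence-structure alignment on the 12-letter alphabet:
# affine-gap pairwise alignment and guide-tree progressive multiple
# alignment ("once a gap, always a gap").

#' Sequence-structure scoring scheme
#'
#' Builds the 12 x 12 substitution matrix used for sequence-structure
#' alignment. The default is additive: a nucleotide component (+2 match, -1
#' mismatch) plus a structural-state component (+2 match, -2 mismatch), so
#' two identical letters score +4 and e.g. an `A`-open against `A`-unpaired
#' scores 0. A full custom 12 x 12 matrix may be supplied instead.
#'
#' @param nt_match,nt_mismatch nucleotide component scores.
#' @param st_match,st_mismatch structural-state component scores.
#' @param gap_open score of the first gapped position (must be `<=
#'   gap_extend`).
#' @param gap_extend score of each further gapped position (`<= 0`).
#' @param matrix optional symmetric 12 x 12 matrix overriding the additive
#'   construction; rows/columns follow the alphabet order
#'   `a c g u A C G U b d h v`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(nt_match = 2, nt_mismatch = -1,
                           st_match = 2, st_mismatch = -2,
                           gap_open = -8, gap_extend = -2,
                           matrix = NULL) {
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("need gap_open <= gap_extend <= 0", call. = FALSE)
  }
  if (is.null(matrix)) {
    S <- base::matrix(0, 12, 12, dimnames = list(RIBO_ALPHABET, RIBO_ALPHABET))
    for (i in 1:12) {
      for (j in 1:12) {
        nt_i <- (i - 1) %% 4; nt_j <- (j - 1) %% 4
        st_i <- (i - 1) %/% 4; st_j <- (j - 1) %/% 4
        S[i, j] <- (if (nt_i == nt_j) nt_match else nt_mismatch) +
          (if (st_i == st_j) st_match else st_mismatch)
      }
    }
  } else {
    S <- matrix
    stopifnot(is.matrix(S), nrow(S) == 12, ncol(S) == 12)
    if (max(abs(S - t(S))) > 1e-12) {
      stop("scoring matrix must be symmetric", call. = FALSE)
    }
    dimnames(S) <- list(RIBO_ALPHABET, RIBO_ALPHABET)
  }
  structure(list(matrix = S, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# 13 x 13 extension of the scoring matrix used for profile columns:
# letter-vs-gap inside a column contributes gap_extend, gap-vs-gap 0.
.scheme_ext <- function(scheme) {
  S13 <- base::matrix(scheme$gap_extend, 13, 13)
  S13[1:12, 1:12] <- scheme$matrix
  S13[13, 13] <- 0
  S13
}

.as_encoded <- function(x) {
  if (inherits(x, "structured_seq")) x <- encode12(x)
  stopifnot(inherits(x, "encoded_seq"))
  x
}

.new_alignment <- function(rows, ids, scheme) {
  rownames(rows) <- ids
  keep <- colSums(rows != 0L) > 0L
  rows <- rows[, keep, drop = FALSE]
  structure(list(rows = rows, ids = ids, scheme = scheme),
            class = "ss_alignment")
}

#' Global pairwise sequence-structure alignment
#'
#' Needleman-Wunsch/Gotoh global alignment of two 12-letter encoded
#' sequences with affine gap costs, maximizing the total score under the
#' scheme. Traceback ties are broken deterministically (diagonal, then up).
#'
#' @param a,b [encode12()] encoded sequences (or [structured_seq()] objects,
#'   which are encoded on the fly).
#' @param scheme a [scoring_scheme()].
#' @return an `ss_alignment` with two rows and a `score` attribute.
#' @export
align_pair <- function(a, b, scheme = scoring_scheme()) {
  a <- .as_encoded(a); b <- .as_encoded(b)
  if (!length(a$codes) || !length(b$codes)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  res <- .gotoh_pair(a$codes, b$codes, scheme$matrix,
                     scheme$gap_open, scheme$gap_extend)
  rows <- rbind(ifelse(res$a > 0L, a$codes[pmax(res$a, 1L)], 0L),
                ifelse(res$b > 0L, b$codes[pmax(res$b, 1L)], 0L))
  aln <- .new_alignment(rows, c(a$id, b$id), scheme)
  attr(aln, "score") <- res$score
  aln
}

.profile_freq <- function(mat) {
  L <- ncol(mat)
  f <- base::matrix(0, L, 13)
  for (k in 1:12) f[, k] <- colMeans(mat == k)
  f[, 13] <- colMeans(mat == 0L)
  f
}

.merge_profiles <- function(A, B, scheme, S13) {
  res <- .gotoh_profile(.profile_freq(A), .profile_freq(B), S13,
                        scheme$gap_open, scheme$gap_extend)
  L <- length(res$a)
  out <- base::matrix(0L, nrow(A) + nrow(B), L)
  sel <- res$a > 0L
  out[seq_len(nrow(A)), sel] <- A[, res$a[sel], drop = FALSE]
  sel <- res$b > 0L
  out[nrow(A) + seq_len(nrow(B)), sel] <- B[, res$b[sel], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple sequence-structure alignment
#'
#' Aligns two or more encoded sequences progressively: pairwise alignment
#' scores give normalized distances, a neighbor-joining guide tree is built,
#' and profiles are merged leaf-to-root under a "once a gap, always a gap"
#' rule. Sequences are processed in a canonical (identifier-sorted) order so
#' that the column content of the result does not depend on input order; the
#' returned rows follow the input order.
#'
#' @param seqs a list of [encode12()] encoded (or [structured_seq()])
#'   sequences with unique ids.
#' @param scheme a [scoring_scheme()].
#' @return an `ss_alignment`.
#' @export
align_progressive <- function(seqs, scheme = scoring_scheme()) {
  seqs <- lapply(seqs, .as_encoded)
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  ord <- order(ids)
  seqs <- seqs[ord]
  sids <- ids[ord]
  n <- length(seqs)

  if (n == 2L) {
    aln <- align_pair(seqs[[1]], seqs[[2]], scheme)
    return(.new_alignment(aln$rows[match(ids, sids), , drop = FALSE],
                          ids, scheme))
  }

  # guide distances from pairwise alignment scores
  self <- vapply(seqs, function(s) {
    sum(scheme$matrix[cbind(s$codes, s$codes)])
  }, numeric(1))
  D <- base::matrix(0, n, n, dimnames = list(sids, sids))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- .gotoh_pair(seqs[[i]]$codes, seqs[[j]]$codes, scheme$matrix,
                       scheme$gap_open, scheme$gap_extend)$score
      D[i, j] <- D[j, i] <- max(0, 1 - s / max(min(self[i], self[j]), 1e-9))
    }
  }

  S13 <- .scheme_ext(scheme)
  profile_of <- function(node, edge) {
    if (node <= n) {
      p <- base::matrix(seqs[[node]]$codes, 1)
      rownames(p) <- sids[node]
      return(p)
    }
    kids <- edge[edge[, 1] == node, 2]
    profs <- lapply(kids, profile_of, edge = edge)
    Reduce(function(A, B) .merge_profiles(A, B, scheme, S13), profs)
  }

  tree <- ape::nj(as.dist(D))
  rows <- profile_of(n + 1L, tree$edge)
  rows <- rows[match(ids, rownames(rows)), , drop = FALSE]
  .new_alignment(rows, ids, scheme)
}

#' @export
print.ss_alignment <- function(x, ...) {
  cat("<ss_alignment> ", nrow(x$rows), " sequences x ", ncol(x$rows),
      " columns\n", sep = "")
  strs <- alignment_strings(x)
  show <- head(seq_along(strs), 10L)
  for (i in show) cat(format(x$ids[i], width = 12), strs[i], "\n")
  if (length(strs) > 10L) cat("  ... and", length(strs) - 10L, "more\n")
  invisible(x)
}

#' Gapped display strings of an alignment
#'
#' @param aln an `ss_alignment`.
#' @return character vector of gapped 12-letter strings (`-` for gaps).
#' @export
alignment_strings <- function(aln) {
  apply(aln$rows, 1, function(r) {
    paste(ifelse(r == 0L, "-", RIBO_ALPHABET[pmax(r, 1L)]), collapse = "")
  })
}

#' Score of an aligned row pair under a scheme
#'
#' Scores two rows of a multiple alignment as aligned: columns where both
#' rows are gapped are skipped, runs of single-row gaps incur affine
#' penalties, other columns score by the substitution matrix. Used to check
#' how much of the optimal pairwise score a progressive alignment retains.
#'
#' @param aln an `ss_alignment`.
#' @param i,j row indices or ids.
#' @param scheme a [scoring_scheme()]; defaults to the alignment's own.
#' @return numeric score.
#' @export
alignment_pair_score <- function(aln, i, j, scheme = aln$scheme) {
  if (is.character(i)) i <- match(i, aln$ids)
  if (is.character(j)) j <- match(j, aln$ids)
  a <- aln$rows[i, ]; b <- aln$rows[j, ]
  keep <- !(a == 0L & b == 0L)
  a <- a[keep]; b <- b[keep]
  score <- 0
  in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == 0L || b[k] == 0L) {
      score <- score + if (in_gap) scheme$gap_extend else scheme$gap_open
      in_gap <- TRUE
    } else {
      score <- score + scheme$matrix[a[k], b[k]]
      in_gap <- FALSE
    }
  }
  score
}

# Per-row pair tables in alignment column space: for row r, partner[c] is the
# column paired with column c in that row's own structure (NA if unpaired or
# gapped).
.alignment_pair_tables <- function(aln) {
  lapply(seq_len(nrow(aln$rows)), function(r) {
    codes <- aln$rows[r, ]
    cols <- which(codes != 0L)
    state <- .code_state(codes[cols])
    db <- c(".", "(", ")")[state + 1L]
    partner_pos <- parse_dotbracket(paste(db, collapse = ""))
    partner_col <- rep(NA_integer_, length(codes))
    partner_col[cols] <- ifelse(is.na(partner_pos), NA_integer_,
                                cols[partner_pos])
    partner_col
  })
}
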