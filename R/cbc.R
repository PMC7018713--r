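# Compensatory base change (CBC) counting on aligned sequence-structure
# rows, the all-pairs CBC matrix, and the zero-CBC species partition.

.CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Count compensatory base changes between two aligned rows
#'
#' A column couple `(c1, c2)` is comparable when *both* sequences pair
#' column `c1` with column `c2` in their own secondary structures. Among
#' comparable couples where both sequences form a canonical pair (Watson-
#' Crick or G-U wobble): if both nucleotides differ the couple is a CBC
#' (e.g. `A-U` to `G-C`); if exactly one differs it is a hemi-CBC (e.g.
#' `G-C` to `G-U`). Comparable couples where either side is non-canonical
#' are skipped and reported as `disrupted`.
#'
#' @param aln an `ss_alignment`.
#' @param i,j row indices or ids.
#' @return a list with integer counts `cbc`, `hemi`, `disrupted` and
#'   `comparable` (number of comparable couples).
#' @export
count_cbc <- function(aln, i, j) {
  if (is.character(i)) i <- match(i, aln$ids)
  if (is.character(j)) j <- match(j, aln$ids)
  tabs <- .alignment_pair_tables(aln)
  .count_cbc_rows(aln$rows[i, ], aln$rows[j, ], tabs[[i]], tabs[[j]])
}

.count_cbc_rows <- function(row_a, row_b, partner_a, partner_b) {
  cbc <- hemi <- disrupted <- comparable <- 0L
  cols <- which(!is.na(partner_a) & partner_a > seq_along(partner_a))
  for (c1 in cols) {
    c2 <- partner_a[c1]
    if (is.na(partner_b[c1]) || partner_b[c1] != c2) next
    comparable <- comparable + 1L
    a1 <- RIBO_NT[.code_nt(row_a[c1])]; a2 <- RIBO_NT[.code_nt(row_a[c2])]
    b1 <- RIBO_NT[.code_nt(row_b[c1])]; b2 <- RIBO_NT[.code_nt(row_b[c2])]
    if (!(paste0(a1, a2) %in% .CANONICAL_PAIRS &&
          paste0(b1, b2) %in% .CANONICAL_PAIRS)) {
      disrupted <- disrupted + 1L
      next
    }
    ndiff <- (a1 != b1) + (a2 != b2)
    if (ndiff == 2L) cbc <- cbc + 1L
    else if (ndiff == 1L) hemi <- hemi + 1L
  }
  list(cbc = cbc, hemi = hemi, disrupted = disrupted, comparable = comparable)
}

#' CBC matrix of a multiple alignment
#'
#' Counts CBCs (and, separately, hemi-CBCs) between every unordered pair of
#' rows of a sequence-structure alignment.
#'
#' @param aln an `ss_alignment` with at least 2 rows.
#' @return a list of class `cbc_matrix`: `cbc` and `hemi` symmetric integer
#'   matrices with zero diagonals, named by the alignment ids.
#' @export
cbc_matrix <- function(aln) {
  n <- nrow(aln$rows)
  if (n < 2) stop("need at least two rows", call. = FALSE)
  tabs <- .alignment_pair_tables(aln)
  cbc <- hemi <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ct <- .count_cbc_rows(aln$rows[i, ], aln$rows[j, ],
                            tabs[[i]], tabs[[j]])
      cbc[i, j] <- cbc[j, i] <- ct$cbc
      hemi[i, j] <- hemi[j, i] <- ct$hemi
    }
  }
  structure(list(cbc = cbc, hemi = hemi, taxa = aln$ids),
            class = "cbc_matrix")
}

#' @export
print.cbc_matrix <- function(x, ...) {
  cat("<cbc_matrix> ", length(x$taxa), " taxa; CBC range ",
      min(x$cbc[upper.tri(x$cbc)]), "-", max(x$cbc[upper.tri(x$cbc)]),
      "\n", sep = "")
  invisible(x)
}

#' Species partition from a CBC matrix
#'
#' Two taxa are called conspecific when they show zero CBCs; the species
#' partition is the set of connected components of the zero-CBC graph.
#' Non-transitive zero patterns (`i~j`, `j~k`, but `cbc(i,k) > 0`) end up in
#' one component and are reported as conflicts.
#'
#' @param m a [cbc_matrix()] (or a plain symmetric CBC count matrix).
#' @return a list of class `species_partition`: `species` (named integer
#'   membership vector), `n_species`, and `conflicts` (data frame of
#'   within-component pairs with positive CBC counts).
#' @export
delineate_species <- function(m) {
  cbc <- if (inherits(m, "cbc_matrix")) m$cbc else .check_distance_matrix(m)
  n <- nrow(cbc)
  taxa <- rownames(cbc)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  # union-find over the zero-CBC graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (cbc[i, j] == 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  species <- match(roots, sort(unique(roots)))
  names(species) <- taxa
  conflicts <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (species[i] == species[j] && cbc[i, j] > 0) {
        conflicts <- rbind(conflicts,
                           data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                                      cbc = cbc[i, j]))
      }
    }
  }
  if (is.null(conflicts)) {
    conflicts <- data.frame(taxon_a = character(), taxon_b = character(),
                            cbc = integer())
  }
  structure(list(species = species, n_species = max(species),
                 conflicts = conflicts),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("<species_partition> ", x$n_species, " species over ",
      length(x$species), " taxa; ", nrow(x$conflicts),
      " zero-CBC conflicts\n", sep = "")
  invisible(x)
}
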