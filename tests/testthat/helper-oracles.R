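# Independent oracles and small generators used across the test suite.
# Everything here is deliberately written without reusing the package's
# internal code paths.

# plain-R Gotoh dynamic programme, scores only (three full matrices)
oracle_align_score <- function(a, b, S, go, ge) {
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- go + (i - 1) * ge
  for (j in seq_len(m)) Y[1, j + 1] <- go + (j - 1) * ge
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- S[a[i], b[j]] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] + go, X[i, j + 1] + ge,
                             Y[i, j + 1] + go)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go, Y[i + 1, j] + ge,
                             X[i + 1, j] + go)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force CBC/hemi-CBC counter working directly on nucleotide and
# dot-bracket character vectors of two equally long (unaligned) rows
oracle_count_cbc <- function(nt_a, db_a, nt_b, db_b) {
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  pair_table <- function(db) {
    partner <- rep(NA_integer_, length(db))
    stack <- integer(0)
    for (i in seq_along(db)) {
      if (db[i] == "(") stack <- c(stack, i)
      if (db[i] == ")") {
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        partner[i] <- j; partner[j] <- i
      }
    }
    partner
  }
  pa <- pair_table(db_a); pb <- pair_table(db_b)
  cbc <- hemi <- 0L
  for (c1 in seq_along(db_a)) {
    c2 <- pa[c1]
    if (is.na(c2) || c2 <= c1) next
    if (is.na(pb[c1]) || pb[c1] != c2) next
    if (!(paste0(nt_a[c1], nt_a[c2]) %in% canon)) next
    if (!(paste0(nt_b[c1], nt_b[c2]) %in% canon)) next
    nd <- (nt_a[c1] != nt_b[c1]) + (nt_a[c2] != nt_b[c2])
    if (nd == 2) cbc <- cbc + 1L
    if (nd == 1) hemi <- hemi + 1L
  }
  list(cbc = cbc, hemi = hemi)
}

# length-safe single draw (sample() treats a scalar as 1:n)
pick1 <- function(v) v[sample.int(length(v), 1)]

# random nested dot-bracket structure of length L with ~n_pairs pairs
random_structure <- function(L, n_pairs) {
  db <- rep(".", L)
  placed <- 0
  guard <- 0
  while (placed < n_pairs && guard < 200) {
    guard <- guard + 1
    free <- which(db == ".")
    if (length(free) < 2) break
    i <- pick1(free)
    right <- free[free > i]
    # keep nesting: the enclosed segment must itself be balanced at every
    # prefix (no pair may straddle the new one)
    right <- right[vapply(right, function(j) {
      if (j == i + 1) return(TRUE)
      seg <- db[(i + 1):(j - 1)]
      depth <- cumsum((seg == "(") - (seg == ")"))
      all(depth >= 0) && depth[length(depth)] == 0
    }, logical(1))]
    if (!length(right)) next
    j <- pick1(right)
    db[i] <- "("; db[j] <- ")"
    placed <- placed + 1
  }
  paste(db, collapse = "")
}

# a pair of random structured sequences sharing length; structure b is a
# with some couples unpaired, nucleotides arbitrary (canonical pairs with
# probability p_canon on each side)
random_structured_pair <- function(L = 60, n_pairs = 12, p_canon = 0.7) {
  db_a <- random_structure(L, n_pairs)
  db_b_chars <- strsplit(db_a, "")[[1]]
  # unpair ~20% of couples in b
  partner <- ribodelim::parse_dotbracket(db_a)
  opens <- which(db_b_chars == "(")
  drop <- opens[runif(length(opens)) < 0.2]
  for (i in drop) { db_b_chars[i] <- "."; db_b_chars[partner[i]] <- "." }
  db_b <- paste(db_b_chars, collapse = "")
  rand_seq <- function(db) {
    nt <- sample(c("A", "C", "G", "U"), nchar(db), replace = TRUE)
    part <- ribodelim::parse_dotbracket(db)
    canon <- c(A = "U", U = "A", G = "C", C = "G")
    for (i in which(!is.na(part) & part > seq_along(part))) {
      if (runif(1) < 0.7) nt[part[i]] <- canon[nt[i]]  # canonical partner
    }
    nt
  }
  list(nt_a = rand_seq(db_a), db_a = db_a,
       nt_b = rand_seq(db_b), db_b = db_b)
}

# random additive distance matrix from a random binary tree with positive
# branch lengths, plus the generating tree
random_additive <- function(n_taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = cophenetic(tr))
}

# gapless structured-seq pair -> two-row alignment without going through
# the aligner (rows are already positionally homologous)
as_fixed_alignment <- function(seq_list) {
  enc <- lapply(seq_list, ribodelim::encode12)
  rows <- do.call(rbind, lapply(enc, `[[`, "codes"))
  rownames(rows) <- vapply(enc, `[[`, character(1), "id")
  structure(list(rows = rows,
                 ids = rownames(rows),
                 scheme = ribodelim::scoring_scheme()),
            class = "ss_alignment")
}

# adjusted Rand index against a reference labeling
ari <- function(a, b) mclust::adjustedRandIndex(a, b[names(a)])

# exact partition equality (same co-membership structure), robust to label
# names and to all-singleton partitions where the ARI is undefined
same_partition <- function(a, b) {
  ids <- sort(names(a))
  if (!identical(ids, sort(names(b)))) return(FALSE)
  ca <- outer(a[ids], a[ids], "==")
  cb <- outer(b[ids], b[ids], "==")
  all(ca == cb)
}
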