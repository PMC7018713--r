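# Alignment-free genome comparison: read filtering, canonical k-mer sets,
# binary-association distances and average-linkage clustering with
# bootstrap Jaccard stability.

#' Read filtering parameters
#'
#' Defaults follow the presence/absence k-mer comparison protocol: k = 21,
#' minimum read length 90 bp, and a mononucleotide Shannon-entropy cutoff of
#' 1.5 bits below which low-complexity reads are discarded.
#'
#' @param min_len minimum read length in bases.
#' @param min_entropy minimum mononucleotide Shannon entropy in bits
#'   (in `[0, 2]`).
#' @param k k-mer size in bases (`k <= min_len`).
#' @return a list of class `read_filter_params`.
#' @export
read_filter_params <- function(min_len = 90, min_entropy = 1.5, k = 21) {
  stopifnot(k >= 1, min_len >= 1, min_entropy >= 0, min_entropy <= 2)
  if (k > min_len) stop("k must not exceed min_len", call. = FALSE)
  structure(list(min_len = min_len, min_entropy = min_entropy, k = k),
            class = "read_filter_params")
}

#' Mononucleotide Shannon entropy of reads
#'
#' `H = -sum(f_b * log2(f_b))` over the observed A/C/G/T(/U) frequencies of
#' each read; `N`s are ignored in the frequencies.
#'
#' @param reads character vector of reads.
#' @return numeric vector of entropies in bits.
#' @export
read_entropy <- function(reads) {
  vapply(reads, function(r) {
    b <- strsplit(toupper(r), "", fixed = TRUE)[[1]]
    b <- b[b != "N"]
    if (!length(b)) return(0)
    f <- table(b) / length(b)
    -sum(f * log2(f))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads by length and complexity
#'
#' Retains reads of length `>= min_len` whose mononucleotide Shannon entropy
#' is `>= min_entropy` bits.
#'
#' @param reads character vector over `A`, `C`, `G`, `T`, `N`.
#' @param params a [read_filter_params()].
#' @return the retained reads.
#' @export
filter_reads <- function(reads, params = read_filter_params()) {
  keep <- nchar(reads) >= params$min_len &
    read_entropy(reads) >= params$min_entropy
  reads[keep]
}

#' Canonical form of k-mers
#'
#' The canonical form is the lexicographic minimum of a k-mer and its
#' reverse complement, making k-mer sets strand-neutral.
#'
#' @param kmers character vector of k-mers over `A`, `C`, `G`, `T`.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", kmers), "", fixed = TRUE),
               function(x) paste(rev(x), collapse = ""), character(1))
  ifelse(kmers <= rc, kmers, rc)
}

#' Canonical k-mer set of a collection of reads
#'
#' Extracts every length-`k` window of each read, skipping windows that
#' contain `N` (and reads shorter than `k`), and stores the canonical form
#' of each window as a presence/absence set.
#'
#' @param reads character vector of (filtered) reads.
#' @param k k-mer size.
#' @param strain_id identifier for the resulting profile.
#' @return a list of class `kmer_profile` with `strain_id`, sorted unique
#'   `kmers`, and `k`.
#' @export
kmer_profile <- function(reads, k = 21, strain_id = "strain") {
  reads <- toupper(reads[nchar(reads) >= k])
  kmers <- character(0)
  if (length(reads)) {
    all <- unlist(lapply(reads, function(r) {
      n <- nchar(r)
      substring(r, 1:(n - k + 1), k:n)
    }))
    all <- all[!grepl("N", all, fixed = TRUE)]
    kmers <- sort(unique(canonical_kmer(unique(all))))
  }
  structure(list(strain_id = strain_id, kmers = kmers, k = k),
            class = "kmer_profile")
}

# wrap an already-canonical k-mer set (used by the simulator)
.kmer_profile_from_set <- function(kmers, k, strain_id) {
  structure(list(strain_id = strain_id, kmers = sort(unique(kmers)), k = k),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("<kmer_profile> ", x$strain_id, ": ", length(x$kmers), " canonical ",
      x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Binary-association distance between two k-mer profiles
#'
#' Presence/absence distances that weight the double presence of k-mers.
#' With `a = |A intersect B|`, `b = |A \ B|`, `c = |B \ A|`:
#' * Kulczynski: `1 - (a/(a+b) + a/(a+c)) / 2`
#' * Ochiai: `1 - a / sqrt((a+b) * (a+c))`
#' * Chord (= Hellinger on presence/absence): `sqrt(2 * (1 - a / sqrt((a+b) * (a+c))))`
#'
#' @param a,b [kmer_profile()] objects with the same `k`.
#' @param metric one of `"kulczynski"`, `"ochiai"`, `"chord"`.
#' @return the distance (Kulczynski/Ochiai in `[0, 1]`, Chord in
#'   `[0, sqrt(2)]`).
#' @export
binary_distance <- function(a, b, metric = c("kulczynski", "ochiai", "chord")) {
  metric <- match.arg(metric)
  if (!length(a$kmers) || !length(b$kmers)) {
    stop("empty k-mer profile: ",
         if (!length(a$kmers)) a$strain_id else b$strain_id, call. = FALSE)
  }
  if (a$k != b$k) stop("profiles have different k", call. = FALSE)
  n_a <- length(a$kmers); n_b <- length(b$kmers)
  n_ab <- length(intersect(a$kmers, b$kmers))
  ochiai_sim <- n_ab / sqrt(n_a * n_b)
  switch(metric,
         kulczynski = 1 - (n_ab / n_a + n_ab / n_b) / 2,
         ochiai = 1 - ochiai_sim,
         chord = sqrt(2 * (1 - ochiai_sim)))
}

#' All-pairs k-mer distance matrix
#'
#' @param profiles list of [kmer_profile()] objects with a uniform `k`.
#' @param metric as in [binary_distance()].
#' @return symmetric distance matrix named by strain ids.
#' @export
kmer_distance_matrix <- function(profiles, metric = "kulczynski") {
  n <- length(profiles)
  if (n < 2) stop("need at least two profiles", call. = FALSE)
  ids <- vapply(profiles, `[[`, character(1), "strain_id")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- binary_distance(profiles[[i]], profiles[[j]],
                                            metric)
    }
  }
  D
}

#' Hierarchical clustering with bootstrap Jaccard stability
#'
#' Clusters a distance matrix by hierarchical agglomeration cut at `K`
#' groups, then assesses cluster stability: in each bootstrap replicate the
#' individuals are resampled with replacement, the induced distance
#' submatrix is reclustered, and every original cluster is scored by its
#' maximum Jaccard overlap with the replicate clusters (computed on the
#' resampled multiset; clusters absent from a replicate score 0). Stability
#' is the mean over replicates.
#'
#' @param d symmetric distance matrix.
#' @param K number of clusters (`>= 2`).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed for resampling.
#' @param linkage `hclust` agglomeration method (`"average"`, `"single"`,
#'   `"complete"`).
#' @return a list of class `cluster_stability`: `assignment` (named
#'   membership vector), `stability` (per-cluster mean Jaccard in `[0, 1]`),
#'   `n_boot`, `linkage`.
#' @export
cluster_with_stability <- function(d, K, n_boot = 100, seed = 1,
                                   linkage = c("average", "single",
                                               "complete")) {
  linkage <- match.arg(linkage)
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (K > n) stop("K exceeds the number of individuals", call. = FALSE)
  assignment <- cutree(hclust(as.dist(d), method = linkage), k = K)
  names(assignment) <- rownames(d)

  set.seed(seed)
  jac <- matrix(0, n_boot, K)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- d[idx, idx]
    # duplicate individuals are distinct observations at distance 0
    new_lab <- cutree(hclust(as.dist(sub), method = linkage), k = K)
    orig_lab <- assignment[idx]
    for (cl in seq_len(K)) {
      in_orig <- orig_lab == cl
      if (!any(in_orig)) next  # cluster unrepresented: scores 0
      best <- 0
      for (nc in unique(new_lab)) {
        in_new <- new_lab == nc
        j <- sum(in_orig & in_new) / sum(in_orig | in_new)
        if (j > best) best <- j
      }
      jac[r, cl] <- best
    }
  }
  structure(list(assignment = assignment, stability = colMeans(jac),
                 n_boot = n_boot, linkage = linkage),
            class = "cluster_stability")
}

#' @export
print.cluster_stability <- function(x, ...) {
  cat("<cluster_stability> ", length(unique(x$assignment)), " clusters, ",
      x$n_boot, " bootstrap replicates (", x$linkage, " linkage)\n",
      "  mean Jaccard stability per cluster: ",
      paste(sprintf("%.2f", x$stability), collapse = " "), "\n", sep = "")
  invisible(x)
}
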