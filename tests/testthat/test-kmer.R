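# Read filtering, canonical k-mer sets, binary distances and cluster
# stability.

test_that("read filtering applies length and entropy rules", {
  p <- read_filter_params()
  expect_equal(filter_reads(strrep("A", 100), p), character(0))  # H = 0
  complex89 <- paste(rep(c("A", "C", "G", "T"), length.out = 89),
                     collapse = "")
  expect_equal(filter_reads(complex89, p), character(0))  # too short
  # two equifrequent bases: H = 1 bit < 1.5 -> discarded
  half <- paste(rep(c("A", "C"), 50), collapse = "")
  expect_equal(read_entropy(half), 1)
  expect_equal(filter_reads(half, p), character(0))
  keep <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  expect_equal(read_entropy(keep), 2)
  expect_equal(filter_reads(keep, p), keep)
})

test_that("k-mer extraction canonicalizes and skips N windows", {
  pr <- kmer_profile("ACGTA", k = 3)
  expect_setequal(pr$kmers, c("ACG", "GTA"))  # CGT canonicalizes to ACG
  expect_equal(length(kmer_profile("ANGT", k = 3)$kmers), 0)
  # palindromic k-mer is its own canonical form
  expect_equal(canonical_kmer("ACGT"), "ACGT")
  # idempotence
  set.seed(1)
  km <- replicate(50, paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                            collapse = ""))
  expect_equal(canonical_kmer(canonical_kmer(km)), canonical_kmer(km))
  # reads shorter than k are skipped
  expect_equal(length(kmer_profile("ACG", k = 21)$kmers), 0)
})

test_that("binary distances follow the set-algebra formulas", {
  A <- function(v, id) ribodelim:::.kmer_profile_from_set(v, 3, id)
  a <- A(c("AAA", "AAC", "AAG"), "a")
  b <- A(c("AAC", "AAG", "AAT"), "b")
  expect_equal(binary_distance(a, b, "kulczynski"), 1 / 3)
  expect_equal(binary_distance(a, b, "ochiai"), 1 / 3)
  expect_equal(binary_distance(a, b, "chord"), sqrt(2 / 3))
  expect_equal(binary_distance(a, a, "kulczynski"), 0)
  expect_equal(binary_distance(a, a, "chord"), 0)
  dis <- A(c("CCC", "CCA"), "d")
  expect_equal(binary_distance(a, dis, "kulczynski"), 1)
  expect_equal(binary_distance(a, dis, "ochiai"), 1)
  expect_equal(binary_distance(a, dis, "chord"), sqrt(2))
  empty <- A(character(0), "e")
  expect_error(binary_distance(a, empty), "empty")
})

test_that("distance matrix matches a naive double-loop oracle", {
  set.seed(33)
  pool <- replicate(400, paste(sample(c("A", "C", "G", "T"), 9,
                                      replace = TRUE), collapse = ""))
  pool <- unique(canonical_kmer(pool))
  profs <- lapply(1:20, function(i) {
    ribodelim:::.kmer_profile_from_set(sample(pool, 60), 9,
                                       paste0("s", i))
  })
  for (metric in c("kulczynski", "ochiai", "chord")) {
    D <- kmer_distance_matrix(profs, metric)
    for (i in 1:19) {
      for (j in (i + 1):20) {
        A <- profs[[i]]$kmers; B <- profs[[j]]$kmers
        a <- length(intersect(A, B))
        bb <- length(setdiff(A, B)); cc <- length(setdiff(B, A))
        exp <- switch(metric,
                      kulczynski = 1 - (a / (a + bb) + a / (a + cc)) / 2,
                      ochiai = 1 - a / sqrt((a + bb) * (a + cc)),
                      chord = sqrt(2 * (1 - a / sqrt((a + bb) * (a + cc)))))
        expect_equal(D[i, j], exp, tolerance = 1e-12)
        expect_equal(D[i, j], D[j, i])
      }
    }
  }
})

test_that("chord-ochiai relation and monotonicity under shared-element removal", {
  set.seed(8)
  for (rep in 1:50) {
    sets <- replicate(2, sample(letters, sample(5:20, 1)), simplify = FALSE)
    a <- ribodelim:::.kmer_profile_from_set(sets[[1]], 1, "a")
    b <- ribodelim:::.kmer_profile_from_set(sets[[2]], 1, "b")
    och <- binary_distance(a, b, "ochiai")
    expect_equal(binary_distance(a, b, "chord"), sqrt(2 * och),
                 tolerance = 1e-12)
    # removing a shared element never decreases any metric
    shared <- intersect(sets[[1]], sets[[2]])
    if (length(shared) > 1) {
      drop <- shared[1]
      a2 <- ribodelim:::.kmer_profile_from_set(setdiff(sets[[1]], drop), 1, "a")
      b2 <- ribodelim:::.kmer_profile_from_set(setdiff(sets[[2]], drop), 1, "b")
      for (m in c("kulczynski", "ochiai", "chord")) {
        expect_gte(binary_distance(a2, b2, m) + 1e-12,
                   binary_distance(a, b, m))
      }
    }
  }
})

test_that("cluster stability is perfect for well-separated groups", {
  set.seed(6)
  # two tight blobs far apart, as a distance matrix
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("i", 1:20), paste0("i", 1:20))
  st <- cluster_with_stability(D, K = 2, n_boot = 50, seed = 1)
  expect_equal(unname(st$stability), c(1, 1))
})

test_that("featureless random distances give unstable clusters", {
  set.seed(14)
  n <- 30
  D <- matrix(0, n, n, dimnames = list(paste0("i", 1:n), paste0("i", 1:n)))
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.5, 1)
  D <- D + t(D)
  st <- cluster_with_stability(D, K = 2, n_boot = 100, seed = 2)
  expect_lt(mean(st$stability), 0.7)
})

test_that("cluster stability rejects degenerate K", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(cluster_with_stability(D, K = 1), "at least 2")
  expect_error(cluster_with_stability(D, K = 5), "exceeds")
})
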