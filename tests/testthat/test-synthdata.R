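# The synthetic-data generators: planted truth, determinism, and the
# statistical features each downstream stage relies on.

test_that("planted CBC counts round-trip through the CBC counter", {
  planted <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  cfg <- synth_config(n_ribotypes = 2, strains_per_ribotype = 2,
                      planted_cbc = planted, seed = 42)
  ss <- simulate_ribotype_sequences(cfg)
  aln <- align_progressive(lapply(ss$sequences, encode12))
  m <- cbc_matrix(aln)
  ro <- ss$truth$ribotype_of_strain
  for (i in 1:3) {
    for (j in (i + 1):4) {
      ri <- match(ro[m$taxa[i]], cfg$ribotypes)
      rj <- match(ro[m$taxa[j]], cfg$ribotypes)
      expect_equal(m$cbc[i, j], planted[ri, rj])
    }
  }
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- synth_config(n_ribotypes = 3, strains_per_ribotype = 2,
                      planted_cbc = default_planted_cbc(3), seed = 99)
  s1 <- simulate_ribotype_sequences(cfg)
  s2 <- simulate_ribotype_sequences(cfg)
  f1 <- tempfile(); d1 <- tempfile(); f2 <- tempfile(); d2 <- tempfile()
  write_structured_fasta(s1$sequences, f1, d1)
  write_structured_fasta(s2$sequences, f2, d2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(d1), readLines(d2))
  expect_identical(simulate_kmer_profiles(cfg), simulate_kmer_profiles(cfg))
  expect_identical(simulate_community_series(cfg),
                   simulate_community_series(cfg))
  expect_identical(simulate_host_phenotype(cfg),
                   simulate_host_phenotype(cfg))
})

test_that("infeasible planted CBC matrices fail naming the ribotype pair", {
  planted <- matrix(9L, 3, 3); diag(planted) <- 0L
  cfg <- synth_config(n_ribotypes = 3, strains_per_ribotype = 1,
                      planted_cbc = planted, helix_pairs = c(3, 3, 3, 3),
                      seed = 1)
  expect_error(simulate_ribotype_sequences(cfg), "infeasible.*RIB")
})

test_that("within-ribotype CBC counts are zero by construction", {
  cfg <- synth_config(strains_per_ribotype = 3, seed = 17)
  ss <- simulate_ribotype_sequences(cfg)
  ro <- ss$truth$ribotype_of_strain
  # check strains of two ribotypes directly (positionally homologous)
  for (r in c("RIB1", "RIB5")) {
    ids <- names(ro)[ro == r]
    aln <- as_fixed_alignment(ss$sequences[ids])
    for (i in 1:(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        expect_equal(count_cbc(aln, i, j)$cbc, 0L)
      }
    }
  }
  # and every strain carries at most intra_snps substitutions
  expect_true(all(lengths(ss$truth$snps) <= cfg$intra_snps))
})

test_that("full core fraction makes within-ribotype k-mer distances zero", {
  cfg <- synth_config(n_ribotypes = 2, strains_per_ribotype = 3,
                      planted_cbc = default_planted_cbc(2),
                      kmer_core_fraction = 1, n_kmers = 200, seed = 8)
  km <- simulate_kmer_profiles(cfg)
  D <- kmer_distance_matrix(km$profiles)
  ro <- km$truth$ribotype_of_strain
  same <- outer(ro[rownames(D)], ro[colnames(D)], "==")
  expect_true(all(D[same & upper.tri(D)] == 0))
  expect_true(all(D[!same & upper.tri(D)] > 0.5))
})

test_that("planted k-mer clusters are recovered at core fraction 0.8", {
  cfg <- synth_config(n_kmers = 300, seed = 12)
  km <- simulate_kmer_profiles(cfg)
  D <- kmer_distance_matrix(km$profiles)
  lab <- cutree(hclust(as.dist(D), method = "average"), k = 8)
  expect_equal(ari(lab, km$truth$ribotype_of_strain), 1)
})

test_that("zero core fraction carries no cluster signal", {
  cfg <- synth_config(kmer_core_fraction = 0, n_kmers = 300, seed = 12)
  km <- simulate_kmer_profiles(cfg)
  D <- kmer_distance_matrix(km$profiles)
  lab <- cutree(hclust(as.dist(D), method = "average"), k = 8)
  truth <- km$truth$ribotype_of_strain
  obs <- ari(lab, truth)
  # permutation baseline for chance agreement
  set.seed(3)
  null <- replicate(200, {
    mclust::adjustedRandIndex(sample(lab), truth[names(lab)])
  })
  expect_lte(obs, quantile(null, 0.99) + 0.05)
})

test_that("between/within distance contrast grows with core fraction", {
  ratios <- vapply(c(0.2, 0.5, 0.8), function(f) {
    r <- vapply(1:3, function(s) {
      cfg <- synth_config(n_ribotypes = 3, strains_per_ribotype = 3,
                          planted_cbc = default_planted_cbc(3),
                          kmer_core_fraction = f, n_kmers = 200, seed = s)
      km <- simulate_kmer_profiles(cfg)
      D <- kmer_distance_matrix(km$profiles)
      ro <- km$truth$ribotype_of_strain
      same <- outer(ro[rownames(D)], ro[colnames(D)], "==")
      mean(D[!same & upper.tri(D)]) / mean(D[same & upper.tri(D)])
    }, numeric(1))
    mean(r)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("coverage tables encode the planted copies exactly without noise", {
  cfg <- synth_config(n_ribotypes = 2, strains_per_ribotype = 1,
                      planted_cbc = default_planted_cbc(2),
                      planted_copies = c(100, 250), coverage_depth = 10,
                      seed = 2)
  cov <- simulate_coverage_table(cfg, noise = "none")
  tab <- cov$table
  op <- tab[tab$feature == "operon" & tab$strain == cfg$strains[1], ]
  expect_equal(op$mean_coverage, 1000)
  genes <- select_reference_genes(tab, cfg$strains[1])
  expect_equal(mean(genes$mean_coverage), 10)
  expect_true(all(tolower(genes$flag) == "ok"))
  # flagged genes present but excluded
  expect_true(any(tab$flag != "ok"))
  est <- estimate_operon_copies(tab)
  expect_equal(est$copies, c(100, 250))
})

test_that("a flat niche response yields near-zero OMI", {
  cfg <- synth_config(n_taxa = 9, n_ribotypes = 8, strains_per_ribotype = 1,
                      niche_breadth = c(rep(0.3, 8), 1e6), seed = 30)
  com <- simulate_community_series(cfg)
  y <- hellinger(com$counts)
  om <- omi_analysis(y, com$env)
  flat <- om$taxa$omi[om$taxa$taxon == "BG01"]
  expect_lt(flat, 0.01)
  expect_gt(max(om$taxa$omi), 10 * flat)
})

test_that("taxa with identical planted niches have near-total overlap", {
  opt <- matrix(0.5, 10, 7)
  opt[, 1] <- c(0.3, 0.3, seq(0.2, 0.8, length.out = 8))  # taxa 1,2 identical
  cfg <- synth_config(n_ribotypes = 8, strains_per_ribotype = 1,
                      n_taxa = 10, niche_optima = opt,
                      peak_count = 800, seed = 31)
  com <- simulate_community_series(cfg)
  om <- omi_analysis(hellinger(com$counts), com$env)
  n1 <- kernel_niche(om$scores[, 1:2], com$counts[, 1])
  n2 <- kernel_niche(om$scores[, 1:2], com$counts[, 2])
  expect_gt(schoener_d(n1, n2), 0.9)
})

test_that("host tables follow the planted host-range classes", {
  cfg <- synth_config(seed = 4)
  hp <- simulate_host_phenotype(cfg)
  # every parasite strain infects every strain of the reference species
  ref_cols <- names(hp$species_of_host)[
    hp$species_of_host == "S.acuminata_STR1"]
  expect_true(all(hp$infection[, ref_cols] == 1))
  # ribotypes of class "1" infect exactly one host species
  hr <- host_range_class(hp$infection, hp$species_of_host,
                         ribotype_of_strain(cfg))
  cls <- hp$truth$host_classes
  expect_true(all(hr$ribotype_max[names(cls)[cls == "1"]] == 1))
  expect_true(all(hr$ribotype_max[names(cls)[cls == "4-5"]] %in% 4:5))
  expect_equal(unname(hr$ribotype_class[names(cls)]), unname(cls))
})
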