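# Pairwise rank tests, range standardization, Bray-Curtis, PCoA and
# descriptor fitting.

test_that("pairwise Mann-Whitney tests behave at the null and under shift", {
  set.seed(19)
  vals <- rnorm(60, 10, 1)
  groups <- rep(c("A", "B", "C"), each = 20)
  null_res <- pairwise_group_tests(vals, groups)
  expect_equal(nrow(null_res), 3)
  expect_true(all(null_res$p_adjusted > 0.01))
  # one group shifted by 10 SD
  vals2 <- vals
  vals2[groups == "C"] <- vals2[groups == "C"] + 10
  res <- pairwise_group_tests(vals2, groups)
  expect_true(all(res$p_adjusted[res$group_b == "C" |
                                   res$group_a == "C"] < 0.01))
  expect_gt(res$p_adjusted[res$group_a == "A" & res$group_b == "B"], 0.01)
})

test_that("rank tests are invariant to the monotone log transform", {
  set.seed(20)
  x <- rexp(15, 1 / 5); y <- rexp(15, 1 / 20)
  p_raw <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  got <- pairwise_group_tests(c(x, y), rep(c("a", "b"), each = 15))
  expect_equal(got$p, p_raw, tolerance = 1e-12)
})

test_that("range standardization maps columns to [0, 1] and is idempotent", {
  m <- cbind(a = c(2, 4, 6), b = c(0, 1, 0.5))
  s <- range_standardize(m)
  expect_equal(unname(s[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(s[, "b"]), c(0, 1, 0.5))
  expect_equal(range_standardize(s), s)
  expect_error(range_standardize(cbind(ok = 1:3, bad = rep(2, 3))), "bad")
})

test_that("Bray-Curtis follows the absolute-difference formula", {
  m <- rbind(c(1, 1), c(0, 2), c(1, 1))
  D <- bray_curtis(m)
  expect_equal(D[1, 2], 0.5)       # (1+1)/(2+2)
  expect_equal(D[1, 3], 0)
  disjoint <- rbind(c(1, 0), c(0, 3))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 1), c(0, 1))), "non-negative")
})

test_that("PCoA round-trips Euclidean configurations", {
  set.seed(23)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  fit <- pcoa(D)
  expect_lt(max(abs(as.matrix(dist(fit$scores)) - D)), 1e-9)
  expect_equal(fit$negative_inertia, 0, tolerance = 1e-10)
  # axes are uncorrelated
  cv <- cov(fit$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
  # two points: one axis separating them by their distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  f2 <- pcoa(d2)
  expect_equal(ncol(f2$scores), 1)
  expect_equal(abs(diff(f2$scores[, 1])), 3)
})

test_that("descriptor fitting recovers axis-aligned and orthogonal cases", {
  set.seed(27)
  S <- matrix(rnorm(60), 30, 2)
  desc <- cbind(axis1 = S[, 1],
                ortho = residuals(lm(rnorm(30) ~ S)))
  fit <- envfit_axes(S, desc, n_perm = 199, seed = 1)
  expect_equal(fit$r2[1], 1, tolerance = 1e-9)
  expect_equal(abs(fit$dir1[1]), 1, tolerance = 1e-6)
  expect_lt(fit$p[1], 0.01)
  expect_equal(fit$r2[2], 0, tolerance = 1e-9)
  expect_gt(fit$p[2], 0.5)
  # location/scale invariance of R^2
  fit_scaled <- envfit_axes(S, cbind(10 + 3 * desc[, 1]), n_perm = 99,
                            seed = 1)
  expect_equal(fit_scaled$r2, fit$r2[1], tolerance = 1e-9)
  expect_error(envfit_axes(S, cbind(k = rep(1, 30))), "constant")
})

test_that("descriptor R^2 agrees with vegan's envfit", {
  set.seed(28)
  S <- matrix(rnorm(80), 40, 2)
  X <- cbind(d1 = S[, 1] + rnorm(40, 0, 0.5),
             d2 = rnorm(40),
             d3 = S[, 2] * 2 + rnorm(40))
  ours <- envfit_axes(S, X, n_perm = 199, seed = 2)
  ref <- vegan::envfit(S, as.data.frame(X), permutations = 199)
  expect_equal(ours$r2, unname(ref$vectors$r), tolerance = 1e-10)
})

test_that("same-ribotype strains are ordination nearest neighbours", {
  hit <- vapply(1:10, function(s) {
    cfg <- synth_config(n_ribotypes = 4, strains_per_ribotype = 4,
                        planted_cbc = default_planted_cbc(4), seed = 100 + s)
    hp <- simulate_host_phenotype(cfg)
    phen <- hp$phenotypes
    gs <- genome_size_from_ratio(phen$ratio)$size_mb
    mat <- cbind(range_standardize(cbind(FSC = phen$FSC, SSC = phen$SSC,
                                         green = phen$green, genome = gs)),
                 hp$infection)
    sc <- pcoa(bray_curtis(mat))$scores[, 1:2]
    d <- as.matrix(dist(sc)); diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    mean(phen$ribotype[nn] == phen$ribotype)
  }, numeric(1))
  expect_gte(mean(hit >= 0.9), 0.9)
})
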