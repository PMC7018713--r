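# Community filtering, Hellinger transform, OMI, kernel niches and
# Schoener's D.

test_that("the two-library filter drops singletons and keeps doubletons", {
  counts <- cbind(once = c(5, 0, 0), twice = c(1, 2, 0), all = c(1, 1, 1))
  out <- filter_unique_sequences(counts)
  expect_equal(colnames(out), c("twice", "all"))
  expect_warning(filter_unique_sequences(cbind(x = c(9, 0, 0))),
                 "no taxa")
})

test_that("Hellinger transform is the square-root relative abundance", {
  out <- hellinger(rbind(c(1, 0, 3)))
  expect_equal(unname(out[1, ]), c(0.5, 0, 0.8660254), tolerance = 1e-6)
  set.seed(2)
  m <- matrix(rpois(60, 5) + 1, 6, 10)
  h <- hellinger(m)
  expect_equal(unname(rowSums(h^2)), rep(1, 6))
  expect_equal(hellinger(10 * m), h)
  expect_error(hellinger(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("OMI of degenerate profiles matches the closed forms", {
  set.seed(40)
  n <- 12
  x <- matrix(runif(n * 7), n, 7,
              dimnames = list(NULL, paste0("e", 1:7)))
  # uniform profile: centroid at the origin
  y_unif <- matrix(1, n, 1, dimnames = list(NULL, "u"))
  om <- omi_analysis(y_unif, x)
  expect_equal(om$taxa$omi, 0, tolerance = 1e-12)
  # profile confined to one sample: OMI = ||x_i||^2, tolerance 0
  y_point <- matrix(0, n, 2, dimnames = list(NULL, c("pt", "u")))
  y_point[3, 1] <- 7
  y_point[, 2] <- 1
  om2 <- omi_analysis(y_point, x)
  Xc <- range_standardize(x)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  expect_equal(om2$taxa$omi[1], sum(Xc[3, ]^2), tolerance = 1e-10)
  expect_equal(om2$taxa$tolerance[1], 0, tolerance = 1e-10)
})

test_that("OMI identities hold on random instances", {
  set.seed(41)
  for (case in 1:30) {
    n <- sample(10:30, 1); S <- sample(3:12, 1)
    y <- matrix(rpois(n * S, 3), n, S,
                dimnames = list(NULL, paste0("t", 1:S)))
    y <- y[, colSums(y) > 0, drop = FALSE]
    if (ncol(y) < 2 || any(rowSums(y) == 0)) next
    x <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("e", 1:7)))
    om <- omi_analysis(y, x)
    expect_lt(max(abs(om$taxa$inertia -
                        (om$taxa$omi + om$taxa$tolerance +
                           om$taxa$residual))), 1e-8)
    expect_lt(abs(sum(om$eigenvalues) -
                    sum(om$taxa$weight * om$taxa$omi)), 1e-8)
  }
})

test_that("OMI values are invariant to sample permutation", {
  set.seed(43)
  n <- 15
  y <- matrix(rpois(n * 4, 4) + 1, n, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  x <- matrix(runif(n * 7), n, 7, dimnames = list(NULL, paste0("e", 1:7)))
  om1 <- omi_analysis(y, x)
  perm <- sample(n)
  om2 <- omi_analysis(y[perm, ], x[perm, ])
  expect_equal(om1$taxa$omi, om2$taxa$omi, tolerance = 1e-10)
  expect_equal(om1$taxa$tolerance, om2$taxa$tolerance, tolerance = 1e-10)
  expect_equal(om2$scores, om1$scores[perm, ], tolerance = 1e-10)
})

test_that("kernel niches are normalized, scale-free and mode-correct", {
  set.seed(44)
  S <- matrix(rnorm(40), 20, 2)
  w <- rexp(20)
  kn <- kernel_niche(S, w)
  expect_equal(sum(kn$density), 1, tolerance = 1e-12)
  expect_equal(kernel_niche(S, 2 * w)$density, kn$density)
  # all weight on one sample: mode cell neighbours that sample
  w1 <- rep(0, 20); w1[7] <- 3
  k1 <- kernel_niche(S, w1)
  mode_cell <- which(k1$density == max(k1$density), arr.ind = TRUE)[1, ]
  expect_equal(which.min(abs(k1$x - S[7, 1])), unname(mode_cell["row"]))
  expect_equal(which.min(abs(k1$y - S[7, 2])), unname(mode_cell["col"]))
  expect_error(kernel_niche(S, rep(0, 20)), "all-zero")
})

test_that("Schoener's D identities and the hand-computed case", {
  grid <- list(x = 1:2, y = 1:2)
  mk <- function(p) structure(list(x = grid$x, y = grid$y,
                                   density = matrix(p, 2, 2)),
                              class = "kernel_niche")
  a <- mk(c(0.5, 0.5, 0, 0))
  b <- mk(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(schoener_d(a, b), 0.5)
  expect_equal(schoener_d(a, a), 1)
  expect_equal(schoener_d(mk(c(1, 0, 0, 0)), mk(c(0, 0, 0, 1))), 0)
  # symmetry
  expect_equal(schoener_d(a, b), schoener_d(b, a))
  bad <- structure(list(x = 2:3, y = 1:2, density = matrix(0.25, 2, 2)),
                   class = "kernel_niche")
  expect_error(schoener_d(a, bad), "different grids")
})

test_that("overlap matrix properties and planted-optima ranking", {
  cfg <- synth_config(n_ribotypes = 8, strains_per_ribotype = 1,
                      n_taxa = 8, peak_count = 600, seed = 46)
  com <- simulate_community_series(cfg)
  om <- omi_analysis(hellinger(com$counts), com$env)
  niches <- lapply(seq_len(8), function(s) {
    kernel_niche(om$scores[, 1:2], com$counts[, s])
  })
  names(niches) <- colnames(com$counts)
  ov <- overlap_matrix(niches)
  expect_equal(ov$D, t(ov$D))
  expect_equal(unname(diag(ov$D)), rep(1, 8))
  expect_true(all(ov$D >= 0 & ov$D <= 1))
  # most distant planted optima give the smallest overlap
  opt1 <- cfg$niche_optima[, 1]
  far <- which(abs(outer(opt1, opt1, "-")) ==
                 max(abs(outer(opt1, opt1, "-"))), arr.ind = TRUE)[1, ]
  low <- which(ov$D == min(ov$D[upper.tri(ov$D)]), arr.ind = TRUE)[1, ]
  expect_setequal(unname(low), unname(far))
})

test_that("OMI permutation test separates responsive from flat taxa", {
  cfg <- synth_config(n_taxa = 9, n_ribotypes = 8, strains_per_ribotype = 1,
                      niche_breadth = c(rep(0.25, 8), 1e6), seed = 47)
  com <- simulate_community_series(cfg)
  sig <- omi_significance(hellinger(com$counts), com$env, n_perm = 199,
                          seed = 2)
  # taxa with extreme optima are clearly marginal; the flat taxon is not
  expect_lt(sig$p[sig$taxon == "RIB1"], 0.05)
  expect_lt(sig$p[sig$taxon == "RIB2"], 0.05)
  expect_lt(sig$omi[sig$taxon == "BG01"],
            0.1 * sig$omi[sig$taxon == "RIB1"])
  expect_gt(sig$p[sig$taxon == "BG01"], sig$p[sig$taxon == "RIB1"])
})
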