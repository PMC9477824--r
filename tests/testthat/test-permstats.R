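test_that("PCoA reproduces Euclidean geometry exactly", {
  set.seed(3)
  X <- matrix(rnorm(16), 8, 2)
  D <- coord_dist(X)
  ord <- pcoa(D)
  emb <- as.matrix(dist(cbind(ord$points)))
  expect_equal(unname(emb), unname(D), tolerance = 1e-8)

  # three collinear points: a single positive axis
  Dl <- coord_dist(cbind(c(0, 1, 3)))
  ol <- pcoa(Dl)
  expect_equal(ncol(ol$points), 1)
  expect_equal(ncol(ol$neg_points), 0)
})

test_that("PCoA eigenvalues sum to the trace of the centered matrix", {
  tab <- random_community(n_taxa = 10, n_samples = 4, seed = 2)
  D <- bray_curtis_matrix(tab)
  ord <- pcoa(D)
  expect_equal(sum(ord$eig), ord$trace, tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA partition is exact and matches vegan's statistic", {
  skip_if_not_installed("vegan")
  set.seed(5)
  X <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 2), 5, 2))
  D <- coord_dist(X)
  g <- rep(c("a", "b"), each = 5)
  res <- permanova(D, g, n_perm = 99, seed = 1)
  va <- vegan::adonis2(as.dist(D) ~ g, permutations = 99)
  expect_equal(res$F, va$F[1], tolerance = 1e-10)
  expect_equal(res$R2, va$R2[1], tolerance = 1e-10)
  # R2 and within-group fraction partition to one
  d2 <- D^2
  sst <- sum(d2) / (2 * nrow(D))
  ssw <- soildispersal:::ss_within(d2, split(seq_len(nrow(D)), g))
  expect_equal(res$R2 + ssw / sst, 1, tolerance = 1e-10)
})

test_that("exact PERMANOVA p equals exhaustive enumeration", {
  # two groups of two, zero within / positive between: p = 1/3
  X <- cbind(c(0, 0, 10, 10), c(0, 0, 0, 0)) +
    cbind(c(0, 1e-9, 0, 1e-9), 0)  # break exact ties in coordinates
  D <- coord_dist(cbind(c(0, 0, 10, 10)))
  g <- c("a", "a", "b", "b")
  res <- permanova(D, g, n_perm = "exact")
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  # general fixtures (n <= 8): compare with an independent enumeration
  # over all label permutations using the hat-matrix F
  for (seed in 1:3) {
    set.seed(seed)
    n <- 7
    Xf <- matrix(rnorm(2 * n), n, 2)
    Df <- coord_dist(Xf)
    gf <- c(rep("a", 3), rep("b", 2), rep("c", 2))
    res <- permanova(Df, gf, n_perm = "exact")
    P <- soildispersal:::all_permutations(n)
    Fobs <- permanova_f_hat(Df, gf)
    Fs <- apply(P, 1, function(p) permanova_f_hat(Df, gf[p]))
    expect_equal(res$F, Fobs, tolerance = 1e-9)
    expect_equal(res$p, mean(Fs >= Fobs - 1e-9), tolerance = 1e-12)
  }
})

test_that("PERMANOVA p has the permutation resolution bound", {
  set.seed(2)
  D <- coord_dist(matrix(rnorm(12), 6, 2))
  g <- rep(c("a", "b"), 3)
  res <- permanova(D, g, n_perm = 1, seed = 1)
  expect_true(res$p %in% c(0.5, 1))
  expect_true(permanova(D, g, n_perm = 99, seed = 1)$p > 0)
})

test_that("statistics are invariant to sample reordering", {
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  D <- coord_dist(X)
  g <- rep(c("a", "b"), each = 5)
  perm <- sample(10)
  r1 <- permanova(D, g, n_perm = 49, seed = 3)
  r2 <- permanova(D[perm, perm], g[perm], n_perm = 49, seed = 3)
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-12)
  expect_equal(shannon(X[1, ] - min(X) + 1),
               shannon(rev(X[1, ] - min(X) + 1)))
})

test_that("PERMANOVA rejects degenerate groupings", {
  D <- coord_dist(matrix(rnorm(8), 4, 2))
  expect_error(permanova(D, c("a", "b", "c", "d"), 9), "singleton")
  expect_error(permanova(D, rep("a", 4), 9), "2 groups")
})

test_that("strata restrict permutations within blocks", {
  set.seed(4)
  D <- coord_dist(matrix(rnorm(16), 8, 2))
  g <- rep(c("a", "b"), 4)
  blocks <- rep(1:4, each = 2)
  P <- soildispersal:::with_seed(1,
    soildispersal:::draw_permutations(8, 50, strata = blocks))
  for (i in seq_len(nrow(P))) {
    expect_equal(blocks[P[i, ]], blocks)
  }
  res <- permanova(D, g, n_perm = 50, seed = 1, strata = blocks)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("pairwise PERMANOVA reproduces per-pair runs and separates clusters", {
  set.seed(6)
  X <- rbind(matrix(rnorm(12, 0, 0.2), 6, 2),
             matrix(rnorm(12, 5, 0.2), 6, 2),
             matrix(rnorm(12, 0, 0.2), 6, 2))
  D <- coord_dist(X)
  g <- rep(c("a", "b", "a2"), each = 6)
  pw <- pairwise_permanova(D, g, n_perm = 99, seed = 11)
  seeds <- soildispersal:::derive_seeds(11, 3)
  keep <- g %in% c("a", "a2")
  manual <- permanova(D[keep, keep], g[keep], n_perm = 99,
                      seed = seeds[[1]])
  row_aa2 <- pw[pw$a == "a" & pw$b == "a2", ]
  expect_equal(row_aa2$p, manual$p)
  # only the duplicated-location pair is non-significant
  expect_gt(row_aa2$p, 0.05)
  expect_lt(max(pw$p[!(pw$a == "a" & pw$b == "a2")]), 0.05)
  pw_bh <- pairwise_permanova(D, g, n_perm = 99, seed = 11,
                              correction = "BH")
  expect_equal(pw_bh$p_adj, p.adjust(pw_bh$p, "BH"))
})

test_that("PERMDISP sees equal dispersion in congruent groups", {
  X <- rbind(cbind(c(0, 1, 0, -1), c(1, 0, -1, 0)),
             cbind(10 + c(0, 1, 0, -1), c(1, 0, -1, 0)))
  D <- coord_dist(X)
  g <- rep(c("a", "b"), each = 4)
  res <- permdisp(D, g, n_perm = 199, seed = 1)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_gt(res$p, 0.5)
  expect_equal(unname(res$dispersion["a"]), unname(res$dispersion["b"]))
})

test_that("PERMDISP scales dispersion linearly with dilation", {
  set.seed(9)
  base <- matrix(rnorm(12), 6, 2)
  X <- rbind(base, 3 * base + 20)
  D <- coord_dist(X)
  g <- rep(c("tight", "wide"), each = 6)
  res <- permdisp(D, g, n_perm = 99, seed = 2)
  expect_equal(unname(res$dispersion["wide"] / res$dispersion["tight"]), 3,
               tolerance = 1e-8)
  expect_error(permdisp(D, c(rep("a", 11), "b"), 9), ">= 2 samples")
})

test_that("PERMDISP centroid distances match vegan::betadisper", {
  skip_if_not_installed("vegan")
  tab <- random_community(n_taxa = 25, n_samples = 10, seed = 12)
  D <- bray_curtis_matrix(tab)
  g <- rep(c("a", "b"), each = 5)
  res <- permdisp(D, g, n_perm = 9, seed = 1)
  bd <- vegan::betadisper(as.dist(D), g, type = "centroid")
  expect_equal(unname(res$distances), unname(bd$distances),
               tolerance = 1e-6)
})

test_that("centroid distances follow the embedded geometry", {
  X <- cbind(c(0, 0, 4, 4), c(0, 2, 0, 2))
  D <- coord_dist(X, ids = c("a1", "a2", "b1", "b2"))
  expect_equal(centroid_distance(D, c("a1", "a2"), c("b1", "b2")), 4,
               tolerance = 1e-8)
  expect_equal(centroid_distance(D, c("a1", "a2"), c("a1", "a2")), 0)
  expect_equal(centroid_distance(D, "a1", "b2"), D["a1", "b2"],
               tolerance = 1e-8)
  expect_error(centroid_distance(D, character(0), "a1"), "empty")
})

test_that("Mantel statistic behaves under identity and affine maps", {
  set.seed(10)
  D1 <- coord_dist(matrix(rnorm(20), 10, 2))
  expect_equal(mantel(D1, D1, n_perm = 9, seed = 1)$r, 1)
  D2 <- 0.5 * D1 + 0.2
  diag(D2) <- 0
  expect_equal(mantel(D1, D2, n_perm = 9, seed = 1)$r, 1, tolerance = 1e-9)
  skip_if_not_installed("vegan")
  D3 <- coord_dist(matrix(rnorm(20), 10, 2), ids = rownames(D1))
  expect_equal(mantel(D1, D3, n_perm = 9, seed = 1)$r,
               vegan::mantel(as.dist(D1), as.dist(D3),
                             permutations = 9)$statistic,
               tolerance = 1e-10)
})

test_that("Mantel aligns matrices by sample id and rejects mismatches", {
  D1 <- coord_dist(matrix(rnorm(12), 6, 2))
  D2 <- coord_dist(matrix(rnorm(12), 6, 2))
  perm <- sample(6)
  D2p <- D2[perm, perm]
  expect_equal(mantel(D1, D2p, n_perm = 9, seed = 1)$r,
               mantel(D1, D2, n_perm = 9, seed = 1)$r, tolerance = 1e-12)
  rownames(D2) <- colnames(D2) <- paste0("x", 1:6)
  expect_error(mantel(D1, D2, 9), "ids")
})

test_that("NMDS reaches near-zero stress on embeddable input", {
  set.seed(13)
  X <- matrix(rnorm(20), 10, 2)
  D <- coord_dist(X)
  res <- nmds(D, k = 2, seed = 1, n_restarts = 2)
  expect_lt(res$stress, 1e-3)
  expect_error(nmds(D, k = 10), "smaller")
})

test_that("NMDS stress trace is non-increasing and seeded runs repeat", {
  tab <- random_community(n_taxa = 30, n_samples = 12, seed = 20)
  D <- bray_curtis_matrix(tab)
  r1 <- nmds(D, k = 2, seed = 5, n_restarts = 3)
  expect_true(all(diff(r1$trace) <= 1e-10))
  r2 <- nmds(D, k = 2, seed = 5, n_restarts = 3)
  expect_identical(r1$points, r2$points)
  r3 <- nmds(D, k = 2, seed = 6, n_restarts = 3)
  expect_equal(r1$stress, r3$stress, tolerance = 0.05)
})
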