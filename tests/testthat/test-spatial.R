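test_that("haversine distances match closed forms", {
  md <- validate_metadata(data.frame(
    sample_id = c("o", "e", "anti"),
    habitat = "w",
    longitude = c(0, 1, 180), latitude = c(0, 0, 0),
    stringsAsFactors = FALSE))
  d <- as.matrix(geographic_distance(md))
  R <- 6371.0088
  expect_equal(d["o", "e"], 2 * R * asin(sin(0.5 * pi / 180)), tolerance = 1e-9)
  expect_equal(d["o", "anti"], pi * R, tolerance = 1e-9)
  expect_equal(d["o", "o"], 0)
  md$latitude[2] <- NA
  expect_error(geographic_distance(md), "missing coordinates.*e")
})

test_that("env_distance: sqrt except pH, standardization, errors", {
  md <- validate_metadata(data.frame(
    sample_id = c("a", "b"), habitat = "w", longitude = 0, latitude = 0,
    pH = c(7, 9), TN = c(1, 4), stringsAsFactors = FALSE))
  expect_equal(as.vector(env_distance(md, "pH", standardize = FALSE)), 2)
  expect_equal(as.vector(env_distance(md, "TN", standardize = FALSE)), 1)
  expect_equal(as.vector(env_distance(md, c("pH", "TN"), standardize = FALSE)),
               sqrt(4 + 1))
  md$TN[1] <- -1
  expect_error(env_distance(md, "TN"), "negative.*TN")
  md$TN[1] <- NA
  expect_error(env_distance(md, "TN"), "missing value")
  expect_equal(as.vector(env_distance(md, "pH"))[1],
               as.vector(stats::dist(scale(c(7, 9))))[1])
})

test_that("mantel: extremes, symmetry, exhaustive enumeration at n = 5", {
  dmA <- random_dist(6, seed = 1)
  expect_equal(mantel(dmA, dmA, n_permutations = 99, seed = 1)$r, 1)
  # rank-reversed copy gives r = -1 (spearman)
  rev_m <- as.matrix(dmA)
  rev_m[] <- max(rev_m) + min(rev_m[rev_m > 0]) - rev_m
  diag(rev_m) <- 0
  expect_equal(mantel(dmA, rev_m, n_permutations = 99, seed = 1)$r, -1)
  # symmetry of the statistic
  dmB <- random_dist(6, seed = 2)
  expect_equal(mantel(dmA, dmB, n_permutations = 0 + 99, seed = 1)$r,
               mantel(dmB, dmA, n_permutations = 99, seed = 1)$r)
  # exhaustive oracle at n = 5, both tails
  A <- random_dist(5, seed = 3); B <- random_dist(5, seed = 4)
  res <- mantel(A, B, n_permutations = 120, seed = 1)
  expect_true(res$exact)
  null <- enumerate_mantel_null(A, B)
  obs <- cor_offdiag(A, B)
  expect_equal(res$r, obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(null >= obs - 1e-12), tolerance = 1e-12)
  res2 <- mantel(A, B, n_permutations = 120, tail = "two", seed = 1)
  expect_equal(res2$p_value, mean(abs(null) >= abs(obs) - 1e-12), tolerance = 1e-12)
  expect_error(mantel(A, random_dist(5, seed = 5, labels = letters[1:5])),
               "labels")
})

test_that("partial mantel: self-conditioning, noise, closed form", {
  A <- random_dist(8, seed = 10)
  B <- random_dist(8, seed = 11)
  # conditioning on a matrix perfectly correlated with A (or B) is degenerate
  expect_error(partial_mantel(A, B, A, n_permutations = 9, seed = 1), "degenerate")
  expect_error(partial_mantel(A, B, B, method = "pearson",
                              n_permutations = 9, seed = 1), "degenerate")
  # closed-form check on a 4-site fixture
  A4 <- random_dist(4, seed = 20); B4 <- random_dist(4, seed = 21)
  C4 <- random_dist(4, seed = 22)
  rAB <- cor_offdiag(A4, B4); rAC <- cor_offdiag(A4, C4); rBC <- cor_offdiag(B4, C4)
  want <- (rAB - rAC * rBC) / sqrt((1 - rAC^2) * (1 - rBC^2))
  got <- partial_mantel(A4, B4, C4, n_permutations = 24, seed = 1)
  expect_equal(got$r, want, tolerance = 1e-12)
  # a conditioning matrix uncorrelated with both leaves r_AB nearly unchanged
  diffs <- vapply(1:20, function(s) {
    C <- random_dist(8, seed = 100 + s)
    partial_mantel(A, B, C, n_permutations = 0 + 9, seed = 1)$r -
      mantel(A, B, n_permutations = 9, seed = 1)$r
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("distance_decay orientation and zero-variance guard", {
  md <- ring_metadata(8)
  geo <- geographic_distance(md)
  # build similarity decaying in distance: dissimilarity = scaled distance
  dis <- geo / max(geo) * 0.8
  res <- distance_decay(dis, geo, n_permutations = 199, seed = 1)
  expect_lt(res$mantel$r, 0)
  expect_lt(res$slope, 0)
  expect_lt(res$mantel$p_value, 0.05)
  # constant similarity warns and reports r = 0
  cst <- geo; cst[] <- 0.4
  expect_warning(res0 <- distance_decay(cst, geo, seed = 1), "constant")
  expect_equal(res0$mantel$r, 0)
})

test_that("pcnm: truncation, orthogonality, transect sinusoid", {
  # 10 equidistant collinear sites
  coords <- data.frame(sample_id = sprintf("t%02d", 1:10), habitat = "w",
                       longitude = seq(0, 0.09, by = 0.01), latitude = 0,
                       stringsAsFactors = FALSE)
  geo <- geographic_distance(validate_metadata(coords))
  b <- pcnm(geo)
  # truncation = largest nearest-neighbour gap on a line = the unit spacing
  D <- as.matrix(geo)
  spacing <- D[1, 2]
  expect_equal(b$truncation_distance, spacing, tolerance = 1e-9)
  # orthonormal columns
  gram <- crossprod(b$vectors)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # eigenvalues positive descending
  expect_true(all(diff(b$values) <= 1e-12) && all(b$values > 0))
  # leading eigenvector is sinusoidal over site order (the broadest-scale
  # harmonics of the transect); with nearest-neighbour truncation the best
  # match is the full-period sine. Identical to the reference implementation.
  i <- seq_len(10)
  half <- cos(pi * (i - 0.5) / 10)
  full <- sin(2 * pi * (i - 0.5) / 10)
  expect_gt(max(abs(stats::cor(b$vectors[, 1], half)),
                abs(stats::cor(b$vectors[, 1], full))), 0.95)
  vg <- vegan::pcnm(geo)
  expect_gt(abs(stats::cor(b$vectors[, 1], vg$vectors[, 1])), 0.9999)
  # invariance to site relabeling (up to sign/order): same eigenvalues
  perm <- withr::with_seed(55, sample(10))
  b2 <- pcnm(stats::as.dist(D[perm, perm]))
  expect_equal(b2$values, b$values, tolerance = 1e-8)
  expect_equal(b2$truncation_distance, b$truncation_distance)
  expect_error(pcnm(matrix(0, 3, 3, dimnames = list(1:3, 1:3))), "zero")
})
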