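# Fixtures built in code; all randomized fixtures take an explicit seed.

# Small count table with sample/OTU names.
toy_table <- function(n_samples = 6, n_otus = 10, lambda = 20, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("otu%03d", seq_len(n_otus))))
    otu_table(m)
  })
}

# Ring of n sites with labeled coordinates; returns validated metadata.
ring_metadata <- function(n = 8, radius_deg = 0.045) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
  validate_metadata(data.frame(
    sample_id = sprintf("r%02d", seq_len(n)),
    habitat = rep(c("water", "sediment"), each = ceiling(n / 2))[seq_len(n)],
    longitude = 118 + radius_deg * sin(ang),
    latitude = 24.5 + radius_deg * cos(ang),
    stringsAsFactors = FALSE))
}

# Random symmetric zero-diagonal labeled distance matrix.
random_dist <- function(n, seed, labels = sprintf("s%02d", seq_len(n))) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
    stats::as.dist(m + t(m))
  })
}

# Independent Spearman/Pearson correlation of two dists' off-diagonals.
cor_offdiag <- function(a, b, method = "spearman") {
  stats::cor(as.vector(stats::as.dist(as.matrix(a))),
             as.vector(stats::as.dist(as.matrix(b))), method = method)
}

# Independent exhaustive enumeration of all n! row/column permutations of B,
# returning the vector of Mantel correlations (identity included).
enumerate_mantel_null <- function(A, B, method = "spearman") {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  idx <- expand_perms(n)
  vapply(idx, function(pm) cor_offdiag(A, B[pm, pm], method), numeric(1))
}

# All permutations of 1..n, iteratively (independent of the package's
# recursive enumerator).
expand_perms <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- vector("list", length(out) * k)
    j <- 1L
    for (p in out) for (pos in seq_len(k)) {
      nxt[[j]] <- append(p, k, after = pos - 1L)
      j <- j + 1L
    }
    out <- nxt
  }
  out
}
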