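#' Great-circle geographic distance matrix
#'
#' Haversine distance on a sphere of radius 6371.0088 km from decimal-degree
#' longitude/latitude columns of a metadata table.
#'
#' @param metadata data.frame with `sample_id`, `longitude`, `latitude`
#' @return a `dist` of pairwise distances in km
#' @export
geographic_distance <- function(metadata) {
  if (any(is.na(metadata$longitude) | is.na(metadata$latitude)))
    stop("missing coordinates for sample(s): ",
         paste(metadata$sample_id[is.na(metadata$longitude) | is.na(metadata$latitude)],
               collapse = ", "))
  R <- 6371.0088
  lon <- metadata$longitude * pi / 180
  lat <- metadata$latitude * pi / 180
  n <- length(lon)
  d <- matrix(0, n, n, dimnames = list(metadata$sample_id, metadata$sample_id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    d[i, j] <- d[j, i] <- 2 * R * asin(min(1, sqrt(a)))
  }
  stats::as.dist(d)
}

#' Environmental Euclidean distance matrix
#'
#' Square-root transforms every variable except pH (concentrations and
#' counts are right-skewed; pH is already a log scale), optionally z-score
#' standardizes each variable (default on: units are incommensurable), and
#' takes Euclidean distances between samples.
#'
#' @param metadata data.frame; rows = samples (sample_id column required)
#' @param variables names of numeric columns to use (default: the
#'   `env_vars` attribute set by [read_sample_metadata]/[validate_metadata])
#' @param standardize z-score each variable after the sqrt transform
#' @return a `dist` with sample labels
#' @export
env_distance <- function(metadata, variables = NULL, standardize = TRUE) {
  if (is.null(variables)) variables <- attr(metadata, "env_vars")
  if (is.null(variables) || !length(variables)) stop("no environmental variables given")
  miss <- setdiff(variables, colnames(metadata))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(metadata[, variables, drop = FALSE])
  if (any(is.na(X))) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value: sample '%s', variable '%s'",
                 metadata$sample_id[bad[1]], variables[bad[2]]))
  }
  for (v in variables) {
    if (identical(tolower(v), "ph")) next
    if (any(X[, v] < 0))
      stop(sprintf("negative value under sqrt: variable '%s', sample '%s'",
                   v, metadata$sample_id[which(X[, v] < 0)[1]]))
    X[, v] <- sqrt(X[, v])
  }
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  rownames(X) <- metadata$sample_id
  stats::dist(X)
}

# Correlation of the off-diagonal vectors of two aligned dists.
mantel_r <- function(dmA, dmB, method) {
  stats::cor(dist_vec(dmA), dist_vec(dmB), method = method)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) between the n(n-1)/2 off-diagonal
#' entries, with significance by simultaneous row/column permutation of the
#' second matrix. When n! fits within `n_permutations` the exact permutation
#' distribution is enumerated.
#'
#' @param dmA,dmB `dist` objects or square labeled matrices on the same samples
#' @param method `"spearman"` (default) or `"pearson"`
#' @param n_permutations default 999
#' @param tail `"upper"` (default), `"lower"`, or `"two"`
#' @param seed integer seed
#' @return list of class `mantel_result`: `r`, `p_value`, `n_permutations`,
#'   `tail`, `method`, `exact`, `seed`
#' @export
mantel <- function(dmA, dmB, method = c("spearman", "pearson"),
                   n_permutations = 999, tail = c("upper", "lower", "two"),
                   seed = 1L) {
  method <- match.arg(method); tail <- match.arg(tail)
  dmA <- as_dist_checked(dmA, "dmA")
  dmB <- align_dist(dmA, as_dist_checked(dmB, "dmB"), "dmB")
  n <- attr(dmA, "Size")
  if (n < 4) stop("need n >= 4 samples")
  obs <- mantel_r(dmA, dmB, method)
  B <- as.matrix(dmB)
  perms <- enumerate_or_sample_perms(n, n_permutations, seed)
  null <- vapply(perms$perms, function(idx)
    mantel_r(dmA, stats::as.dist(B[idx, idx]), method), numeric(1))
  p <- perm_pvalue(obs, null, tail, perms$exact)
  structure(list(r = obs, p_value = p, n_permutations = length(perms$perms),
                 tail = tail, method = method, exact = perms$exact, seed = seed),
            class = "mantel_result")
}

perm_pvalue <- function(obs, null, tail, exact) {
  eps <- 1e-12
  hits <- switch(tail,
    upper = sum(null >= obs - eps),
    lower = sum(null <= obs + eps),
    two = sum(abs(null) >= abs(obs) - eps))
  if (exact) hits / length(null) else (hits + 1) / (length(null) + 1)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.3f, p = %.4g (%d %s permutations, %s tail)\n",
              x$method, x$r, x$p_value, x$n_permutations,
              if (x$exact) "exact" else "random", x$tail))
  invisible(x)
}

#' Partial Mantel test
#'
#' First-order partial correlation r_AB.C between the off-diagonal vectors
#' of A and B, conditioning on C; significance by simple permutation of the
#' second matrix (the classic Smouse-Long-Sokal scheme).
#'
#' @inheritParams mantel
#' @param dmC conditioning distance matrix
#' @return a `mantel_result`
#' @export
partial_mantel <- function(dmA, dmB, dmC, method = c("spearman", "pearson"),
                           n_permutations = 999, tail = c("upper", "lower", "two"),
                           seed = 1L) {
  method <- match.arg(method); tail <- match.arg(tail)
  dmA <- as_dist_checked(dmA, "dmA")
  dmB <- align_dist(dmA, as_dist_checked(dmB, "dmB"), "dmB")
  dmC <- align_dist(dmA, as_dist_checked(dmC, "dmC"), "dmC")
  n <- attr(dmA, "Size")
  rAC <- mantel_r(dmA, dmC, method)
  partial_r <- function(dmBperm) {
    rAB <- mantel_r(dmA, dmBperm, method)
    rBC <- mantel_r(dmBperm, dmC, method)
    if (abs(rAC) >= 1 - 1e-12 || abs(rBC) >= 1 - 1e-12)
      stop("degenerate conditioning: |r_AC| or |r_BC| = 1")
    (rAB - rAC * rBC) / sqrt((1 - rAC^2) * (1 - rBC^2))
  }
  obs <- partial_r(dmB)
  B <- as.matrix(dmB)
  perms <- enumerate_or_sample_perms(n, n_permutations, seed)
  null <- vapply(perms$perms, function(idx)
    partial_r(stats::as.dist(B[idx, idx])), numeric(1))
  p <- perm_pvalue(obs, null, tail, perms$exact)
  structure(list(r = obs, p_value = p, n_permutations = length(perms$perms),
                 tail = tail, method = method, exact = perms$exact, seed = seed),
            class = "mantel_result")
}

#' Distance-decay analysis
#'
#' Mantel test of community similarity (1 - dissimilarity) against
#' geographic distance, plus a descriptive OLS slope of similarity on
#' distance. A negative Mantel r is the distance-decay signature of
#' dispersal limitation; the orientation (similarity vs distance,
#' lower-tail test) is recorded in the result.
#'
#' @param community_dm community dissimilarity `dist` (converted internally
#'   to similarity)
#' @param geo_dm geographic distance `dist` (km)
#' @param n_permutations default 999
#' @param seed integer seed
#' @return list of class `distance_decay_result`: `mantel` (a `mantel_result`,
#'   lower tail on similarity), `slope` (similarity per km), `intercept`,
#'   `orientation`
#' @export
distance_decay <- function(community_dm, geo_dm, n_permutations = 999, seed = 1L) {
  community_dm <- as_dist_checked(community_dm, "community_dm")
  geo_dm <- align_dist(community_dm, as_dist_checked(geo_dm, "geo_dm"), "geo_dm")
  sim <- 1 - community_dm
  if (stats::sd(dist_vec(sim)) < 1e-12) {
    warning("community similarity is constant; Mantel r undefined, reported as 0")
    mt <- structure(list(r = 0, p_value = 1, n_permutations = 0, tail = "lower",
                         method = "spearman", exact = FALSE, seed = seed),
                    class = "mantel_result")
    slope <- c(0, mean(dist_vec(sim)))
  } else {
    mt <- mantel(sim, geo_dm, method = "spearman",
                 n_permutations = n_permutations, tail = "lower", seed = seed)
    fit <- stats::lm.fit(cbind(1, dist_vec(geo_dm)), dist_vec(sim))
    slope <- c(fit$coefficients[2], fit$coefficients[1])
  }
  structure(list(mantel = mt, slope = unname(slope[1]), intercept = unname(slope[2]),
                 orientation = "similarity_vs_distance; decay <=> r < 0, lower tail"),
            class = "distance_decay_result")
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated at t = the longest edge of its minimum spanning tree
#' (all larger distances replaced by 4t), the truncated matrix is double
#' centered (-0.5 D^2), and the eigenvectors with positive eigenvalues
#' (> 1e-9 of the largest) are returned as spatial predictors, ordered from
#' broadest to finest scale.
#'
#' @param geo_dm a `dist` or square labeled matrix of geographic distances
#' @return list of class `pcnm_basis`: `vectors` (sites x q, orthonormal,
#'   columns PCNM1..q), `values` (descending positive eigenvalues),
#'   `truncation_distance`
#' @export
pcnm <- function(geo_dm) {
  geo_dm <- as_dist_checked(geo_dm, "geo_dm")
  n <- attr(geo_dm, "Size")
  if (n < 3) stop("need >= 3 sites")
  D <- as.matrix(geo_dm)
  if (max(D) == 0) stop("all distances are zero")
  t_trunc <- max(mst_edges(D))
  Dt <- D
  Dt[Dt > t_trunc] <- 4 * t_trunc
  diag(Dt) <- 0
  A <- -0.5 * Dt^2
  # double centering
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  rownames(V) <- rownames(D)
  colnames(V) <- paste0("PCNM", seq_len(ncol(V)))
  structure(list(vectors = V, values = e$values[keep],
                 truncation_distance = t_trunc),
            class = "pcnm_basis")
}

# Edge lengths of the minimum spanning tree of a distance matrix (Prim).
mst_edges <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  edges <- numeric(0)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    edges <- c(edges, best[nxt])
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  edges
}
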