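#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed after an optional
#' transform of the counts. On tables rarefied to equal depth the `none`
#' and `relative` transforms are equivalent; `sqrt` down-weights dominant
#' taxa as in common PRIMER workflows.
#'
#' @param x an [otu_table] (or non-negative numeric matrix, samples in rows)
#' @param transform `"none"` (default), `"sqrt"`, or `"relative"`
#' @return a `dist` object with sample labels
#' @export
bray_curtis <- function(x, transform = c("none", "sqrt", "relative")) {
  transform <- match.arg(transform)
  m <- unclass(x)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(rownames(m)[tot == 0], collapse = ", "))
  m <- switch(transform, none = m, sqrt = sqrt(m), relative = m / tot)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  stats::as.dist(d)
}

#' Hellinger transform
#'
#' sqrt of relative abundance: the Euclidean distance between transformed
#' rows is the Hellinger distance, which makes community data suitable for
#' RDA and other Euclidean-based methods.
#'
#' @param x an [otu_table]
#' @return numeric matrix of sqrt(count / sample total)
#' @export
hellinger_transform <- function(x) {
  sqrt(relative_abundance(x))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal's NMDS (stress-1, monotone regression) of a dissimilarity
#' matrix, taking the best (lowest-stress) solution over `n_restarts`
#' random starting configurations plus a metric-scaling start. The
#' iterative engine is vegan's `monoMDS`; restart logic, seeding and
#' degenerate-input handling live here.
#'
#' @param dm a `dist` or square labeled matrix
#' @param k number of ordination dimensions
#' @param n_restarts random restarts (default 50)
#' @param seed integer seed
#' @param maxit maximum iterations per start
#' @return list of class `nmds_result`: `coordinates` (centered, samples x k),
#'   `stress` (Kruskal stress-1 in \[0,1\]), `k`, `converged`, `seed`,
#'   `degenerate`
#' @export
nmds <- function(dm, k = 2, n_restarts = 50, seed = 1L, maxit = 500) {
  dm <- as_dist_checked(dm)
  n <- attr(dm, "Size")
  if (n < k + 2) stop("need at least k + 2 samples")
  v <- dist_vec(dm)
  if (max(v) - min(v) < 1e-12) {
    # all dissimilarities equal: any simplex embedding is perfect
    co <- stats::cmdscale(dm, k = k)
    co <- scale(co, scale = FALSE)
    rownames(co) <- attr(dm, "Labels")
    return(structure(list(coordinates = co, stress = 0, k = k, converged = TRUE,
                          seed = seed, degenerate = TRUE),
                     class = "nmds_result"))
  }
  best <- NULL
  with_seed(seed, {
    starts <- c(list(NULL), replicate(n_restarts,
                matrix(stats::rnorm(n * k), n, k), simplify = FALSE))
    for (y0 in starts) {
      fit <- if (is.null(y0))
        vegan::monoMDS(dm, k = k, model = "global", maxit = maxit,
                       smin = 1e-6, sfgrmin = 1e-9)
      else
        vegan::monoMDS(dm, y = y0, k = k, model = "global", maxit = maxit,
                       smin = 1e-6, sfgrmin = 1e-9)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  co <- scale(best$points, scale = FALSE)
  attr(co, "scaled:center") <- NULL
  rownames(co) <- attr(dm, "Labels")
  colnames(co) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = co, stress = best$stress, k = k,
                 converged = best$maxits < maxit, seed = seed,
                 degenerate = FALSE),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress-1 = %.4f%s\n",
              nrow(x$coordinates), x$k, x$stress,
              if (x$degenerate) " (degenerate input)" else ""))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Global R = (mean between-group rank - mean within-group rank) / (M/2)
#' with M = n(n-1)/2 dissimilarity pairs; R = 0 means no separation,
#' R = 1 complete separation. Significance by permutation of group labels;
#' when the group sizes allow full enumeration within `n_permutations`
#' distinct relabelings, the exact permutation distribution is used.
#'
#' @param dm a `dist` or square labeled matrix
#' @param grouping named vector mapping each sample to a group (>= 2 groups,
#'   each of size >= 2)
#' @param n_permutations number of random permutations (default 999)
#' @param seed integer seed
#' @return list of class `anosim_result`: `global_R`, `p_value`, `n_permutations`,
#'   `exact`, `seed`
#' @export
anosim <- function(dm, grouping, n_permutations = 999, seed = 1L) {
  dm <- as_dist_checked(dm)
  labs <- attr(dm, "Labels")
  g <- as.character(grouping[labs])
  if (any(is.na(g))) stop("grouping missing for sample(s): ",
                          paste(labs[is.na(grouping[labs])], collapse = ", "))
  if (length(unique(g)) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  n <- length(labs)
  rk <- rank(dist_vec(dm))
  M <- n * (n - 1) / 2
  within <- dist_vec(stats::as.dist(outer(g, g, "==")))  # TRUE = same group
  stat <- function(w) (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  obs <- stat(within == 1)
  perms <- enumerate_or_sample_perms(n, n_permutations, seed)
  null <- vapply(perms$perms, function(idx) {
    gp <- g[idx]
    w <- dist_vec(stats::as.dist(outer(gp, gp, "==")))
    stat(w == 1)
  }, numeric(1))
  p <- if (perms$exact) mean(null >= obs - 1e-12)
       else (sum(null >= obs - 1e-12) + 1) / (length(null) + 1)
  structure(list(global_R = obs, p_value = p,
                 n_permutations = length(perms$perms), exact = perms$exact,
                 seed = seed),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: global R = %.3f, p = %.4g (%d %s permutations)\n",
              x$global_R, x$p_value, x$n_permutations,
              if (x$exact) "exact" else "random"))
  invisible(x)
}

# All n! permutations if n! <= budget (exact test, identity included),
# otherwise `budget` random permutations (identity excluded from the draw;
# +1 correction applied by the caller).
enumerate_or_sample_perms <- function(n, budget, seed) {
  nf <- factorial(n)
  if (nf <= budget) {
    perms <- all_permutations(n)
    list(perms = perms, exact = TRUE)
  } else {
    perms <- with_seed(seed,
      replicate(budget, sample.int(n), simplify = FALSE))
    list(perms = perms, exact = FALSE)
  }
}

all_permutations <- function(n) {
  perm_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- vector("list", 0)
    for (i in seq_along(v))
      out <- c(out, lapply(perm_of(v[-i]), function(s) c(v[i], s)))
    out
  }
  perm_of(seq_len(n))
}
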