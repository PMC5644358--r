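# Multivariate redundancy-analysis machinery used by variation partitioning.
# Everything is ordinary least squares on column-centered matrices; the
# "explained variance" R2 is sum of squares of fitted values over total sum
# of squares, and adjusted R2 is the Ezekiel closed form.

rda_r2 <- function(Y, X, strict = TRUE) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  qrX <- qr(Xc)
  if (strict && qrX$rank < ncol(Xc)) {
    if (is.null(colnames(Xc))) colnames(Xc) <- paste0("V", seq_len(ncol(Xc)))
    bad <- colnames(Xc)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("predictor matrix is rank-deficient (collinear columns: ",
         paste(bad, collapse = ", "), ")")
  }
  fitted <- qr.fitted(qrX, Yc)
  sum(fitted^2) / sum(Yc^2)
}

#' Ezekiel-adjusted R2
#' @param r2 unadjusted R2
#' @param n number of samples
#' @param p number of predictors
#' @return adjusted R2 (may be negative)
#' @export
adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Redundancy analysis of a community matrix on predictors
#'
#' Fits Y ~ X by multivariate least squares after centering both, reporting
#' the fraction of total community variance explained (R2), its Ezekiel
#' adjustment, and a permutation p-value obtained by freely permuting the
#' rows of Y.
#'
#' @param Y numeric matrix, samples x species (typically Hellinger-transformed)
#' @param X numeric predictor matrix, samples x p (full column rank)
#' @param n_permutations default 999 (0 skips the test)
#' @param seed integer seed
#' @return list of class `rda_result`: `R2`, `adjR2`, `n`, `p`, `p_value`, `seed`
#' @export
rda <- function(Y, X, n_permutations = 999, seed = 1L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); p <- ncol(X)
  if (nrow(X) != n) stop("Y and X must have matching rows")
  if (n <= p + 1) stop("need n > p + 1")
  r2 <- rda_r2(Y, X)
  pval <- NA_real_
  if (n_permutations > 0) {
    null <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
      rda_r2(Y[sample.int(n), , drop = FALSE], X), numeric(1)))
    pval <- (sum(null >= r2 - 1e-12) + 1) / (n_permutations + 1)
  }
  structure(list(R2 = r2, adjR2 = adj_r2(r2, n, p), n = n, p = p,
                 p_value = pval, seed = seed),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.4f, adjR2 = %.4f (n = %d, p = %d predictors), perm p = %.4g\n",
              x$R2, x$adjR2, x$n, x$p, x$p_value))
  invisible(x)
}

#' Iterative VIF-based collinearity filter
#'
#' Repeatedly removes the predictor with the highest variance inflation
#' factor until all VIFs are at or below `threshold` (default 10).
#' Perfectly collinear columns (infinite VIF) are removed first, ties
#' broken by column order.
#'
#' @param X numeric predictor matrix with column names
#' @param threshold maximum tolerated VIF (default 10)
#' @return list: `X` (filtered matrix), `kept`, `removed` (in removal order),
#'   `vif` (final VIFs)
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need >= 2 predictors")
  removed <- character(0)
  repeat {
    v <- vif_values(X)
    if (all(v <= threshold, na.rm = TRUE) && !any(is.infinite(v))) break
    worst <- which.max(ifelse(is.finite(v), v, Inf))
    removed <- c(removed, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
    if (ncol(X) == 1) { v <- c(1); names(v) <- colnames(X); break }
  }
  list(X = X, kept = colnames(X), removed = removed, vif = v)
}

# VIF_j = 1 / (1 - R2_j) from regressing predictor j on the others.
vif_values <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NA_real_)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) -> v
  names(v) <- colnames(X)
  v
}

#' Forward selection of predictors for RDA
#'
#' Blanchet-style forward selection with the double stopping rule: the
#' procedure first requires the global model (all candidates) to be
#' significant at `alpha`; it then adds, at each step, the candidate giving
#' the largest adjusted R2, provided its partial contribution is significant
#' at `alpha` (permutation of Y rows) and the cumulative adjusted R2 does
#' not exceed the global model's adjusted R2.
#'
#' @param Y response matrix (samples x species)
#' @param X candidate predictor matrix with column names
#' @param alpha per-step significance level (default 0.05)
#' @param n_permutations default 999
#' @param seed integer seed
#' @return list of class `forward_selection`: `selected` (ordered names),
#'   `steps` (data.frame variable/adjR2_cum/p), `stopping_reason`
#'   (`"alpha"`, `"global_adjR2"`, `"exhausted"`, or `"global_test_failed"`),
#'   `global_adjR2`, `global_p`
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_permutations = 999, seed = 1L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(Y)
  glob <- rda(Y, X, n_permutations = n_permutations, seed = seed)
  steps <- data.frame(variable = character(0), adjR2_cum = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  if (glob$p_value > alpha)
    return(structure(list(selected = character(0), steps = steps,
                          stopping_reason = "global_test_failed",
                          global_adjR2 = glob$adjR2, global_p = glob$p_value),
                     class = "forward_selection"))
  sel <- character(0)
  reason <- "exhausted"
  seed_i <- as.integer(seed)
  while (length(sel) < ncol(X)) {
    cand <- setdiff(colnames(X), sel)
    if (n <= length(sel) + 2) { reason <- "exhausted"; break }
    a2 <- vapply(cand, function(v)
      adj_r2(rda_r2(Y, X[, c(sel, v), drop = FALSE]), n, length(sel) + 1),
      numeric(1))
    best <- cand[which.max(a2)]
    # partial contribution test: statistic = R2 gain of adding `best`
    base_r2 <- if (length(sel)) rda_r2(Y, X[, sel, drop = FALSE]) else 0
    gain <- rda_r2(Y, X[, c(sel, best), drop = FALSE]) - base_r2
    seed_i <- seed_i + 1L
    null <- with_seed(seed_i, vapply(seq_len(n_permutations), function(b) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      base_p <- if (length(sel)) rda_r2(Yp, X[, sel, drop = FALSE]) else 0
      rda_r2(Yp, X[, c(sel, best), drop = FALSE]) - base_p
    }, numeric(1)))
    p <- (sum(null >= gain - 1e-12) + 1) / (n_permutations + 1)
    if (p > alpha) { reason <- "alpha"; break }
    cum_adj <- max(a2)
    if (cum_adj > glob$adjR2 + 1e-12) { reason <- "global_adjR2"; break }
    sel <- c(sel, best)
    steps <- rbind(steps, data.frame(variable = best, adjR2_cum = cum_adj, p = p))
  }
  structure(list(selected = sel, steps = steps, stopping_reason = reason,
                 global_adjR2 = glob$adjR2, global_p = glob$p_value),
            class = "forward_selection")
}

#' Two-component variation partitioning
#'
#' Partitions the variance of Y (typically a Hellinger-transformed
#' community matrix) into pure environmental \[a\], shared \[b\], pure
#' spatial \[c\], and residual \[d\] adjusted-R2 fractions:
#' a = adjR2(env+spat) - adjR2(spat), b = adjR2(env) + adjR2(spat) -
#' adjR2(env+spat), c = adjR2(env+spat) - adjR2(env), d = 1 - adjR2(env+spat).
#' The testable fractions \[a\] and \[c\] receive permutation p-values from
#' partial RDA (response residualized on the other predictor set, rows of
#' the residuals freely permuted); \[b\] is not independently testable.
#' Negative fractions are reported as-is, never clamped.
#'
#' @param Y response matrix (samples x species)
#' @param X_env environmental predictor matrix
#' @param X_spat spatial predictor matrix (e.g. selected PCNM vectors)
#' @param n_permutations default 999
#' @param seed integer seed
#' @return list of class `varpart_result`: `fractions` (a, b, c, d),
#'   `marginal` (adjR2 of env, spat, combined with p-values), `p_pure_env`,
#'   `p_pure_spat`, `n`, `seed`
#' @export
varpart2 <- function(Y, X_env, X_spat, n_permutations = 999, seed = 1L) {
  Y <- as.matrix(Y)
  X_env <- as.matrix(X_env); X_spat <- as.matrix(X_spat)
  if (!ncol(X_env) || !ncol(X_spat)) stop("both predictor sets must be non-empty")
  n <- nrow(Y)
  env_fit  <- rda(Y, X_env,  n_permutations = n_permutations, seed = seed)
  spat_fit <- rda(Y, X_spat, n_permutations = n_permutations, seed = seed + 1L)
  # the combined model tolerates overlap between the two sets (identical
  # predictors are legitimate); R2 is that of the joint column space, with
  # the Ezekiel adjustment at the space's rank
  Xboth <- cbind(X_env, X_spat)
  rank_both <- qr(scale(Xboth, scale = FALSE))$rank
  if (n <= rank_both + 1) stop("combined model has too many predictors for n")
  r2_both <- rda_r2(Y, Xboth, strict = FALSE)
  null <- with_seed(seed + 2L, vapply(seq_len(max(n_permutations, 1)), function(b)
    rda_r2(Y[sample.int(n), , drop = FALSE], Xboth, strict = FALSE), numeric(1)))
  p_both <- if (n_permutations > 0)
    (sum(null >= r2_both - 1e-12) + 1) / (n_permutations + 1) else NA_real_
  both <- list(adjR2 = adj_r2(r2_both, n, rank_both), p_value = p_both)
  ab <- env_fit$adjR2; bc <- spat_fit$adjR2; abc <- both$adjR2
  a <- abc - bc; b <- ab + bc - abc; c_ <- abc - ab; d <- 1 - abc
  p_a <- partial_rda_p(Y, X_env, X_spat, n_permutations, seed + 3L)
  p_c <- partial_rda_p(Y, X_spat, X_env, n_permutations, seed + 4L)
  structure(list(
    fractions = c(pure_env = a, shared = b, pure_spatial = c_, residual = d),
    marginal = data.frame(
      component = c("env", "spatial", "combined"),
      adjR2 = c(ab, bc, abc),
      p = c(env_fit$p_value, spat_fit$p_value, both$p_value)),
    p_pure_env = p_a, p_pure_spat = p_c, n = n, seed = seed),
    class = "varpart_result")
}

# p-value of the pure fraction of X1 given X2: semi-partial R2 of X1 after
# residualizing Y and X1 on X2, rows of the Y-residuals freely permuted.
partial_rda_p <- function(Y, X1, X2, n_permutations, seed) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  X2c <- scale(as.matrix(X2), scale = FALSE)
  q2 <- qr(X2c)
  Yr <- qr.resid(q2, Yc)
  X1r <- qr.resid(q2, scale(as.matrix(X1), scale = FALSE))
  stat <- function(Yres) {
    f <- qr.fitted(qr(X1r), Yres)
    sum(f^2) / sum(Yc^2)
  }
  obs <- stat(Yr)
  n <- nrow(Yr)
  null <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
    stat(Yr[sample.int(n), , drop = FALSE]), numeric(1)))
  (sum(null >= obs - 1e-12) + 1) / (n_permutations + 1)
}

#' @export
print.varpart_result <- function(x, ...) {
  f <- x$fractions
  cat("Variation partitioning (adjusted R2 fractions):\n")
  cat(sprintf("  Environment [a]  %8.4f   P = %.4g\n", f["pure_env"], x$p_pure_env))
  cat(sprintf("  Spatial     [c]  %8.4f   P = %.4g\n", f["pure_spatial"], x$p_pure_spat))
  cat(sprintf("  Shared      [b]  %8.4f\n", f["shared"]))
  cat(sprintf("  Residual    [d]  %8.4f\n", f["residual"]))
  if (any(f < 0)) cat("  (negative fractions reported as-is; standard for adjusted R2)\n")
  invisible(x)
}
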