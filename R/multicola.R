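#' Multivariate cutoff level analysis (MultiCoLA)
#'
#' Assesses how robust the data-set structure is to the definition of
#' rarity: OTUs are ranked by total abundance and, for each truncation
#' fraction f, the rarest ceiling(f * n_OTUs) OTU types are removed
#' (nested truncation: a larger f removes a superset). The Bray-Curtis
#' matrix of each truncated table is compared with that of the original
#' table, by Spearman rank correlation of the off-diagonal entries
#' (default) and/or by Procrustes m2 between NMDS ordinations.
#'
#' With `direction = "remove_dominant"` the series is inverted: the most
#' abundant types are removed instead, profiling how much structure the
#' rare tail alone retains.
#'
#' @param x an [otu_table] with >= 3 samples
#' @param fractions truncation fractions in \[0, 1)
#' @param comparator `"matrix_spearman"`, `"procrustes"`, or both
#' @param direction `"remove_rare"` (default) or `"remove_dominant"`
#' @param seed integer seed (used by the NMDS restarts for procrustes)
#' @return data.frame of class `multicola_profile` with columns `fraction`,
#'   `n_removed`, `spearman`, `procrustes_m2` (NA where not requested or
#'   undefined); truncations producing an all-zero sample are flagged via
#'   the logical column `undefined`
#' @export
multicola <- function(x, fractions = seq(0, 0.9, by = 0.05),
                      comparator = "matrix_spearman",
                      direction = c("remove_rare", "remove_dominant"),
                      seed = 1L) {
  direction <- match.arg(direction)
  comparator <- match.arg(comparator, c("matrix_spearman", "procrustes"),
                          several.ok = TRUE)
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (any(fractions < 0 | fractions >= 1)) stop("fractions must lie in [0, 1)")
  fractions <- sort(unique(fractions))
  m <- unclass(x)
  tot <- colSums(m)
  # rank rarest-first; ties broken by OTU id for a deterministic nested series
  ord <- order(tot, colnames(m), decreasing = (direction == "remove_dominant"))
  d0 <- bray_curtis(x)
  ref_nmds <- if ("procrustes" %in% comparator)
    nmds(d0, k = 2, n_restarts = 10, seed = seed) else NULL
  out <- data.frame(fraction = fractions, n_removed = NA_integer_,
                    spearman = NA_real_, procrustes_m2 = NA_real_,
                    undefined = FALSE)
  for (i in seq_along(fractions)) {
    n_rm <- ceiling(fractions[i] * ncol(m))
    out$n_removed[i] <- n_rm
    keep <- if (n_rm > 0) sort(ord[-seq_len(n_rm)]) else seq_len(ncol(m))
    sub <- m[, keep, drop = FALSE]
    if (any(rowSums(sub) == 0)) { out$undefined[i] <- TRUE; next }
    d1 <- bray_curtis(otu_table(sub))
    if ("matrix_spearman" %in% comparator) {
      v0 <- dist_vec(d0); v1 <- dist_vec(d1)
      out$spearman[i] <- if (identical(v0, v1)) 1
        else stats::cor(v0, v1, method = "spearman")
    }
    if ("procrustes" %in% comparator) {
      nm1 <- nmds(d1, k = 2, n_restarts = 10, seed = seed)
      out$procrustes_m2[i] <- procrustes_m2(ref_nmds$coordinates, nm1$coordinates)
    }
  }
  class(out) <- c("multicola_profile", "data.frame")
  out
}

# Symmetric Procrustes m2 between two configurations (rows matched).
procrustes_m2 <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  X <- X / sqrt(sum(X^2)); Y <- Y / sqrt(sum(Y^2))
  s <- svd(crossprod(X, Y))
  1 - sum(s$d)^2
}
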