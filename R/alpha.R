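#' Per-sample alpha diversity
#'
#' Computes, for every sample: observed richness, bias-corrected Chao1,
#' ACE (rare-abundance cutoff 10), Shannon-Wiener H' in nats, Pielou's
#' evenness J', Simpson's index of diversity 1 - D, and Good's coverage
#' 1 - F1/N.
#'
#' Chao1 uses the bias-corrected form S_obs + F1(F1-1)/(2(F2+1)), defined
#' even when no doubletons exist. J' is reported as NA for single-OTU
#' samples (ln S = 0).
#'
#' @param x an [otu_table]
#' @return data.frame, one row per sample, columns `richness`, `chao1`,
#'   `ace`, `shannon`, `pielou`, `simpson_1_minus_D`, `goods_coverage`
#' @export
alpha_diversity <- function(x) {
  m <- unclass(x)
  if (any(rowSums(m) == 0))
    stop("empty sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  res <- t(apply(m, 1, function(cts) {
    cts <- cts[cts > 0]
    N <- sum(cts)
    S <- length(cts)
    F1 <- sum(cts == 1); F2 <- sum(cts == 2)
    chao1 <- S + F1 * (F1 - 1) / (2 * (F2 + 1))
    p <- cts / N
    H <- -sum(p * log(p))
    J <- if (S > 1) H / log(S) else NA_real_
    c(richness = S,
      chao1 = chao1,
      ace = ace_estimator(cts),
      shannon = H,
      pielou = J,
      simpson_1_minus_D = 1 - sum(p^2),
      goods_coverage = 1 - F1 / N)
  }))
  as.data.frame(res)
}

# Abundance-based coverage estimator with rare cutoff k = 10.
ace_estimator <- function(cts, k = 10) {
  cts <- cts[cts > 0]
  S_abund <- sum(cts > k)
  rare <- cts[cts <= k]
  S_rare <- length(rare)
  if (S_rare == 0) return(S_abund)
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C_ace <- 1 - F1 / N_rare
  if (C_ace == 0) return(NA_real_)  # all rare reads are singletons; ACE undefined
  Fi <- tabulate(rare, nbins = k)
  g2 <- max(S_rare / C_ace * sum(seq_len(k) * (seq_len(k) - 1) * Fi) /
              (N_rare * (N_rare - 1)) - 1, 0)
  S_abund + S_rare / C_ace + F1 / C_ace * g2
}

#' OTU counts unique to and shared between sample groups
#'
#' Venn-diagram bookkeeping: an OTU is "present" in a group if it has a
#' positive count in at least one of the group's samples.
#'
#' @param x an [otu_table]
#' @param grouping named character/factor vector mapping every sample to a
#'   group label
#' @return list with `per_group` (presence counts per group), `unique`
#'   (per group), `shared_all` (present in every group), `total` (present
#'   overall), and the full presence incidence matrix `presence`
#' @export
shared_otu_counts <- function(x, grouping) {
  grouping <- grouping[rownames(x)]
  if (any(is.na(grouping)))
    stop("grouping missing for sample(s): ",
         paste(rownames(x)[is.na(grouping)], collapse = ", "))
  groups <- unique(as.character(grouping))
  if (length(groups) < 2) stop("need at least 2 groups")
  pres <- vapply(groups, function(g)
    colSums(unclass(x)[grouping == g, , drop = FALSE]) > 0, logical(ncol(x)))
  present_any <- rowSums(pres) > 0
  uniq <- vapply(seq_along(groups), function(k)
    sum(pres[, k] & rowSums(pres) == 1), integer(1))
  names(uniq) <- groups
  list(per_group = colSums(pres),
       unique = uniq,
       shared_all = sum(rowSums(pres) == length(groups)),
       total = sum(present_any),
       presence = pres)
}

#' Aggregate OTUs by taxonomy rank
#'
#' Splits each lineage on ";" and groups OTUs by the component at `rank`
#' (1 = highest). Lineages shallower than `rank`, empty, or absent are
#' binned as "unclassified". Returns both sequence-abundance shares and
#' OTU-richness shares per sample (each summing to 1).
#'
#' @param x an [otu_table] (taxonomy optional; missing taxonomy warns and
#'   bins everything as unclassified)
#' @param rank positive integer lineage depth
#' @return list of two matrices (groups x samples): `abundance_share`,
#'   `richness_share`
#' @export
aggregate_taxonomy <- function(x, rank = 1) {
  tax <- otu_taxonomy(x)
  if (is.null(tax)) {
    warning("no taxonomy present; all OTUs binned as 'unclassified'")
    tax <- rep("", ncol(x))
  }
  parts <- strsplit(tax, ";", fixed = TRUE)
  grp <- vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) >= rank && nzchar(p[rank])) p[rank] else "unclassified"
  }, character(1))
  m <- unclass(x)
  ab <- rowsum(t(m), grp)                       # groups x samples, sequence counts
  pres <- rowsum((t(m) > 0) + 0, grp)           # groups x samples, OTU counts
  list(abundance_share = sweep(ab, 2, colSums(ab), "/"),
       richness_share = sweep(pres, 2, colSums(pres), "/"))
}
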