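#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, the
#' standard normalization before comparing samples of unequal sequencing
#' effort. Samples whose total is below `depth` are an error: dropping
#' shallow samples must be an explicit caller action.
#'
#' @param x an [otu_table]
#' @param depth positive integer target depth
#' @param seed integer seed (mandatory; recorded in the result)
#' @return rarefied [otu_table] with attributes `rarefaction_depth` and `seed`
#' @export
rarefy <- function(x, depth, seed) {
  stopifnot(depth >= 1, depth == round(depth))
  tot <- sample_totals(x)
  shallow <- names(tot)[tot < depth]
  if (length(shallow))
    stop("samples shallower than depth ", depth, ": ",
         paste(shallow, collapse = ", "),
         " (drop them explicitly before rarefying)")
  out <- unclass(x)
  with_seed(seed, {
    for (i in seq_len(nrow(out))) {
      if (tot[i] == depth) next
      picked <- sample.int(tot[i], depth)  # which of the reads survive
      cum <- cumsum(out[i, ])
      # read index r belongs to OTU j with cum[j-1] < r <= cum[j]
      otu_of <- findInterval(picked, cum, left.open = TRUE) + 1L
      out[i, ] <- tabulate(otu_of, nbins = ncol(out))
    }
  })
  res <- otu_table(out, taxonomy = otu_taxonomy(x))
  attr(res, "rarefaction_depth") <- as.integer(depth)
  attr(res, "seed") <- as.integer(seed)
  res
}

#' Expected or Monte-Carlo rarefaction curves
#'
#' Expected OTU richness per sample at each depth. Analytic mode uses the
#' hypergeometric expectation E[S(d)] = sum_j (1 - C(N - c_j, d) / C(N, d));
#' Monte-Carlo mode averages observed richness over `reps` independent
#' subsamples.
#'
#' @param x an [otu_table]
#' @param depths increasing vector of depths (each <= every sample total)
#' @param mode `"analytic"` or `"montecarlo"`
#' @param reps Monte-Carlo replicates
#' @param seed integer seed (Monte-Carlo mode)
#' @return matrix samples x depths of expected richness
#' @export
rarefaction_curve <- function(x, depths, mode = c("analytic", "montecarlo"),
                              reps = 100, seed = NULL) {
  mode <- match.arg(mode)
  depths <- as.integer(depths)
  stopifnot(all(depths >= 1), !is.unsorted(depths))
  tot <- sample_totals(x)
  if (any(depths > min(tot)))
    stop("depth exceeds the total of sample(s): ",
         paste(names(tot)[tot < max(depths)], collapse = ", "))
  out <- matrix(NA_real_, nrow(x), length(depths),
                dimnames = list(rownames(x), as.character(depths)))
  if (mode == "analytic") {
    for (i in seq_len(nrow(x))) {
      c_j <- unclass(x)[i, ]
      c_j <- c_j[c_j > 0]
      N <- tot[i]
      for (k in seq_along(depths)) {
        d <- depths[k]
        # P(OTU j absent from subsample) = C(N - c_j, d)/C(N, d), in log space
        lp_absent <- ifelse(N - c_j >= d,
                            lchoose(N - c_j, d) - lchoose(N, d), -Inf)
        out[i, k] <- sum(1 - exp(lp_absent))
      }
    }
  } else {
    with_seed(seed, {
      for (i in seq_len(nrow(x))) {
        c_j <- unclass(x)[i, ]
        reads <- rep.int(seq_along(c_j), c_j)
        for (k in seq_along(depths)) {
          rich <- numeric(reps)
          for (r in seq_len(reps))
            rich[r] <- length(unique(reads[sample.int(length(reads), depths[k])]))
          out[i, k] <- mean(rich)
        }
      }
    })
  }
  out
}
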