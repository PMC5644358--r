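#' Occurrence frequency and regional mean abundance per OTU
#'
#' Builds the input of the Sloan neutral community model from a table
#' rarefied to equal depth N: for each OTU, p = mean relative abundance
#' across samples (its regional metacommunity abundance) and f_obs = the
#' fraction of samples in which it is detected (count > 0). OTUs with zero
#' total count are dropped. The detection limit is d = 1/N (one read).
#'
#' @param x an [otu_table] with all sample totals equal
#' @return data.frame of class `ncm_input` with columns `otu_id`, `p`,
#'   `f_obs`, and attributes `N` (reads per sample), `d`, `n_samples`
#' @export
occurrence_frequency <- function(x) {
  tot <- sample_totals(x)
  if (length(unique(tot)) != 1)
    stop("samples have unequal depths (", min(tot), "-", max(tot),
         "); rarefy to even depth first")
  N <- unname(tot[1])
  m <- unclass(x)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  out <- data.frame(otu_id = colnames(m),
                    p = colMeans(m) / N,
                    f_obs = colMeans(m > 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, N = N, d = 1 / N, n_samples = nrow(m),
            class = c("ncm_input", "data.frame"))
}

#' Neutral-model predicted occurrence frequency
#'
#' Under Sloan's neutral model, the long-run local relative abundance of a
#' taxon with metacommunity abundance p follows Beta(Nm p, Nm (1 - p)), so
#' the probability of detecting it above the detection limit d is
#' 1 - I_d(Nm p, Nm (1 - p)), the upper tail of the regularized incomplete
#' beta function. Monotone increasing in p, and in Nm for p > d.
#'
#' @param p metacommunity relative abundance(s), in (0, 1)
#' @param Nm metacommunity size times immigration rate (> 0)
#' @param d detection limit, in (0, 1) (1/N for one read at depth N)
#' @return predicted occurrence frequency in \[0, 1\]
#' @export
ncm_predict <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (Nm <= 0) stop("Nm must be positive")
  if (d <= 0 || d >= 1) stop("d must lie in (0, 1)")
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan neutral community model
#'
#' Estimates Nm by least squares: minimizes the sum of squared differences
#' between observed occurrence frequencies and [ncm_predict] over
#' log(Nm) in \[log 1, log 1e8\] (coarse grid scan then bounded
#' optimization around the best grid point). Goodness of fit is the
#' non-linear R2 about the mean of f_obs, which can be negative when the
#' data do not follow the neutral expectation. 95% bands around the
#' prediction are Wilson binomial intervals at n_samples trials, and each
#' OTU is partitioned as above / neutral / below the bands.
#'
#' @param input an `ncm_input` from [occurrence_frequency]
#' @return list of class `ncm_fit`: `Nm`, `m` (= Nm/N), `N`, `d`, `R2`,
#'   `n_otus`, `n_samples`, `partition_counts`, `boundary_warning`, and
#'   `per_otu` (data.frame: otu_id, p, f_obs, f_pred, ci_low, ci_high,
#'   partition)
#' @export
fit_ncm <- function(input) {
  if (nrow(input) < 10) stop("need >= 10 OTUs to fit")
  N <- attr(input, "N"); d <- attr(input, "d"); nsamp <- attr(input, "n_samples")
  p <- input$p; f <- input$f_obs
  sse <- function(logNm) sum((f - ncm_predict(p, exp(logNm), d))^2)
  lo <- log(1); hi <- log(1e8)
  grid <- seq(lo, hi, length.out = 60)
  g_sse <- vapply(grid, sse, numeric(1))
  i <- which.min(g_sse)
  opt <- stats::optimize(sse, lower = grid[max(1, i - 1)],
                         upper = grid[min(length(grid), i + 1)], tol = 1e-10)
  boundary <- opt$minimum <= lo + 1e-6 || opt$minimum >= hi - 1e-6
  Nm <- exp(opt$minimum)
  f_pred <- ncm_predict(p, Nm, d)
  R2 <- 1 - opt$objective / sum((f - mean(f))^2)
  ci <- wilson_interval(f_pred, nsamp)
  partition <- ifelse(f > ci[, 2], "above", ifelse(f < ci[, 1], "below", "neutral"))
  per_otu <- data.frame(otu_id = input$otu_id, p = p, f_obs = f, f_pred = f_pred,
                        ci_low = ci[, 1], ci_high = ci[, 2],
                        partition = partition, stringsAsFactors = FALSE)
  structure(list(Nm = Nm, m = Nm / N, N = N, d = d, R2 = R2,
                 n_otus = nrow(input), n_samples = nsamp,
                 partition_counts = table(factor(partition,
                   levels = c("above", "neutral", "below"))),
                 boundary_warning = boundary, per_otu = per_otu),
            class = "ncm_fit")
}

# Wilson 95% interval for a proportion `prob` estimated from n trials.
wilson_interval <- function(prob, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (prob + z^2 / (2 * n)) / denom
  half <- z * sqrt(prob * (1 - prob) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: Nm = %.0f (m = %.4f at N = %d), R2 = %.3f\n",
              x$Nm, x$m, x$N, x$R2))
  cat(sprintf("  %d OTUs over %d samples: %d above / %d neutral / %d below the 95%% bands\n",
              x$n_otus, x$n_samples, x$partition_counts["above"],
              x$partition_counts["neutral"], x$partition_counts["below"]))
  if (x$boundary_warning) cat("  warning: optimizer at parameter bound\n")
  invisible(x)
}

#' Serialize an NCM fit
#'
#' Writes the summary as JSON and the per-OTU table (enough to redraw the
#' occurrence-frequency figure) as TSV.
#'
#' @param fit an `ncm_fit`
#' @param json_path,tsv_path output paths (NULL to skip either)
#' @export
write_ncm_fit <- function(fit, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    write_json_report(list(Nm = fit$Nm, m = fit$m, N = fit$N, d = fit$d,
                           R2 = fit$R2, n_otus = fit$n_otus,
                           n_samples = fit$n_samples,
                           partition_counts = as.list(fit$partition_counts),
                           boundary_warning = fit$boundary_warning), json_path)
  if (!is.null(tsv_path))
    utils::write.table(fit$per_otu, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fit)
}
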