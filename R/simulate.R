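# Synthetic metacommunity generators. Every function is a pure function of
# its arguments and seed; together they provide ground truth for each
# analysis stage (neutral-model fitting, distance decay, variation
# partitioning) without any real sequence data.

#' Simulate a metacommunity relative-abundance vector
#'
#' Species abundances drawn from a log-series (logarithmic distribution
#' with parameter `x`) or lognormal(meanlog, sdlog) species-abundance
#' distribution, then normalized to sum to 1.
#'
#' @param n_species number of species
#' @param dist `"lognormal"` (default) or `"logseries"`
#' @param meanlog,sdlog lognormal parameters (sdlog = 0 gives a uniform vector)
#' @param x logarithmic-distribution parameter in (0, 1); larger x gives a
#'   longer rare tail
#' @param seed integer seed
#' @return numeric vector summing to 1, named sp0001...
#' @export
simulate_metacommunity <- function(n_species, dist = c("lognormal", "logseries"),
                                   meanlog = 0, sdlog = 1.5, x = 0.999,
                                   seed = 1L) {
  dist <- match.arg(dist)
  stopifnot(n_species >= 1)
  ab <- with_seed(seed, {
    if (dist == "lognormal") {
      if (sdlog < 0) stop("sdlog must be >= 0")
      stats::rlnorm(n_species, meanlog, sdlog)
    } else {
      if (x <= 0 || x >= 1) stop("logseries parameter x must lie in (0, 1)")
      rlogarithmic(n_species, x)
    }
  })
  p <- ab / sum(ab)
  names(p) <- sprintf("sp%04d", seq_len(n_species))
  p
}

# Logarithmic-series distribution sampler (inversion on the pmf
# P(k) = -x^k / (k log(1 - x))), with a tail cutoff where the cdf
# numerically reaches 1.
rlogarithmic <- function(n, x) {
  kmax <- 10
  repeat {
    k <- seq_len(kmax)
    pmf <- -x^k / (k * log(1 - x))
    if (sum(pmf) > 1 - 1e-12 || kmax > 1e7) break
    kmax <- kmax * 10
  }
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(stats::runif(n), cdf) + 1L
}

#' Simulate neutral local communities
#'
#' Sloan's neutral model in stationarity: each site's local composition is
#' drawn from Dirichlet(N m p) — whose margins are the model's
#' Beta(Nmp, Nm(1-p)) — and reads are a Multinomial(N, composition) draw.
#'
#' @param p metacommunity relative-abundance vector (sums to 1)
#' @param m immigration rate in (0, 1\]
#' @param N reads (individuals) per site
#' @param n_sites number of local communities
#' @param seed integer seed
#' @param site_ids optional sample identifiers
#' @return an [otu_table] (n_sites x length(p))
#' @export
simulate_neutral_communities <- function(p, m, N, n_sites, seed = 1L,
                                         site_ids = NULL) {
  stopifnot(abs(sum(p) - 1) < 1e-8, m > 0, N >= 1, n_sites >= 1)
  if (is.null(names(p))) names(p) <- sprintf("sp%04d", seq_along(p))
  if (is.null(site_ids)) site_ids <- sprintf("site%03d", seq_len(n_sites))
  alpha <- N * m * p
  counts <- with_seed(seed, {
    t(vapply(seq_len(n_sites), function(i) {
      g <- stats::rgamma(length(p), shape = alpha, rate = 1)
      if (sum(g) == 0) g[sample.int(length(p), 1, prob = p)] <- 1
      stats::rmultinom(1, N, g / sum(g))[, 1]
    }, integer(length(p))))
  })
  dimnames(counts) <- list(site_ids, names(p))
  otu_table(counts)
}

#' Simulate niche-structured local communities
#'
#' Deterministic (environmental-filtering) alternative to the neutral
#' generator: at each site the sampling weight of species j is
#' p_j * \[exp(-(env - optimum_j)^2 / (2 breadth_j^2))\]^w, renormalized,
#' and reads are Multinomial(N, weights). `w` interpolates between pure
#' mass-effects sampling of the metacommunity (w = 0) and pure niche
#' assembly (w = 1).
#'
#' @param p metacommunity relative-abundance vector
#' @param env numeric vector of the environmental value at each site
#' @param optima per-species environmental optima (recycled if length 1)
#' @param breadth per-species Gaussian niche breadth (same units as env)
#' @param w niche weight in \[0, 1\]
#' @param N reads per site
#' @param seed integer seed
#' @param site_ids optional sample identifiers
#' @return an [otu_table] (length(env) x length(p))
#' @export
simulate_niche_communities <- function(p, env, optima, breadth, w, N,
                                       seed = 1L, site_ids = NULL) {
  stopifnot(abs(sum(p) - 1) < 1e-8, w >= 0, w <= 1, N >= 1)
  if (any(is.na(env))) stop("env values required for all sites")
  S <- length(p)
  optima <- rep_len(optima, S)
  breadth <- rep_len(breadth, S)
  if (is.null(names(p))) names(p) <- sprintf("sp%04d", seq_len(S))
  if (is.null(site_ids)) site_ids <- sprintf("site%03d", seq_along(env))
  counts <- with_seed(seed, {
    t(vapply(seq_along(env), function(i) {
      logfit <- -(env[i] - optima)^2 / (2 * breadth^2)
      wts <- p * exp(w * logfit)
      if (sum(wts) == 0) stop("zero total sampling weight at site ", site_ids[i])
      stats::rmultinom(1, N, wts / sum(wts))[, 1]
    }, integer(S)))
  })
  dimnames(counts) <- list(site_ids, names(p))
  otu_table(counts)
}

#' Spatially autocorrelated environmental gradient
#'
#' Gaussian-kernel smoothing of site-level white noise: values at sites
#' closer than `range` (in the units of `coords`/`geo_dm`) are strongly
#' correlated, distant sites are independent.
#'
#' @param geo_dm `dist` of between-site distances
#' @param range autocorrelation range (same units as geo_dm)
#' @param seed integer seed
#' @return numeric vector (z-scored) named by site
#' @export
simulate_env_gradient <- function(geo_dm, range, seed = 1L) {
  D <- as.matrix(as_dist_checked(geo_dm))
  K <- exp(-(D / range)^2 / 2)
  z <- with_seed(seed, stats::rnorm(nrow(D)))
  g <- as.vector(K %*% z)
  g <- (g - mean(g)) / stats::sd(g)
  names(g) <- rownames(D)
  g
}

#' Simulate the two-habitat 24-site study layout
#'
#' Emulates a ring of 24 coastal sites around a ~10 km-diameter island:
#' 12 "water" and 12 "sediment" samples, each habitat organized as 4
#' stations of 3 nearby replicates. Environmental variables are drawn
#' inside habitat-specific ranges typical of a subtropical coastal contrast
#' (warm, nutrient-rich sediment pore water vs cooler, alkaline seawater):
#' temperature water 28.1-30.2 vs sediment 31.5-33.9 degC; salinity means
#' 26.4 vs 25.0 psu; pH means 9.35 vs 7.97; TN means 0.57 vs 3.07 mg/L;
#' TP means 0.018 vs 0.112 mg/L, all with small jitter.
#'
#' @param seed integer seed
#' @param center_lon,center_lat ring center in decimal degrees
#' @return metadata data.frame (24 rows) as from [validate_metadata]
#' @export
simulate_study_layout <- function(seed = 1L, center_lon = 118.10,
                                  center_lat = 24.48) {
  radius_km <- 5
  km_per_deg_lat <- 111.195
  km_per_deg_lon <- km_per_deg_lat * cos(center_lat * pi / 180)
  with_seed(seed, {
    # 8 stations interleaved around the ring: water N,E,S,W; sediment A,B,C,D
    station_angle <- (0:7) * 2 * pi / 8
    habitat <- rep(c("water", "sediment"), 4)
    station <- c("N", "A", "E", "B", "S", "C", "W", "D")
    rows <- list()
    for (s in seq_len(8)) for (r in 1:3) {
      ang <- station_angle[s] + stats::rnorm(1, 0, 0.02)
      rad <- radius_km * (1 + stats::rnorm(1, 0, 0.02))
      hw <- habitat[s] == "water"
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0(station[s], r),
        habitat = habitat[s],
        longitude = center_lon + rad * sin(ang) / km_per_deg_lon,
        latitude = center_lat + rad * cos(ang) / km_per_deg_lat,
        temperature = if (hw) stats::runif(1, 28.1, 30.2) else stats::runif(1, 31.5, 33.9),
        salinity = (if (hw) 26.4 else 25.0) * (1 + stats::rnorm(1, 0, 0.02)),
        pH = (if (hw) 9.35 else 7.97) + stats::rnorm(1, 0, 0.05),
        TN = (if (hw) 0.57 else 3.07) * (1 + stats::rnorm(1, 0, 0.08)),
        TP = (if (hw) 0.018 else 0.112) * (1 + stats::rnorm(1, 0, 0.08)),
        stringsAsFactors = FALSE)
    }
    validate_metadata(do.call(rbind, rows))
  })
}

#' Simulate a complete dataset (counts + metadata + truth)
#'
#' Convenience wrapper tying the generators together: builds the 24-site
#' two-habitat layout (or a smaller ring), a metacommunity, a spatially
#' autocorrelated gradient, and counts that interpolate between neutral
#' (w = 0, immigration m) and niche (w = 1) assembly.
#'
#' @param n_species metacommunity richness
#' @param m immigration rate used for the neutral component
#' @param N reads per sample
#' @param w niche weight in \[0, 1\]
#' @param seed integer seed
#' @param layout `"paper_like"` (24 sites) or an integer site count for a
#'   plain ring with a single habitat
#' @return list of class `synthetic_dataset`: `table` ([otu_table]),
#'   `metadata`, `truth` (p, m, w, optima, breadth, env gradient, seed)
#' @export
simulate_dataset <- function(n_species = 2000, m = 0.1, N = 5000, w = 0,
                             seed = 1L, layout = "paper_like") {
  md <- if (identical(layout, "paper_like")) simulate_study_layout(seed) else {
    n <- as.integer(layout)
    ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
    validate_metadata(data.frame(
      sample_id = sprintf("site%03d", seq_len(n)),
      habitat = rep(c("water", "sediment"), each = ceiling(n / 2))[seq_len(n)],
      longitude = 118.10 + 0.045 * sin(ang), latitude = 24.48 + 0.045 * cos(ang),
      stringsAsFactors = FALSE))
  }
  p <- simulate_metacommunity(n_species, seed = seed + 1L)
  gd <- geographic_distance(md)
  env <- simulate_env_gradient(gd, range = 4, seed = seed + 2L)
  # measured covariates on a positive, temperature-like scale:
  # the true gradient, a noisy correlate of it, and pure noise
  md$env1 <- round(25 + 2 * env, 6)
  md$env2 <- round(25 + 2 * env + with_seed(seed + 6L, stats::rnorm(nrow(md))), 6)
  md$env3 <- round(25 + 2 * with_seed(seed + 7L, stats::rnorm(nrow(md))), 6)
  md <- validate_metadata(md)
  optima <- with_seed(seed + 3L, stats::runif(n_species, -2, 2))
  breadth <- 1
  tab <- if (w == 0)
    simulate_neutral_communities(p, m, N, nrow(md), seed = seed + 4L,
                                 site_ids = md$sample_id)
  else
    simulate_niche_communities(p, env, optima, breadth, w, N,
                               seed = seed + 5L, site_ids = md$sample_id)
  structure(list(table = tab, metadata = md,
                 truth = list(p = p, m = m, w = w, optima = optima,
                              breadth = breadth, env = env, seed = seed)),
            class = "synthetic_dataset")
}
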