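#' Build an analysis configuration
#'
#' Collects the knobs of the end-to-end workflow in one list that
#' round-trips losslessly through JSON. Subsetting (e.g. excluding named
#' outlier samples before re-analysis) is a first-class concept.
#'
#' @param otu_table_path path to an OTU table TSV
#' @param metadata_path path to a metadata CSV/TSV
#' @param out_dir output directory for the report bundle
#' @param rarefaction_depth target depth (NULL = table already even-depth)
#' @param rare_thresh,abund_thresh category thresholds (fractions)
#' @param exclude_samples character vector of sample ids to drop before
#'   every analysis
#' @param group_by metadata column defining groups for ANOSIM/Venn (default
#'   `"habitat"`)
#' @param n_permutations permutation count for all tests
#' @param multicola_fractions truncation grid
#' @param nmds_restarts random restarts for NMDS
#' @param seed master integer seed (every stage derives its own from it)
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(otu_table_path, metadata_path, out_dir,
                            rarefaction_depth = NULL,
                            rare_thresh = 1e-4, abund_thresh = 1e-2,
                            exclude_samples = character(0),
                            group_by = "habitat",
                            n_permutations = 999,
                            multicola_fractions = seq(0, 0.9, by = 0.05),
                            nmds_restarts = 50,
                            seed = 1L) {
  structure(list(otu_table_path = otu_table_path, metadata_path = metadata_path,
                 out_dir = out_dir, rarefaction_depth = rarefaction_depth,
                 rare_thresh = rare_thresh, abund_thresh = abund_thresh,
                 exclude_samples = as.character(exclude_samples),
                 group_by = group_by, n_permutations = n_permutations,
                 multicola_fractions = multicola_fractions,
                 nmds_restarts = nmds_restarts, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Write / read an analysis configuration (JSON)
#' @param config an `analysis_config`
#' @param path JSON path
#' @export
write_analysis_config <- function(config, path) {
  write_json_report(unclass(config), path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$exclude_samples <- as.character(x$exclude_samples)
  do.call(analysis_config, x)
}

#' Run the full analysis pipeline
#'
#' Executes, from an [analysis_config]: rarefaction, alpha diversity,
#' abundance-category classification (+ MultiCoLA), Bray-Curtis / NMDS /
#' ANOSIM, Mantel tables per category subset (all / dominant / RT / CRT)
#' against geographic and environmental distance, PCNM + VIF + forward
#' selection + two-component variation partitioning, and neutral-model
#' fits (all samples and per group). All tables are written as TSV and all
#' summaries as JSON under `config$out_dir`; the run manifest records
#' inputs, parameters and seeds. Reports are byte-identical across reruns
#' with the same config.
#'
#' @param config an [analysis_config]
#' @return invisibly, a named list of the in-memory results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[pipeline] ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tab <- stage("read", read_otu_table(config$otu_table_path))
  md <- stage("metadata", read_sample_metadata(config$metadata_path))
  if (length(config$exclude_samples)) {
    keep <- setdiff(rownames(tab), config$exclude_samples)
    tab <- tab[keep, ]
    md <- validate_metadata(md[md$sample_id %in% keep, , drop = FALSE])
  }
  md <- validate_metadata(md[rownames(tab), , drop = FALSE])
  if (!is.null(config$rarefaction_depth))
    tab <- stage("rarefy", rarefy(tab, config$rarefaction_depth, seed = config$seed))
  empty <- colSums(unclass(tab)) == 0
  if (any(empty)) {
    message("[pipeline] dropping ", sum(empty), " zero-count OTUs")
    tab <- tab[, !empty]
  }
  out <- list(config = config)
  grp <- stats::setNames(md[[config$group_by]], md$sample_id)

  out$alpha <- stage("alpha", alpha_diversity(tab))
  utils::write.table(data.frame(sample_id = rownames(out$alpha), out$alpha),
                     file.path(config$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$categories <- stage("classify",
    classify_otus(tab, config$rare_thresh, config$abund_thresh))
  write_category_assignment(out$categories,
                            file.path(config$out_dir, "otu_categories.tsv"))
  out$multicola <- stage("multicola",
    multicola(tab, fractions = config$multicola_fractions, seed = config$seed))
  utils::write.table(out$multicola, file.path(config$out_dir, "multicola.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$bray <- stage("bray_curtis", bray_curtis(tab))
  write_dist_tsv(out$bray, file.path(config$out_dir, "bray_curtis.tsv"))
  out$nmds <- stage("nmds",
    nmds(out$bray, k = 2, n_restarts = config$nmds_restarts, seed = config$seed))
  utils::write.table(
    data.frame(sample_id = rownames(out$nmds$coordinates), out$nmds$coordinates),
    file.path(config$out_dir, "nmds_coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  out$anosim <- stage("anosim",
    anosim(out$bray, grp, n_permutations = config$n_permutations,
           seed = config$seed))

  geo <- stage("geographic_distance", geographic_distance(md))
  env <- stage("env_distance", env_distance(md))
  subsets <- category_subsets(tab, out$categories)
  out$mantel_table <- stage("mantel", {
    rows <- list()
    for (nm in names(subsets)) {
      sub <- subsets[[nm]]
      if (is.null(sub)) next
      bc <- bray_curtis(sub)
      for (against in c("geographic", "environmental")) {
        dm <- if (against == "geographic") geo else env
        mt <- mantel(1 - bc, dm, n_permutations = config$n_permutations,
                     tail = "two", seed = config$seed)
        rows[[length(rows) + 1]] <- data.frame(
          subset = nm, predictor = against, r = mt$r, p = mt$p_value,
          n_permutations = mt$n_permutations)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.table(out$mantel_table, file.path(config$out_dir, "mantel_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$varpart <- stage("varpart", {
    res <- list()
    for (nm in names(subsets)) {
      sub <- subsets[[nm]]
      if (is.null(sub)) next
      res[[nm]] <- varpart_workflow(sub, md, geo,
                                    n_permutations = config$n_permutations,
                                    seed = config$seed)
    }
    res
  })
  write_json_report(lapply(out$varpart, varpart_report),
                    file.path(config$out_dir, "varpart.json"))

  out$ncm <- stage("ncm", {
    fits <- list(all = fit_ncm(occurrence_frequency(tab)))
    for (g in unique(as.character(grp))) {
      sub <- tab[names(grp)[grp == g], ]
      sub <- sub[, colSums(unclass(sub)) > 0]
      if (nrow(sub) >= 3) fits[[g]] <- fit_ncm(occurrence_frequency(sub))
    }
    fits
  })
  for (nm in names(out$ncm))
    write_ncm_fit(out$ncm[[nm]],
                  json_path = file.path(config$out_dir, paste0("ncm_", nm, ".json")),
                  tsv_path = file.path(config$out_dir, paste0("ncm_", nm, ".tsv")))

  params <- unclass(config)
  params$out_dir <- NULL  # reports are location-independent
  manifest <- list(
    inputs = list(otu_table = basename(config$otu_table_path),
                  metadata = basename(config$metadata_path)),
    parameters = params,
    n_samples = nrow(tab), n_otus = ncol(tab),
    anosim = list(global_R = out$anosim$global_R, p = out$anosim$p_value),
    nmds_stress = out$nmds$stress,
    category_counts = as.list(table(out$categories)))
  write_json_report(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(out)
}

# Per-category OTU subsets used in the Mantel and varpart tables; subsets
# with too few OTUs or an all-zero sample are skipped (NULL).
category_subsets <- function(tab, categories) {
  pick <- function(ids) {
    if (length(ids) < 3) return(NULL)
    sub <- tab[, ids]
    if (any(rowSums(unclass(sub)) == 0)) return(NULL)
    sub
  }
  list(all = tab,
       dominant = pick(combine_dominant(categories)),
       RT = pick(names(categories)[categories == "RT"]),
       CRT = pick(names(categories)[categories == "CRT"]))
}

# PCNM + VIF + forward selection + varpart2 for one community subset.
varpart_workflow <- function(tab, md, geo, n_permutations = 999, seed = 1L) {
  Y <- hellinger_transform(tab)
  env_vars <- attr(md, "env_vars")
  if (is.null(env_vars) || !length(env_vars))
    stop("no environmental variables in metadata")
  X_env <- as.matrix(md[rownames(Y), env_vars, drop = FALSE])
  for (v in env_vars) if (!identical(tolower(v), "ph"))
    X_env[, v] <- sqrt(pmax(X_env[, v], 0))
  X_env <- scale(X_env)
  X_spat <- pcnm(geo)$vectors[rownames(Y), , drop = FALSE]
  n <- nrow(Y)
  cap <- max(2, n - 3)  # keep models estimable at small n
  keep_env <- if (ncol(X_env) >= 2) vif_filter(X_env)$kept else colnames(X_env)
  X_env <- X_env[, keep_env, drop = FALSE]
  sel_env <- forward_select(Y, X_env, n_permutations = n_permutations, seed = seed)
  sel_spat <- forward_select(Y, X_spat, n_permutations = n_permutations,
                             seed = seed + 1L)
  env_sel <- sel_env$selected
  spat_sel <- sel_spat$selected
  # fall back to the single best predictor if selection returned nothing,
  # so the partition is always computable (flagged in the report)
  fallback <- character(0)
  if (!length(env_sel)) {
    fallback <- c(fallback, "env")
    a2 <- apply(X_env, 2, function(v) rda_r2(Y, cbind(v)))
    env_sel <- colnames(X_env)[which.max(a2)]
  }
  if (!length(spat_sel)) {
    fallback <- c(fallback, "spatial")
    a2 <- apply(X_spat, 2, function(v) rda_r2(Y, cbind(v)))
    spat_sel <- colnames(X_spat)[which.max(a2)]
  }
  env_sel <- utils::head(env_sel, cap)
  spat_sel <- utils::head(spat_sel, cap)
  vp <- varpart2(Y, X_env[, env_sel, drop = FALSE],
                 X_spat[, spat_sel, drop = FALSE],
                 n_permutations = n_permutations, seed = seed + 2L)
  vp$selected_env <- env_sel
  vp$selected_spatial <- spat_sel
  vp$selection_fallback <- fallback
  vp
}

varpart_report <- function(vp) {
  list(fractions = as.list(vp$fractions),
       p_pure_env = vp$p_pure_env, p_pure_spat = vp$p_pure_spat,
       selected_env = vp$selected_env, selected_spatial = vp$selected_spatial,
       selection_fallback = vp$selection_fallback, n = vp$n)
}

#' Generate a synthetic fixture dataset on disk
#'
#' `tiny` = 8 sites x 200 OTUs x 500 reads (seconds to analyse);
#' `paper_like` = 24 sites x ~6000 OTUs x 33996 reads (the full-scale
#' two-habitat design).
#'
#' @param dir output directory
#' @param scale `"tiny"` or `"paper_like"`
#' @param seed integer seed
#' @return list of paths: `otu_table`, `metadata`, `truth`
#' @export
generate_fixtures <- function(dir, scale = c("tiny", "paper_like"), seed = 1L) {
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- if (scale == "tiny")
    simulate_dataset(n_species = 200, m = 0.1, N = 500, w = 0.5, seed = seed,
                     layout = 8L)
  else
    simulate_dataset(n_species = 6000, m = 0.1, N = 33996, w = 0.5, seed = seed,
                     layout = "paper_like")
  paths <- list(otu_table = file.path(dir, "otu_table.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                truth = file.path(dir, "truth.json"))
  write_otu_table(ds$table, paths$otu_table)
  write_sample_metadata(ds$metadata, paths$metadata)
  write_json_report(list(m = ds$truth$m, w = ds$truth$w, seed = ds$truth$seed,
                         n_species = length(ds$truth$p)),
                    paths$truth)
  paths
}
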