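# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Every randomized operation in the package
# funnels through this, so results are reproducible per call and calls do
# not perturb each other.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Coerce a square labeled matrix or dist to a validated "dist" object.
as_dist_checked <- function(m, name = "distance matrix") {
  if (inherits(m, "dist")) {
    if (is.null(attr(m, "Labels"))) stop(name, " must carry sample labels")
    return(m)
  }
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(name, " must be square")
  if (is.null(rownames(m))) stop(name, " must carry sample labels")
  if (max(abs(m - t(m))) > 1e-12) stop(name, " must be symmetric")
  if (any(diag(m) != 0)) stop(name, " must have a zero diagonal")
  stats::as.dist(m)
}

# Align dmB's labels onto dmA's ordering; error on mismatch.
align_dist <- function(dmA, dmB, nameB = "second matrix") {
  la <- attr(dmA, "Labels"); lb <- attr(dmB, "Labels")
  if (!setequal(la, lb))
    stop(nameB, " labels do not match: ",
         paste(union(setdiff(la, lb), setdiff(lb, la)), collapse = ", "))
  if (identical(la, lb)) return(dmB)
  stats::as.dist(as.matrix(dmB)[la, la])
}

# Off-diagonal lower-triangle vector of a dist (the n(n-1)/2 pairs).
dist_vec <- function(dm) as.vector(dm)

#' Write a labeled square distance matrix as TSV
#' @param dm a `dist` or square labeled matrix
#' @param path output path
#' @export
write_dist_tsv <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix from TSV
#' @param path path written by [write_dist_tsv]
#' @return a `dist` object
#' @export
read_dist_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as_dist_checked(as.matrix(df))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
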