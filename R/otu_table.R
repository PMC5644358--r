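#' Construct an OTU table
#'
#' An `otu_table` is an integer count matrix with samples in rows and OTUs in
#' columns, optionally carrying a taxonomy lineage string per OTU. It is the
#' central container of the package: every downstream analysis (diversity,
#' classification, ordination, neutral-model fitting) consumes one.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs.
#'   Row names are sample identifiers, column names OTU identifiers; both are
#'   mandatory and must be unique.
#' @param taxonomy optional character vector of semicolon-delimited lineage
#'   strings, one per OTU (named or in column order).
#' @return an object of class `otu_table`: the integer matrix with a
#'   `taxonomy` attribute.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("counts must be non-negative integers; offending cell sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) taxonomy <- taxonomy[colnames(counts)]
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy must have one entry per OTU")
    taxonomy <- as.character(taxonomy)
    names(taxonomy) <- colnames(counts)
  }
  structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads total%s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ","),
              if (is.null(attr(x, "taxonomy"))) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  tax <- attr(x, "taxonomy")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    if (!is.null(tax)) tax <- tax[colnames(out)]
    out <- structure(out, taxonomy = tax, class = class(x))
  }
  out
}

#' Taxonomy accessor
#' @param x an `otu_table`
#' @return named character vector of lineages, or NULL
#' @export
otu_taxonomy <- function(x) attr(x, "taxonomy")

sample_totals <- function(x) rowSums(unclass(x))

#' Read an OTU table from a tab-separated file
#'
#' Expected dialect: header row of OTU ids, first column sample ids
#' (samples-in-rows). A final column named `taxonomy` holds semicolon
#' delimited lineages (QIIME-classic style: then the file is OTUs-in-rows
#' and you should pass `orientation = "otus_in_rows"`).
#'
#' @param path file path
#' @param orientation `"samples_in_rows"` (default) or `"otus_in_rows"`
#' @return an [otu_table]
#' @export
read_otu_table <- function(path, orientation = c("samples_in_rows", "otus_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, quote = "")
  taxonomy <- NULL
  if ("taxonomy" %in% colnames(df)) {
    taxonomy <- as.character(df[["taxonomy"]])
    names(taxonomy) <- rownames(df)
    df[["taxonomy"]] <- NULL
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric count at row '%s', column '%s'",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "numeric"
  }
  if (orientation == "otus_in_rows") m <- t(m) else if (!is.null(taxonomy))
    stop("a 'taxonomy' column implies OTUs in rows; use orientation = 'otus_in_rows'")
  tab <- otu_table(m, taxonomy = taxonomy)
  message(sprintf("read_otu_table: %d samples, %d OTUs, %s reads",
                  nrow(tab), ncol(tab), format(sum(as.numeric(tab)), big.mark = ",")))
  tab
}

#' Write an OTU table to a tab-separated file
#'
#' Writes the samples-in-rows dialect that [read_otu_table] reads back; if the
#' table carries taxonomy the OTUs-in-rows dialect with a final `taxonomy`
#' column is written instead (and noted in the return value).
#'
#' @param x an [otu_table]
#' @param path output path
#' @return invisibly, the orientation written
#' @export
write_otu_table <- function(x, path) {
  tax <- otu_taxonomy(x)
  if (is.null(tax)) {
    df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible("samples_in_rows")
  } else {
    df <- data.frame(otu_id = colnames(x), t(unclass(x)), taxonomy = tax,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible("otus_in_rows")
  }
}

#' Read a sample metadata table
#'
#' Mandatory columns: `sample_id`, `habitat`, `longitude`, `latitude`
#' (decimal degrees). All remaining numeric columns are treated as
#' environmental variables.
#'
#' @param path CSV or TSV path (delimiter sniffed from the header line)
#' @return data.frame with row names = sample ids and an
#'   `env_vars` attribute naming the environmental columns
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "habitat", "longitude", "latitude")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing mandatory columns: ", paste(miss, collapse = ", "))
  validate_metadata(df)
}

#' Validate (and annotate) a metadata data.frame
#' @param df data.frame with sample_id, habitat, longitude, latitude columns
#' @return the data.frame with sample_id row names and `env_vars` attribute
#' @export
validate_metadata <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(df$latitude < -90 | df$latitude > 90))
    stop("latitude outside [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180))
    stop("longitude outside [-180, 180]")
  rownames(df) <- df$sample_id
  fixed <- c("sample_id", "habitat", "longitude", "latitude")
  env <- setdiff(colnames(df)[vapply(df, is.numeric, logical(1))], fixed)
  attr(df, "env_vars") <- env
  df
}

#' Write sample metadata
#' @param df metadata data.frame
#' @param path output path (TSV)
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
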