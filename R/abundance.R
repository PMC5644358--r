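#' Per-sample relative abundances
#' @param x an [otu_table]
#' @return numeric matrix, same shape, each row summing to 1
#' @export
relative_abundance <- function(x) {
  m <- unclass(x)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("empty sample(s): ", paste(rownames(m)[tot == 0], collapse = ", "))
  m / tot
}

#' Classify OTUs into the six abundance categories
#'
#' Each OTU is labeled by its per-sample relative-abundance profile:
#' \describe{
#'   \item{AT}{abundant: >= `abund_thresh` in all samples}
#'   \item{RT}{rare: < `rare_thresh` in all samples}
#'   \item{MT}{moderate: in \[`rare_thresh`, `abund_thresh`) in all samples}
#'   \item{CRT}{conditionally rare: always < `abund_thresh`, sometimes
#'     < `rare_thresh` (but not always)}
#'   \item{CAT}{conditionally abundant: always >= `rare_thresh`, sometimes
#'     >= `abund_thresh` (but not always)}
#'   \item{CRAT}{conditionally rare and abundant: spans both extremes}
#' }
#' Absence (count 0) counts as below `rare_thresh`, so an OTU absent in one
#' sample and abundant in another is CRAT. The six predicates are exhaustive
#' and mutually exclusive, so the labels partition the OTU set.
#'
#' @param x an [otu_table]
#' @param rare_thresh rarity threshold as a fraction (default 1e-4, i.e. 0.01\%)
#' @param abund_thresh abundance threshold as a fraction (default 1e-2, i.e. 1\%)
#' @return object of class `category_assignment`: named factor otu -> category
#'   with levels AT, CAT, CRAT, MT, CRT, RT and attributes `rare_thresh`,
#'   `abund_thresh`
#' @export
classify_otus <- function(x, rare_thresh = 1e-4, abund_thresh = 1e-2) {
  if (!(rare_thresh > 0 && rare_thresh < abund_thresh && abund_thresh <= 1))
    stop("need 0 < rare_thresh < abund_thresh <= 1")
  ra <- relative_abundance(x)
  mn <- apply(ra, 2, min)
  mx <- apply(ra, 2, max)
  cat <- ifelse(mn >= abund_thresh, "AT",
         ifelse(mx < rare_thresh, "RT",
         ifelse(mn >= rare_thresh & mx < abund_thresh, "MT",
         ifelse(mn >= rare_thresh & mx >= abund_thresh, "CAT",
         ifelse(mx < abund_thresh & mn < rare_thresh, "CRT", "CRAT")))))
  out <- factor(cat, levels = c("AT", "CAT", "CRAT", "MT", "CRT", "RT"))
  names(out) <- colnames(x)
  structure(out, rare_thresh = rare_thresh, abund_thresh = abund_thresh,
            class = c("category_assignment", "factor"))
}

#' Dominant OTU set (AT + CAT + CRAT)
#'
#' The union of abundant, conditionally abundant, and conditionally
#' rare-and-abundant taxa, pooled as the "dominant taxa" subcommunity for
#' downstream analyses.
#'
#' @param assignment a `category_assignment` from [classify_otus]
#' @return character vector of OTU ids
#' @export
combine_dominant <- function(assignment) {
  names(assignment)[assignment %in% c("AT", "CAT", "CRAT")]
}

#' Serialize a category assignment as two-column TSV
#' @param assignment a `category_assignment`
#' @param path output path
#' @export
write_category_assignment <- function(assignment, path) {
  utils::write.table(
    data.frame(otu_id = names(assignment), category = as.character(assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
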