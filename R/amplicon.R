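# 16S OTU-table screening. The screening stage treats the amplicon data as a
# presence overview of dominant symbionts, so it is deliberately aggressive:
# non-bacterial and organelle OTUs are removed, low-abundance cells are zeroed
# per sample, and samples are equalized by rarefaction.

#' Construct an OTU count table
#'
#' @param counts Integer matrix of read counts, rows = OTUs (rownames are OTU
#'   ids), columns = samples (colnames are sample ids). All counts must be
#'   non-negative.
#' @param taxonomy Character vector of semicolon-delimited lineage strings,
#'   named by OTU id (or unnamed, in row order of `counts`). OTUs without an
#'   entry get `"Unassigned"`.
#' @return An object of class `otu_table` (list with `counts`, `taxonomy`).
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) {
      stop("counts must have OTU ids as rownames", call. = FALSE)
    }
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) {
      stop("counts must have sample ids as colnames", call. = FALSE)
    }
    colnames(counts) <- character(0)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  tax <- stats::setNames(rep("Unassigned", nrow(counts)), rownames(counts))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) {
      stopifnot(length(taxonomy) == nrow(counts))
      names(taxonomy) <- rownames(counts)
    }
    known <- intersect(names(taxonomy), rownames(counts))
    tax[known] <- taxonomy[known]
  }
  structure(list(counts = counts, taxonomy = tax), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples;",
      sum(x$counts), "reads\n")
  invisible(x)
}

# Lineage ranks matching any of these tokens mark an OTU for removal.
# Tokens are compared per rank (semicolon-delimited), case-insensitively,
# tolerating QIIME-style rank prefixes such as "d__".
.tax_filter_terms <- c("archaea", "eukaryota", "mitochondria", "chloroplast")

#' Remove archaeal, eukaryotic, mitochondrial and chloroplast OTUs
#'
#' An OTU is removed when any rank of its lineage equals (case-insensitively,
#' ignoring a leading `d__`/`k__`/... prefix) one of Archaea, Eukaryota,
#' Mitochondria or Chloroplast. All other rows are untouched.
#'
#' @param table An [otu_table()].
#' @return The filtered `otu_table`; the number of removed OTUs is attached
#'   as attribute `otus_removed_taxonomy`.
#' @export
taxonomic_filter <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  hit <- vapply(table$taxonomy[rownames(table$counts)], function(lin) {
    ranks <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    ranks <- tolower(sub("^[a-z]__", "", ranks))
    any(ranks %in% .tax_filter_terms)
  }, logical(1))
  keep <- rownames(table$counts)[!hit]
  out <- otu_table(table$counts[keep, , drop = FALSE], table$taxonomy[keep])
  attr(out, "otus_removed_taxonomy") <- sum(hit)
  out
}

#' Zero per-sample low-abundance cells
#'
#' For each sample independently, any OTU whose count is strictly below
#' `threshold` of that sample's total reads is set to zero; presence in other
#' samples is not considered, and a cell sitting exactly at the threshold is
#' retained. Samples with zero total reads are left unchanged.
#'
#' @param table An [otu_table()].
#' @param threshold Fraction in (0, 1); default 0.01 (1 percent).
#' @return List with `table` (the floored `otu_table`) and `report` (list
#'   with `cells_zeroed`, `threshold`).
#' @export
abundance_floor <- function(table, threshold = 0.01) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  counts <- table$counts
  zeroed <- 0L
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    if (tot == 0) next
    low <- counts[, j] > 0L & counts[, j] / tot < threshold
    zeroed <- zeroed + sum(low)
    counts[low, j] <- 0L
  }
  list(table = otu_table(counts, table$taxonomy),
       report = list(cells_zeroed = zeroed, threshold = threshold))
}

#' Rarefy an OTU table to fixed depth
#'
#' Each retained sample is subsampled without replacement to exactly `depth`
#' reads (classic rarefaction, via [vegan::rrarefy()]); samples whose total is
#' below `depth` are removed and listed in the report. A sample with exactly
#' `depth` reads is returned unchanged.
#'
#' @param table An [otu_table()].
#' @param depth Target reads per sample (default 1000).
#' @param seed Integer seed making the subsampling reproducible.
#' @return List with `table` and `report` (list with `samples_dropped`,
#'   `depth`, `seed`).
#' @export
rarefy <- function(table, depth = 1000, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  counts <- table$counts
  totals <- colSums(counts)
  dropped <- colnames(counts)[totals < depth]
  keep <- colnames(counts)[totals >= depth]
  report <- list(samples_dropped = as.character(dropped),
                 depth = as.integer(depth), seed = as.integer(seed))
  if (length(keep) == 0 || nrow(counts) == 0) {
    out <- otu_table(counts[, keep, drop = FALSE], table$taxonomy)
    return(list(table = out, report = report))
  }
  set.seed(seed)
  # vegan warns whenever the smallest count is large (suspecting
  # pre-normalized data); our inputs are raw integer counts, so muffle it
  rar <- withCallingHandlers(
    vegan::rrarefy(t(counts[, keep, drop = FALSE]), sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  rar <- t(rar)
  storage.mode(rar) <- "integer"
  list(table = otu_table(rar, table$taxonomy), report = report)
}

#' Rank the dominant OTUs
#'
#' OTUs are ranked by total count across samples, ties broken
#' lexicographically by OTU id. The default `k = 13` matches the convention
#' of summarizing a screening table by its 13 most abundant OTUs.
#'
#' @param table An [otu_table()]; must be nonempty.
#' @param k Number of top OTUs to report (default 13). If `k` exceeds the
#'   number of OTUs, all are returned and `truncated` is flagged.
#' @return List with `otu_ids` (ranked), `totals` (named), `rel_abund`
#'   (matrix, top OTUs x samples, relative to each sample's total), and
#'   `truncated` (TRUE when fewer than `k` OTUs were available).
#' @export
dominant_otus <- function(table, k = 13) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table$counts) == 0) {
    stop("OTU table is empty", call. = FALSE)
  }
  totals <- rowSums(table$counts)
  ord <- order(-totals, rownames(table$counts))
  truncated <- k > nrow(table$counts)
  top <- rownames(table$counts)[ord][seq_len(min(k, nrow(table$counts)))]
  sample_tot <- colSums(table$counts)
  rel <- sweep(table$counts[top, , drop = FALSE], 2,
               pmax(sample_tot, 1L), "/")
  rel[, sample_tot == 0] <- 0
  list(otu_ids = top,
       totals = totals[top],
       rel_abund = rel,
       truncated = truncated)
}

#' Run the full amplicon screening stage
#'
#' Fixed processing order: taxonomic filtering, then the per-sample
#' relative-abundance floor (computed on post-filter sample totals), then
#' rarefaction, then the dominant-OTU summary.
#'
#' @inheritParams abundance_floor
#' @inheritParams rarefy
#' @inheritParams dominant_otus
#' @return List with `table` (final `otu_table`), `report` (merged
#'   `FilterReport`-style list) and `dominant`.
#' @export
amplicon_pipeline <- function(table, threshold = 0.01, depth = 1000,
                              seed = 1, k = 13) {
  filt <- taxonomic_filter(table)
  floored <- abundance_floor(filt, threshold = threshold)
  rar <- rarefy(floored$table, depth = depth, seed = seed)
  dom <- if (nrow(rar$table$counts) > 0 && ncol(rar$table$counts) > 0) {
    dominant_otus(rar$table, k = k)
  } else {
    NULL
  }
  list(table = rar$table,
       report = list(otus_removed_taxonomy = attr(filt, "otus_removed_taxonomy"),
                     cells_zeroed = floored$report$cells_zeroed,
                     samples_dropped = rar$report$samples_dropped,
                     depth = rar$report$depth,
                     seed = rar$report$seed),
       dominant = dom)
}
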