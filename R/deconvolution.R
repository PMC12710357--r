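# Strain deconvolution for double infections. Two strains of one genus in a
# single host show up in an assembly as (i) an excess of duplicated
# orthologs and (ii) a bimodal contig coverage distribution. The bin is split
# on log2 coverage at the threshold maximizing between-class variance
# (Otsu's criterion in one dimension), with a proportional exclusion band
# around the threshold because contigs of intermediate coverage cannot be
# assigned reliably.

#' Detect a double infection from duplicated-ortholog excess
#'
#' @param profiles Orthogroup copy-count profile: either a data frame with a
#'   `copy_count` column or a numeric vector of per-orthogroup copy counts
#'   within the bin.
#' @param dup_fraction_threshold Flag a double infection when the duplicated
#'   fraction reaches this value (default 0.2). "Excess" has no canonical
#'   definition, so the threshold is a tunable.
#' @return List with `flag` (logical) and `duplicated_fraction` =
#'   (orthogroups with >= 2 copies) / (orthogroups with >= 1 copy).
#' @export
detect_double_infection <- function(profiles, dup_fraction_threshold = 0.2) {
  counts <- if (is.data.frame(profiles)) {
    if (!"copy_count" %in% names(profiles)) {
      stop("profiles data frame needs a 'copy_count' column", call. = FALSE)
    }
    profiles$copy_count
  } else {
    profiles
  }
  if (length(counts) == 0) {
    stop("empty orthogroup profile table", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("copy counts must be >= 0", call. = FALSE)
  }
  present <- sum(counts >= 1)
  if (present == 0) {
    stop("no orthogroups present (all copy counts zero)", call. = FALSE)
  }
  frac <- sum(counts >= 2) / present
  list(flag = frac >= dup_fraction_threshold, duplicated_fraction = frac)
}

#' Split a contig bin into high- and low-coverage strains
#'
#' Chooses a threshold on log2 coverage by maximizing the between-class
#' variance of the two resulting groups (exhaustive search over split points
#' of the sorted values). Two guards apply:
#' \itemize{
#'   \item bimodality: if the two class means differ by less than
#'     `log2(min_fold)` the bin is considered unimodal and the function
#'     refuses to split (`refused = TRUE`; this is a result, not an error);
#'   \item intermediate band: contigs whose log2 coverage lies within
#'     `band_fraction * (mean_high - mean_low)` of the threshold are excluded
#'     as unassignable.
#' }
#' The split is invariant to contig order and equivariant under rescaling all
#' coverages by a common factor.
#'
#' @param contigs Contig table with columns `contig_id` and `coverage`, or a
#'   named numeric coverage vector. At least 4 contigs, all coverages > 0.
#' @param band_fraction Half-width of the exclusion band as a fraction of the
#'   distance between class means (default 0.2).
#' @param min_fold Minimum fold difference between class mean coverages for a
#'   split to be accepted (default 1.5).
#' @return Object of class `coverage_split`: list with `refused`,
#'   `threshold_log2`, `band_halfwidth_log2`, `mean_high_log2`,
#'   `mean_low_log2`, and `assignment` (named character vector with values
#'   `"HIGH"`, `"LOW"`, `"EXCLUDED_INTERMEDIATE"`). When `refused` is TRUE
#'   only `refused` and `reason` are meaningful.
#' @export
split_by_coverage <- function(contigs, band_fraction = 0.2, min_fold = 1.5) {
  if (is.data.frame(contigs)) {
    cov <- stats::setNames(contigs$coverage, contigs$contig_id)
  } else {
    cov <- contigs
    if (is.null(names(cov))) {
      names(cov) <- paste0("contig_", seq_along(cov))
    }
  }
  if (length(cov) < 4) {
    stop("need at least 4 contigs to attempt a coverage split", call. = FALSE)
  }
  if (any(!is.finite(cov)) || any(cov <= 0)) {
    stop("all coverages must be positive", call. = FALSE)
  }
  x <- log2(cov)
  ord <- order(x, names(cov))  # deterministic in contig order
  xs <- x[ord]
  n <- length(xs)

  # between-class variance w1*w2*(m1-m2)^2, maximized over the n-1 cut points
  best_k <- NA_integer_
  best_score <- -Inf
  csum <- cumsum(xs)
  total <- csum[n]
  for (k in seq_len(n - 1)) {
    m1 <- csum[k] / k
    m2 <- (total - csum[k]) / (n - k)
    score <- k * (n - k) * (m1 - m2)^2
    if (score > best_score + 1e-12) {
      best_score <- score
      best_k <- k
    }
  }
  mean_low <- csum[best_k] / best_k
  mean_high <- (total - csum[best_k]) / (n - best_k)

  if (!is.finite(mean_high - mean_low) ||
      (mean_high - mean_low) < log2(min_fold)) {
    return(structure(list(refused = TRUE,
                          reason = sprintf(
                            "class means differ by %.3f log2 units (< log2(%.2f)); no evidence of bimodal coverage",
                            mean_high - mean_low, min_fold)),
                     class = "coverage_split"))
  }

  threshold <- (xs[best_k] + xs[best_k + 1]) / 2
  halfwidth <- band_fraction * (mean_high - mean_low)

  assignment <- ifelse(abs(x - threshold) < halfwidth,
                       "EXCLUDED_INTERMEDIATE",
                       ifelse(x > threshold, "HIGH", "LOW"))
  names(assignment) <- names(cov)

  structure(list(refused = FALSE,
                 threshold_log2 = threshold,
                 band_halfwidth_log2 = halfwidth,
                 mean_high_log2 = mean_high,
                 mean_low_log2 = mean_low,
                 assignment = assignment),
            class = "coverage_split")
}

#' @export
print.coverage_split <- function(x, ...) {
  if (isTRUE(x$refused)) {
    cat("coverage split refused:", x$reason, "\n")
  } else {
    tab <- table(factor(x$assignment,
                        levels = c("HIGH", "LOW", "EXCLUDED_INTERMEDIATE")))
    cat(sprintf(
      "coverage split at log2 = %.3f (band +/- %.3f): %d HIGH, %d LOW, %d excluded\n",
      x$threshold_log2, x$band_halfwidth_log2,
      tab["HIGH"], tab["LOW"], tab["EXCLUDED_INTERMEDIATE"]))
  }
  invisible(x)
}

#' Pool the genes of co-resident same-genus strains into a composite genome
#'
#' For metabolic analysis a double infection is treated as one entry: the
#' composite genome is the multiset union of all genes of the genus in the
#' sample, duplicates retained as separate copies.
#'
#' @param genes Gene table with columns `strain_id` and `gene_symbol` (one
#'   row per gene copy), or a list of per-strain gene-symbol vectors.
#' @param strain_ids Strains to pool (default: all in `genes`). At least one
#'   strain must be present.
#' @return Character vector of gene symbols, copy-preserving.
#' @export
composite_genome <- function(genes, strain_ids = NULL) {
  if (is.data.frame(genes)) {
    if (is.null(strain_ids)) {
      strain_ids <- unique(genes$strain_id)
    }
    if (length(strain_ids) == 0 ||
        !any(genes$strain_id %in% strain_ids)) {
      stop("no genes found for the requested strain(s)", call. = FALSE)
    }
    out <- genes$gene_symbol[genes$strain_id %in% strain_ids]
  } else {
    if (is.null(strain_ids)) {
      strain_ids <- names(genes)
    }
    if (length(strain_ids) == 0) {
      stop("at least one resident strain is required", call. = FALSE)
    }
    out <- unlist(genes[strain_ids], use.names = FALSE)
  }
  as.character(out)
}
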