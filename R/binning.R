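# Symbiont contig binning: marker-gene recruitment followed by per-contig
# majority-vote taxonomy ("back-BLAST"): every annotated gene on a contig
# contributes its best reference hit, and the bacterial genus with the
# greatest number of hits is taken as the contig's origin. Contigs dominated
# by eukaryotic hits are excluded as host contamination.

#' Recruit candidate symbiont contigs
#'
#' A contig is recruited when at least one of its gene hits belongs to a
#' target genus. Recruitment is a superset pre-filter; the final identity of
#' each contig is decided by [classify_contig()].
#'
#' @param hits Hit table (`contig_id`, `gene_id`, `hit_genus`,
#'   `hit_superkingdom`).
#' @param target_genera Nonempty character vector of genus names.
#' @return Character vector of recruited contig ids (possibly empty).
#' @export
recruit_contigs <- function(hits, target_genera) {
  if (length(target_genera) == 0) {
    stop("target_genera must be nonempty", call. = FALSE)
  }
  if (nrow(hits) == 0) {
    return(character(0))
  }
  sort(unique(hits$contig_id[hits$hit_genus %in% target_genera]))
}

#' Classify one contig by majority vote over its gene hits
#'
#' Bacterial hits are tallied per genus; the strict-plurality genus wins.
#' If the eukaryotic hit count exceeds the best bacterial tally the contig is
#' excluded as host-derived (`EUKARYOTIC_EXCLUDED`). No hits, or an exact tie
#' for the best bacterial genus, give `UNCLASSIFIED`. Archaeal and viral hits
#' count neither as bacterial votes nor as eukaryotic evidence.
#'
#' @param hits Hit table rows for a single contig.
#' @return List with `contig_id`, `verdict` (genus name,
#'   `"UNCLASSIFIED"`, or `"EUKARYOTIC_EXCLUDED"`), `tally` (named integer
#'   vector of bacterial genus hit counts) and `euk_hits`.
#' @export
classify_contig <- function(hits) {
  contig_id <- if (nrow(hits) > 0) unique(hits$contig_id) else NA_character_
  if (length(contig_id) > 1) {
    stop("classify_contig expects hits for a single contig", call. = FALSE)
  }
  bact <- hits[hits$hit_superkingdom == "Bacteria", , drop = FALSE]
  tally <- if (nrow(bact) > 0) {
    tab <- table(bact$hit_genus)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  euk_hits <- sum(hits$hit_superkingdom == "Eukaryota")
  best <- if (length(tally) > 0) max(tally) else 0L

  verdict <- if (euk_hits > best) {
    "EUKARYOTIC_EXCLUDED"
  } else if (best == 0L) {
    "UNCLASSIFIED"
  } else if (sum(tally == best) > 1L) {
    "UNCLASSIFIED"
  } else {
    names(tally)[which.max(tally)]
  }
  list(contig_id = contig_id, verdict = verdict, tally = tally,
       euk_hits = as.integer(euk_hits))
}

#' Classify every contig in a hit table
#'
#' @param hits Hit table covering any number of contigs.
#' @return Data frame with one row per contig: `contig_id`, `verdict`,
#'   `best_tally`, `euk_hits`.
#' @export
classify_contigs <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(contig_id = character(0), verdict = character(0),
                      best_tally = integer(0), euk_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  pieces <- split(hits, hits$contig_id)
  rows <- lapply(pieces, function(h) {
    cl <- classify_contig(h)
    data.frame(contig_id = cl$contig_id, verdict = cl$verdict,
               best_tally = if (length(cl$tally) > 0) max(cl$tally) else 0L,
               euk_hits = cl$euk_hits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group classified contigs into per-genus bins
#'
#' Partitions contigs by verdict genus; `UNCLASSIFIED` and
#' `EUKARYOTIC_EXCLUDED` contigs are omitted. Bins are disjoint by
#' construction since each contig has exactly one verdict.
#'
#' @param calls Data frame from [classify_contigs()].
#' @param contigs Contig table (`contig_id`, ...); every call must reference
#'   a known contig.
#' @return Named list: genus -> character vector of contig ids.
#' @export
build_bins <- function(calls, contigs) {
  dangling <- setdiff(calls$contig_id, contigs$contig_id)
  if (length(dangling) > 0) {
    stop("call(s) reference unknown contig(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  keep <- !(calls$verdict %in% c("UNCLASSIFIED", "EUKARYOTIC_EXCLUDED"))
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(stats::setNames(list(), character(0)))
  }
  lapply(split(calls$contig_id, calls$verdict), sort)
}

#' Summary statistics for one genome bin
#'
#' Computes assembly-level statistics for a bin of contigs: total size, GC
#' percentage over non-N bases, CDS count, and coding density as the
#' percentage of the genome covered by the union of CDS intervals
#' (overlapping CDS are counted once).
#'
#' @param contigs Contig table with columns `contig_id` and `sequence`
#'   (sequences required for all contigs in the bin).
#' @param cds Data frame of CDS intervals with columns `contig_id`, `start`,
#'   `end`; coordinates 1-based inclusive, and each interval must lie within
#'   its contig.
#' @param genus Optional genus label carried into the output.
#' @return One-row data frame: `genus`, `n_contigs`, `genome_size_bp`,
#'   `gc_percent`, `cds_count`, `coding_density_percent`.
#' @export
genome_summary <- function(contigs, cds, genus = NA_character_) {
  if (any(is.na(contigs$sequence)) || is.null(contigs$sequence)) {
    stop("sequences are required for all bin contigs", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(contigs$sequence)
  names(seqs) <- contigs$contig_id
  lens <- Biostrings::width(seqs)
  genome_size <- sum(lens)

  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- 100 * (acgt["G"] + acgt["C"]) / sum(acgt)

  len_of <- stats::setNames(lens, contigs$contig_id)
  if (nrow(cds) > 0) {
    unknown <- setdiff(cds$contig_id, contigs$contig_id)
    if (length(unknown) > 0) {
      stop("CDS interval(s) on unknown contig(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    bad <- cds$start < 1 | cds$end > len_of[cds$contig_id] |
      cds$start > cds$end
    if (any(bad)) {
      stop("CDS interval(s) outside their contig: rows ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    covered <- sum(vapply(split(cds, cds$contig_id), function(d) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end))))
    }, numeric(1)))
  } else {
    covered <- 0
  }

  data.frame(genus = genus,
             n_contigs = nrow(contigs),
             genome_size_bp = genome_size,
             gc_percent = unname(gc),
             cds_count = nrow(cds),
             coding_density_percent = 100 * covered / genome_size,
             stringsAsFactors = FALSE)
}
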