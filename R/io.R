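# Plain-text interchange formats. All tables are tab-separated with a header
# row; writers use fixed formatting so identical inputs give byte-identical
# files.

#' Read / write a strain-host association table
#'
#' TSV with columns `strain_id`, `host_id`, `genus`; one row per symbiont
#' strain (a host carrying two strains of one genus appears in two rows).
#'
#' @param path File path.
#' @return `read_association()`: a validated data frame.
#' @export
read_association <- function(path) {
  validate_association(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_association
#' @param assoc Association data frame.
#' @export
write_association <- function(assoc, path) {
  write_tsv(validate_association(assoc), path)
}

#' Read / write a per-gene taxonomic hit table
#'
#' TSV with columns `contig_id`, `gene_id`, `hit_genus`, `hit_superkingdom`;
#' one row per annotated gene, carrying its single best reference hit.
#'
#' @param path File path.
#' @export
read_hits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "gene_id", "hit_genus", "hit_superkingdom")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) {
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  h
}

#' @rdname read_hits
#' @param hits Hit table data frame.
#' @export
write_hits <- function(hits, path) {
  write_tsv(hits, path)
}

#' Read / write a gene copy-status matrix
#'
#' Long-format TSV with columns `genome_id`, `gene_symbol`, `copy_index`,
#' `status` (status one of INTACT, DISRUPTED, ABSENT). A gene absent from a
#' genome may either be listed with a single ABSENT row or simply omitted;
#' both are treated identically by the pathway scorer.
#'
#' @param path File path.
#' @export
read_gene_matrix <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_matrix(m)
}

#' @rdname read_gene_matrix
#' @param matrix Gene copy-status data frame.
#' @export
write_gene_matrix <- function(matrix, path) {
  write_tsv(validate_gene_matrix(matrix), path)
}

validate_gene_matrix <- function(m) {
  need <- c("genome_id", "gene_symbol", "copy_index", "status")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    stop("gene matrix lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(m$status), c("INTACT", "DISRUPTED", "ABSENT"))
  if (length(bad) > 0) {
    stop("invalid copy status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Read an OTU table in the package TSV dialect
#'
#' Rows are OTUs. The first column is `otu_id`, the last column `taxonomy`
#' (a semicolon-delimited lineage string), and every column in between is one
#' sample of integer counts.
#'
#' @param path File path.
#' @return An [otu_table()] object.
#' @export
read_otu_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "otu_id" || names(d)[ncol(d)] != "taxonomy") {
    stop("OTU TSV must have 'otu_id' as first and 'taxonomy' as last column",
         call. = FALSE)
  }
  counts <- as.matrix(d[, -c(1, ncol(d)), drop = FALSE])
  rownames(counts) <- d$otu_id
  storage.mode(counts) <- "integer"
  otu_table(counts, stats::setNames(d$taxonomy, d$otu_id))
}

#' @rdname read_otu_tsv
#' @param table An [otu_table()] object.
#' @export
write_otu_tsv <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  d <- data.frame(otu_id = rownames(table$counts),
                  table$counts,
                  taxonomy = unname(table$taxonomy[rownames(table$counts)]),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, path)
}

#' Write contig sequences to FASTA
#'
#' @param contigs Data frame with columns `contig_id` and `sequence`.
#' @param path Output file path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  if (any(is.na(contigs$sequence))) {
    stop("cannot write FASTA: some contigs have no sequence", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(contigs$sequence)
  names(seqs) <- contigs$contig_id
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read contig sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Data frame with columns `contig_id`, `length`, `sequence`.
#' @export
read_contigs_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(contig_id = names(seqs),
             length = Biostrings::width(seqs),
             sequence = as.character(seqs),
             stringsAsFactors = FALSE)
}

#' Read CDS intervals from a GFF3 file
#'
#' Consumes only the seqid, type, start and end columns; rows with type other
#' than `CDS` are dropped. Coordinates are 1-based inclusive.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `contig_id`, `start`, `end`.
#' @export
read_cds_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) >= 5
  parts <- parts[ok]
  d <- data.frame(contig_id = vapply(parts, `[[`, character(1), 1),
                  type = vapply(parts, `[[`, character(1), 3),
                  start = as.integer(vapply(parts, `[[`, character(1), 4)),
                  end = as.integer(vapply(parts, `[[`, character(1), 5)),
                  stringsAsFactors = FALSE)
  d <- d[d$type == "CDS", c("contig_id", "start", "end")]
  rownames(d) <- NULL
  d
}

#' Write a report as pure JSON
#'
#' Reports carry no timestamps, so reruns with the same inputs and seed are
#' byte-identical and diffable.
#'
#' @param x A list (or other jsonlite-serializable object).
#' @param path Output file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
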