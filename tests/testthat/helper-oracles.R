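# Independent oracles and small fixture builders. The oracles deliberately
# share no code with the implementations they check.

# Brute-force majority-vote classification of one contig's hits.
oracle_classify <- function(hits) {
  genera <- character(0)
  euk <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$hit_superkingdom[i] == "Bacteria") {
      genera <- c(genera, hits$hit_genus[i])
    } else if (hits$hit_superkingdom[i] == "Eukaryota") {
      euk <- euk + 1L
    }
  }
  best <- 0L
  best_genus <- NA_character_
  n_best <- 0L
  for (g in unique(genera)) {
    n <- 0L
    for (gg in genera) if (gg == g) n <- n + 1L
    if (n > best) {
      best <- n
      best_genus <- g
      n_best <- 1L
    } else if (n == best) {
      n_best <- n_best + 1L
    }
  }
  if (euk > best) return("EUKARYOTIC_EXCLUDED")
  if (best == 0L || n_best > 1L) return("UNCLASSIFIED")
  best_genus
}

# Bipartition symmetric-difference RF oracle. Each internal edge contributes
# the bipartition (tips below it | rest); splits are canonicalized to the
# side not containing the alphabetically first label.
oracle_rf <- function(t1, t2) {
  splits_of <- function(tr) {
    labels <- sort(tr$tip.label)
    n <- length(labels)
    ntip <- length(tr$tip.label)
    below <- function(node) {
      if (node <= ntip) return(tr$tip.label[node])
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      unlist(lapply(kids, below))
    }
    keys <- character(0)
    for (node in unique(tr$edge[, 2])) {
      if (node <= ntip) next
      side <- below(node)
      if (length(side) < 2 || length(side) > n - 2) next
      if (labels[1] %in% side) side <- setdiff(labels, side)
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
    unique(keys)
  }
  s1 <- splits_of(t1)
  s2 <- splits_of(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Random rooted binary tree on given labels (generator only, not an oracle).
random_tree <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::rtree(length(labels), tip.label = sample(labels))
}

# One-contig hit table.
make_hits <- function(contig_id, genera = character(0),
                      kingdoms = rep("Bacteria", length(genera))) {
  data.frame(contig_id = rep(contig_id, length(genera)),
             gene_id = if (length(genera)) {
               paste0(contig_id, "_g", seq_along(genera))
             } else {
               character(0)
             },
             hit_genus = genera, hit_superkingdom = kingdoms,
             stringsAsFactors = FALSE)
}

# Random hit multiset for one contig.
random_hits <- function(contig_id = "c1") {
  n <- sample(0:10, 1)
  if (n == 0) return(make_hits(contig_id))
  kingdoms <- sample(c("Bacteria", "Eukaryota", "Archaea", "Viruses"), n,
                     replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05))
  genera <- ifelse(kingdoms == "Bacteria",
                   sample(c("Wolbachia", "Sodalis", "Serratia"), n,
                          replace = TRUE),
                   sample(c("Homo", "Drosophila"), n, replace = TRUE))
  make_hits(contig_id, genera, kingdoms)
}

# Random gene copy-status matrix over the default pathway genes; broader
# than simulate_gene_matrix (independent draws per copy, up to 3 copies).
random_gene_matrix <- function(genomes, defs = default_pathways()) {
  genes <- unique(unlist(lapply(defs, function(d) {
    unlist(lapply(d$steps, `[[`, "genes"))
  })))
  rows <- list()
  for (g in genomes) {
    for (gene in genes) {
      r <- runif(1)
      if (r < 0.35) next                       # omitted row == absent
      if (r < 0.45) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = g, gene_symbol = gene, copy_index = 1L,
          status = "ABSENT", stringsAsFactors = FALSE)
      } else {
        k <- sample(1:3, 1, prob = c(0.8, 0.15, 0.05))
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = g, gene_symbol = gene, copy_index = seq_len(k),
          status = sample(c("INTACT", "DISRUPTED"), k, replace = TRUE,
                          prob = c(0.7, 0.3)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Tiny OTU table builder.
make_otu <- function(counts, taxonomy = NULL) {
  otu_table(counts, taxonomy)
}
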