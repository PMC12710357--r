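# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with known ground truth, so each stage is testable without
# any external download. All generators are deterministic for a fixed seed.

#' Simulate a host phylogeny
#'
#' Random sequential leaf attachment (Yule-like): starting from a two-leaf
#' tree, each new leaf is attached as the sister of a uniformly chosen
#' existing leaf. All downstream analyses are topology-level, so branch
#' lengths are not assigned.
#'
#' @param n_hosts Number of leaves (>= 2), labeled `h1 ... hN`.
#' @param seed Integer seed; the same seed gives the identical tree.
#' @return A rooted binary `phylo` object.
#' @export
simulate_host_tree <- function(n_hosts, seed = 1) {
  if (!is.numeric(n_hosts) || n_hosts < 2) {
    stop("n_hosts must be >= 2", call. = FALSE)
  }
  n_hosts <- as.integer(n_hosts)
  set.seed(seed)
  s <- "(h1,h2)"
  leaves <- c("h1", "h2")
  if (n_hosts > 2) {
    for (i in 3:n_hosts) {
      target <- sample(leaves, 1)
      new_lab <- paste0("h", i)
      s <- sub(paste0(target, "(?![0-9])"),
               paste0("(", target, ",", new_lab, ")"), s, perl = TRUE)
      leaves <- c(leaves, new_lab)
    }
  }
  ape::read.tree(text = paste0(s, ";"))
}

#' Simulate symbiont acquisitions on a host tree
#'
#' Places `cfg$n_origins` independent acquisitions on the host tree. Each
#' acquisition either stays a single strain on one host or, with probability
#' `cfg$clade_expansion_prob`, expands into a coevolving clade: a host clade
#' of 2 to `cfg$max_clade_size` samples is chosen and the symbiont subtree is
#' an exact relabeled copy of the induced host subtree, so the clade is
#' host-congruent by construction. Singleton acquisitions may land on a host
#' already carrying the genus (a double infection) with probability
#' `cfg$double_infection_rate`. Per genus, the acquisitions are assembled
#' into one genus tree on a pectinate backbone; host assignments and backbone
#' orders that would create additional host-congruent groupings by chance are
#' rejected and redrawn, so the generated origin count is exactly recoverable
#' from the trees.
#'
#' @param host_tree A `phylo` host tree (at least `cfg$n_origins` leaves).
#' @param cfg A [sim_config()].
#' @return List with `association` (data frame `strain_id`, `host_id`,
#'   `genus`), `genus_trees` (named list of `phylo`; genera with a single
#'   strain have no tree), and `ground_truth` (list with
#'   `true_origin_count_per_genus`, `n_origins`, `clades`).
#' @export
simulate_symbiosis <- function(host_tree, cfg) {
  stopifnot(inherits(host_tree, "phylo"))
  cfg <- as_sim_config(cfg)
  if (length(host_tree$tip.label) < cfg$n_origins) {
    stop("simulation error: host tree has ", length(host_tree$tip.label),
         " leaves but ", cfg$n_origins, " origins were requested",
         call. = FALSE)
  }
  set.seed(cfg$seed)
  for (attempt in seq_len(100)) {
    plan <- draw_symbiosis_plan(host_tree, cfg)
    if (is.null(plan)) next
    built <- build_genus_trees(host_tree, plan)
    if (!has_spurious_congruence(built, host_tree)) {
      truth <- table(vapply(plan, `[[`, character(1), "genus"))
      return(list(
        association = built$association,
        genus_trees = built$genus_trees,
        ground_truth = list(
          true_origin_count_per_genus =
            stats::setNames(as.integer(truth), names(truth)),
          n_origins = length(plan),
          clades = built$true_clades)))
    }
  }
  stop("simulation error: could not place ", cfg$n_origins, " origins on a ",
       length(host_tree$tip.label), "-leaf host tree without creating ",
       "chance host-congruent groupings; reduce n_origins or enlarge the ",
       "host tree", call. = FALSE)
}

# One candidate placement of all origins; NULL when placement is infeasible
# for this draw (caller retries).
draw_symbiosis_plan <- function(host_tree, cfg) {
  hosts <- host_tree$tip.label
  usage <- list()  # genus -> named integer usage per host
  plan <- list()
  for (i in seq_len(cfg$n_origins)) {
    genus <- sample(cfg$genus_pool, 1)
    if (is.null(usage[[genus]])) {
      usage[[genus]] <- stats::setNames(integer(length(hosts)), hosts)
    }
    used <- usage[[genus]]
    if (stats::runif(1) < cfg$clade_expansion_prob) {
      cand <- candidate_host_clades(host_tree, used, cfg$max_clade_size)
      if (length(cand) == 0) return(NULL)
      clade_hosts <- cand[[sample.int(length(cand), 1)]]
      usage[[genus]][clade_hosts] <- usage[[genus]][clade_hosts] + 1L
      plan[[i]] <- list(genus = genus, type = "clade", hosts = clade_hosts)
    } else {
      fresh <- hosts[used == 0L]
      once <- hosts[used == 1L]
      host <- if (stats::runif(1) < cfg$double_infection_rate &&
                  length(once) > 0) {
        sample(once, 1)
      } else if (length(fresh) > 0) {
        sample(fresh, 1)
      } else if (length(once) > 0) {
        sample(once, 1)
      } else {
        return(NULL)
      }
      usage[[genus]][host] <- usage[[genus]][host] + 1L
      plan[[i]] <- list(genus = genus, type = "singleton", hosts = host)
    }
  }
  plan
}

# Host clades of size 2..max_size whose hosts are all unused by the genus.
candidate_host_clades <- function(host_tree, used, max_size) {
  ntip <- length(host_tree$tip.label)
  nodes <- (ntip + 1L):(ntip + host_tree$Nnode)
  out <- list()
  for (nd in nodes) {
    tips <- node_tips(host_tree, nd)
    if (length(tips) >= 2 && length(tips) <= max_size &&
        all(used[tips] == 0L)) {
      out[[length(out) + 1L]] <- tips
    }
  }
  out
}

build_genus_trees <- function(host_tree, plan) {
  genera <- unique(vapply(plan, `[[`, character(1), "genus"))
  assoc_rows <- list()
  genus_trees <- list()
  true_clades <- list()

  for (g in genera) {
    origins <- plan[vapply(plan, `[[`, character(1), "genus") == g]
    seen <- character(0)
    units <- character(0)
    for (o in origins) {
      if (o$type == "clade") {
        ids <- paste0(g, "_", o$hosts)
        sub <- induced_subtree(host_tree, o$hosts)
        sub$tip.label <- paste0(g, "_", sub$tip.label)
        units <- c(units, sub(";$", "", ape::write.tree(sub)))
        true_clades[[length(true_clades) + 1L]] <-
          list(genus = g, strain_ids = sort(ids), host_ids = sort(o$hosts))
        seen <- c(seen, o$hosts)
        for (k in seq_along(ids)) {
          assoc_rows[[length(assoc_rows) + 1L]] <-
            data.frame(strain_id = ids[k], host_id = o$hosts[k], genus = g,
                       stringsAsFactors = FALSE)
        }
      } else {
        id <- paste0(g, "_", o$hosts)
        if (o$hosts %in% seen) id <- paste0(id, "_b")
        seen <- c(seen, o$hosts)
        units <- c(units, id)
        assoc_rows[[length(assoc_rows) + 1L]] <-
          data.frame(strain_id = id, host_id = o$hosts, genus = g,
                     stringsAsFactors = FALSE)
      }
    }
    units <- units[sample.int(length(units))]
    # pectinate backbone: (u1,(u2,(...,(u_{n-1},u_n))))
    nwk <- units[length(units)]
    if (length(units) > 1) {
      for (k in (length(units) - 1L):1L) {
        nwk <- paste0("(", units[k], ",", nwk, ")")
      }
    }
    tr <- ape::read.tree(text = paste0(nwk, ";"))
    if (length(tr$tip.label) >= 2) {
      genus_trees[[g]] <- tr
    }
  }
  list(association = do.call(rbind, assoc_rows),
       genus_trees = genus_trees,
       true_clades = true_clades)
}

# TRUE when any genus tree contains a host-congruent grouping that is not one
# of (or inside one of) the constructed coevolving clades. Uses a flat scan
# over all clades of each genus tree rather than the production traversal.
has_spurious_congruence <- function(built, host_tree) {
  assoc <- built$association
  host_of <- stats::setNames(assoc$host_id, assoc$strain_id)
  truth_sets <- lapply(built$true_clades, `[[`, "strain_ids")
  for (g in names(built$genus_trees)) {
    tr <- built$genus_trees[[g]]
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    for (idx in pp) {
      tips <- labs[idx]
      if (length(tips) < 2) next
      is_true <- any(vapply(truth_sets, function(s) setequal(s, tips),
                            logical(1)))
      inside_true <- any(vapply(truth_sets, function(s) all(tips %in% s),
                                logical(1)))
      if (is_true || inside_true) next
      hosts <- unname(host_of[tips])
      if (anyDuplicated(hosts)) next
      mono <- length(hosts) == length(host_tree$tip.label) ||
        ape::is.monophyletic(host_tree, hosts)
      if (!mono) next
      sub_g <- ape::keep.tip(tr, tips)
      sub_g$tip.label <- unname(host_of[sub_g$tip.label])
      sub_h <- ape::keep.tip(host_tree, hosts)
      rf <- if (length(hosts) <= 3) 0 else {
        phangorn::RF.dist(ape::unroot(sub_g), ape::unroot(sub_h),
                          check.labels = TRUE)
      }
      if (rf == 0) return(TRUE)
    }
  }
  FALSE
}

#' Simulate metagenome contigs, gene hits, and orthogroup profiles
#'
#' Per strain, contig coverages are drawn log-normally around the strain's
#' mean log2 coverage: the two strains of a double infection get the high and
#' low mean of `cfg$coverage_log2_means` respectively, single strains the
#' high mean. Every contig carries at least one annotated gene; each gene's
#' best hit reports the true genus with probability `1 - cfg$hit_error_rate`.
#' With probability `cfg$euk_contig_rate` a contig is replaced by a
#' eukaryotic (host-derived) contamination contig whose hits are eukaryotic.
#' A per-(host, genus) orthogroup copy-count profile is also emitted:
#' orthogroups of a double-infected bin are mostly duplicated, those of a
#' single-strain bin mostly single-copy.
#'
#' @param association Association data frame from [simulate_symbiosis()].
#' @param cfg A [sim_config()].
#' @param seed Seed (default `cfg$seed`).
#' @return List with `contigs` (data frame `contig_id`, `host_id`, `length`,
#'   `coverage`; `host_id` records which sample's assembly the contig belongs
#'   to), `hits`, `orthogroups` (data frame `host_id`, `genus`,
#'   `orthogroup_id`, `copy_count`), and `ground_truth` (data frame
#'   `contig_id`, `truth` in HIGH/LOW/EUK, `strain_id`, `genus`).
#' @export
simulate_metagenome <- function(association, cfg, seed = NULL) {
  cfg <- as_sim_config(cfg)
  assoc <- validate_association(association)
  if (is.null(seed)) seed <- cfg$seed
  key <- paste(assoc$genus, assoc$host_id, sep = "|")
  dup_groups <- unique(key[duplicated(key)])
  if (length(dup_groups) > 0 &&
      cfg$coverage_log2_means[1] == cfg$coverage_log2_means[2]) {
    stop("coverage_log2_means must differ when double infections are present",
         call. = FALSE)
  }
  set.seed(seed)

  # strain roles: second strain of a (genus, host) pair is the LOW one
  role <- ifelse(duplicated(key), "LOW", "HIGH")
  mu <- ifelse(role == "HIGH", cfg$coverage_log2_means[1],
               cfg$coverage_log2_means[2])

  euk_genera <- c("Homo", "Drosophila", "Myotis")
  wrong_pool <- c(cfg$genus_pool, "Escherichia", "Bacillus", "Rickettsia")

  contigs <- list(); hits <- list(); truth <- list()
  for (i in seq_len(nrow(assoc))) {
    strain <- assoc$strain_id[i]
    for (j in seq_len(cfg$contigs_per_strain)) {
      cid <- paste0("ctg_", strain, "_", j)
      is_euk <- stats::runif(1) < cfg$euk_contig_rate
      n_genes <- 1L + stats::rpois(1, max(cfg$mean_genes_per_contig - 1, 0))
      if (is_euk) {
        coverage <- 2^stats::rnorm(1, mean = 4, sd = 1)
        genus_hits <- sample(euk_genera, n_genes, replace = TRUE)
        kingdom <- rep("Eukaryota", n_genes)
        truth[[cid]] <- data.frame(contig_id = cid, truth = "EUK",
                                   strain_id = NA_character_,
                                   genus = NA_character_,
                                   stringsAsFactors = FALSE)
      } else {
        coverage <- 2^stats::rnorm(1, mean = mu[i], sd = cfg$coverage_log2_sd)
        wrong <- stats::runif(n_genes) < cfg$hit_error_rate
        genus_hits <- ifelse(
          wrong,
          sample(setdiff(wrong_pool, assoc$genus[i]), n_genes, replace = TRUE),
          assoc$genus[i])
        kingdom <- rep("Bacteria", n_genes)
        truth[[cid]] <- data.frame(contig_id = cid, truth = role[i],
                                   strain_id = strain,
                                   genus = assoc$genus[i],
                                   stringsAsFactors = FALSE)
      }
      contigs[[cid]] <- data.frame(
        contig_id = cid,
        host_id = assoc$host_id[i],
        length = sample(5000:50000, 1),
        coverage = coverage, stringsAsFactors = FALSE)
      hits[[cid]] <- data.frame(
        contig_id = cid,
        gene_id = paste0(cid, "_g", seq_len(n_genes)),
        hit_genus = genus_hits,
        hit_superkingdom = kingdom, stringsAsFactors = FALSE)
    }
  }

  groups <- unique(data.frame(host_id = assoc$host_id, genus = assoc$genus,
                              stringsAsFactors = FALSE))
  ortho <- list()
  for (i in seq_len(nrow(groups))) {
    double <- sum(assoc$host_id == groups$host_id[i] &
                    assoc$genus == groups$genus[i]) >= 2
    p_dup <- if (double) 0.8 else 0.05
    ortho[[i]] <- data.frame(
      host_id = groups$host_id[i], genus = groups$genus[i],
      orthogroup_id = paste0("OG", seq_len(cfg$n_orthogroups)),
      copy_count = 1L + stats::rbinom(cfg$n_orthogroups, 1, p_dup),
      stringsAsFactors = FALSE)
  }

  list(contigs = do.call(rbind, c(contigs, list(make.row.names = FALSE))),
       hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
       orthogroups = do.call(rbind, c(ortho, list(make.row.names = FALSE))),
       ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate a gene copy-status matrix with ground-truth pathway calls
#'
#' Per genome and pathway gene, the gene is absent with probability
#' `cfg$pathway_loss_rate`; otherwise it has one copy (two with probability
#' `cfg$duplication_rate`), and each copy is disrupted with probability
#' `cfg$pseudogene_rate`. Ground-truth calls are computed by applying the
#' scoring rules with [reference_vitamin_calls()], a deliberately naive
#' straight-line scorer kept separate from the production one.
#'
#' @param genomes Character vector of genome ids.
#' @param defs Pathway definitions (default [default_pathways()]).
#' @param cfg A [sim_config()].
#' @param seed Seed (default `cfg$seed`).
#' @return List with `matrix` (long data frame) and `ground_truth` (data
#'   frame `genome_id`, `pathway_id`, `call`).
#' @export
simulate_gene_matrix <- function(genomes, defs = default_pathways(), cfg,
                                 seed = NULL) {
  cfg <- as_sim_config(cfg)
  if (length(defs) == 0) stop("pathway definitions are empty", call. = FALSE)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  genes <- unique(unlist(lapply(defs, function(d) {
    unlist(lapply(d$steps, `[[`, "genes"))
  })))
  rows <- list()
  for (g in genomes) {
    for (gene in genes) {
      if (stats::runif(1) < cfg$pathway_loss_rate) {
        rows[[length(rows) + 1L]] <-
          data.frame(genome_id = g, gene_symbol = gene, copy_index = 1L,
                     status = "ABSENT", stringsAsFactors = FALSE)
      } else {
        n_copies <- 1L + stats::rbinom(1, 1, cfg$duplication_rate)
        st <- ifelse(stats::runif(n_copies) < cfg$pseudogene_rate,
                     "DISRUPTED", "INTACT")
        rows[[length(rows) + 1L]] <-
          data.frame(genome_id = g, gene_symbol = gene,
                     copy_index = seq_len(n_copies), status = st,
                     stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  list(matrix = mat,
       ground_truth = reference_vitamin_calls(mat, defs, genomes))
}

#' Simulate an amplicon OTU table
#'
#' One sample per host in the association table. Each sample's depth is drawn
#' uniformly from `cfg$otu_depth_range`; symbiont OTUs (one per genus)
#' jointly receive `1 - cfg$background_rate` of the reads in expectation,
#' split equally among the genera present in the sample, and a fixed panel of
#' background OTUs (including mitochondrial, chloroplast and eukaryotic
#' labels, so the taxonomic filter has work to do) receives the rest with
#' geometrically decaying weights. Counts are multinomial.
#'
#' @param association Association data frame.
#' @param cfg A [sim_config()].
#' @param seed Seed (default `cfg$seed`).
#' @return An [otu_table()].
#' @export
simulate_otu_table <- function(association, cfg, seed = NULL) {
  cfg <- as_sim_config(cfg)
  assoc <- validate_association(association)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)

  samples <- sort(unique(assoc$host_id))
  sym_genera <- sort(unique(assoc$genus))
  sym_otus <- paste0("OTU_", sym_genera)
  sym_tax <- stats::setNames(
    paste0("Bacteria;Proteobacteria;;;;", sym_genera), sym_otus)

  background <- c(
    OTU_chloroplast = "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast;;",
    OTU_mitochondria = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria;",
    OTU_fungus = "Eukaryota;Ascomycota;;;;",
    OTU_archaeon = "Archaea;Euryarchaeota;;;;",
    OTU_staph = "Bacteria;Firmicutes;Bacilli;Staphylococcales;Staphylococcaceae;Staphylococcus",
    OTU_pseudomonas = "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas",
    OTU_acinetobacter = "Bacteria;Proteobacteria;Gammaproteobacteria;Moraxellales;Moraxellaceae;Acinetobacter",
    OTU_lactobacillus = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus")

  otu_ids <- c(sym_otus, names(background))
  counts <- matrix(0L, nrow = length(otu_ids), ncol = length(samples),
                   dimnames = list(otu_ids, samples))
  bg_w <- 2^-(seq_along(background))
  bg_w <- bg_w / sum(bg_w)

  for (s in samples) {
    depth <- sample(cfg$otu_depth_range[1]:cfg$otu_depth_range[2], 1)
    present <- paste0("OTU_", sort(unique(assoc$genus[assoc$host_id == s])))
    p <- stats::setNames(numeric(length(otu_ids)), otu_ids)
    if (length(present) > 0) {
      p[present] <- (1 - cfg$background_rate) / length(present)
    }
    p[names(background)] <- cfg$background_rate * bg_w
    p <- p / sum(p)
    counts[, s] <- as.integer(stats::rmultinom(1, size = depth, prob = p))
  }
  if (cfg$background_rate == 0) {
    counts <- counts[sym_otus, , drop = FALSE]
  }
  otu_table(counts, c(sym_tax, background))
}

#' Write a simulated study to a fixture directory
#'
#' Emits the complete set of interchange files: association TSV, Newick
#' trees, coverage and hit TSVs, orthogroup TSV, gene matrix TSV, OTU table
#' TSV, and a ground-truth JSON. Writers are deterministic, so the same
#' simulation writes byte-identical files.
#'
#' @param sim List with any of `association`, `host_tree`, `genus_trees`,
#'   `metagenome`, `gene_matrix`, `otu`, `ground_truth` components (as
#'   produced by the `simulate_*` functions).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$association)) {
    write_association(sim$association, file.path(dir, "association.tsv"))
  }
  if (!is.null(sim$host_tree)) {
    write_newick(sim$host_tree, file.path(dir, "host_tree.nwk"))
  }
  for (g in names(sim$genus_trees)) {
    write_newick(sim$genus_trees[[g]],
                 file.path(dir, paste0("tree_", tolower(g), ".nwk")))
  }
  if (!is.null(sim$metagenome)) {
    write_tsv(sim$metagenome$contigs, file.path(dir, "coverage.tsv"))
    write_hits(sim$metagenome$hits, file.path(dir, "hits.tsv"))
    write_tsv(sim$metagenome$orthogroups, file.path(dir, "orthogroups.tsv"))
  }
  if (!is.null(sim$gene_matrix)) {
    write_gene_matrix(sim$gene_matrix$matrix,
                      file.path(dir, "gene_matrix.tsv"))
  }
  if (!is.null(sim$otu)) {
    write_otu_tsv(sim$otu, file.path(dir, "otu_table.tsv"))
  }
  if (!is.null(sim$ground_truth)) {
    write_report_json(sim$ground_truth, file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}
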