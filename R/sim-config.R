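#' Configuration for the synthetic-data generators
#'
#' Bundles every knob the generators use, with defaults chosen to emulate a
#' cimicid-scale symbiont survey: 14 host samples, a handful of independent
#' acquisitions drawn from a small pool of symbiont genera, double infections
#' whose two strains differ roughly 16-fold in coverage (log2 means 6 and 2,
#' sd 0.3 log2 units), a low rate of misassigned gene hits and of eukaryotic
#' contamination contigs, and amplicon depths in the thousands with symbiont
#' OTUs dominating each sample.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param n_hosts Number of host-tree leaves (>= 2).
#' @param n_origins Number of independent symbiont acquisitions (>= 1).
#' @param clade_expansion_prob Probability that an acquisition expands into a
#'   host-congruent coevolving clade rather than staying a single strain.
#' @param coverage_log2_means Length-2 numeric: mean log2 coverage of the
#'   high- and low-coverage strain of a double infection.
#' @param coverage_log2_sd Standard deviation of log2 coverage around the
#'   strain mean.
#' @param hit_error_rate Probability that a gene hit reports a wrong genus.
#' @param euk_contig_rate Probability that a contig is eukaryotic
#'   (host-derived contamination).
#' @param pathway_loss_rate Per-gene probability of absence in the gene
#'   matrix generator.
#' @param pseudogene_rate Per-copy probability of a `DISRUPTED` status.
#' @param otu_depth_range Integer pair: per-sample amplicon depth is drawn
#'   uniformly from this range.
#' @param genus_pool Symbiont genus names acquisitions are drawn from.
#' @param max_clade_size Largest host clade an acquisition may expand into.
#' @param double_infection_rate Probability that a singleton acquisition
#'   lands on a host already carrying a strain of the same genus.
#' @param contigs_per_strain Contigs simulated per symbiont strain.
#' @param mean_genes_per_contig Mean number of annotated genes per contig
#'   (each contig carries at least one).
#' @param duplication_rate Per-gene probability of a second copy in the gene
#'   matrix generator.
#' @param background_rate Expected fraction of non-symbiont reads per
#'   amplicon sample (0 gives a table of symbiont OTUs only).
#' @param n_orthogroups Orthogroups simulated per genus bin for the
#'   duplicated-ortholog profile.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_hosts = 14,
                       n_origins = 5,
                       clade_expansion_prob = 0.3,
                       coverage_log2_means = c(6, 2),
                       coverage_log2_sd = 0.3,
                       hit_error_rate = 0.02,
                       euk_contig_rate = 0.05,
                       pathway_loss_rate = 0.1,
                       pseudogene_rate = 0.05,
                       otu_depth_range = c(1000L, 20000L),
                       genus_pool = c("Wolbachia", "Symbiopectobacterium",
                                      "Sodalis", "Serratia", "Tisiphia"),
                       max_clade_size = 4,
                       double_infection_rate = 0.1,
                       contigs_per_strain = 30,
                       mean_genes_per_contig = 3,
                       duplication_rate = 0.1,
                       background_rate = 0.3,
                       n_orthogroups = 200) {
  cfg <- list(seed = as.integer(seed), n_hosts = as.integer(n_hosts),
              n_origins = as.integer(n_origins),
              clade_expansion_prob = clade_expansion_prob,
              coverage_log2_means = as.numeric(coverage_log2_means),
              coverage_log2_sd = coverage_log2_sd,
              hit_error_rate = hit_error_rate,
              euk_contig_rate = euk_contig_rate,
              pathway_loss_rate = pathway_loss_rate,
              pseudogene_rate = pseudogene_rate,
              otu_depth_range = as.integer(otu_depth_range),
              genus_pool = as.character(genus_pool),
              max_clade_size = as.integer(max_clade_size),
              double_infection_rate = double_infection_rate,
              contigs_per_strain = as.integer(contigs_per_strain),
              mean_genes_per_contig = mean_genes_per_contig,
              duplication_rate = duplication_rate,
              background_rate = background_rate,
              n_orthogroups = as.integer(n_orthogroups))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c("clade_expansion_prob", "hit_error_rate", "euk_contig_rate",
             "pathway_loss_rate", "pseudogene_rate", "double_infection_rate",
             "duplication_rate", "background_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: '", p, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$n_hosts < 2) stop("sim_config: n_hosts must be >= 2", call. = FALSE)
  if (cfg$n_origins < 1) stop("sim_config: n_origins must be >= 1",
                              call. = FALSE)
  if (length(cfg$coverage_log2_means) != 2) {
    stop("sim_config: coverage_log2_means must have length 2", call. = FALSE)
  }
  if (cfg$coverage_log2_sd <= 0) {
    stop("sim_config: coverage_log2_sd must be > 0", call. = FALSE)
  }
  if (length(cfg$otu_depth_range) != 2 || any(cfg$otu_depth_range < 1) ||
      cfg$otu_depth_range[1] > cfg$otu_depth_range[2]) {
    stop("sim_config: otu_depth_range must be an increasing positive pair",
         call. = FALSE)
  }
  if (cfg$max_clade_size < 2) {
    stop("sim_config: max_clade_size must be >= 2", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

as_sim_config <- function(cfg) {
  if (inherits(cfg, "sim_config")) return(cfg)
  if (is.list(cfg)) return(do.call(sim_config, cfg))
  stop("cfg must be a sim_config or a list of sim_config arguments",
       call. = FALSE)
}
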