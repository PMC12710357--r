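#!/usr/bin/env Rscript
# Generate the synthetic symbiont survey used by the downstream analysis
# scripts: host tree, acquisitions (with coevolving clades and double
# infections), metagenome contigs/hits/orthogroups, gene copy-status matrix,
# and an amplicon OTU table. Everything is written as plain-text interchange
# files under results/sim/ with the ground truth alongside.

suppressPackageStartupMessages(library(cimsym))

cfg <- sim_config(seed = 42, n_hosts = 14, n_origins = 6,
                  clade_expansion_prob = 0.6, double_infection_rate = 0.15,
                  contigs_per_strain = 30)

host_tree <- simulate_host_tree(cfg$n_hosts, seed = cfg$seed)
sym <- simulate_symbiosis(host_tree, cfg)
metag <- simulate_metagenome(sym$association, cfg)
gm <- simulate_gene_matrix(sym$association$strain_id, cfg = cfg)
otu <- simulate_otu_table(sym$association, cfg)

dir <- file.path("results", "sim")
write_fixture(list(association = sym$association, host_tree = host_tree,
                   genus_trees = sym$genus_trees, metagenome = metag,
                   gene_matrix = gm, otu = otu,
                   ground_truth = c(sym$ground_truth,
                                    list(contig_truth = metag$ground_truth,
                                         pathway_truth = gm$ground_truth))),
              dir)

cat("simulated", cfg$n_hosts, "hosts,", nrow(sym$association), "strains (",
    sym$ground_truth$n_origins, "true origins,",
    length(sym$ground_truth$clades), "coevolving clades ),",
    nrow(metag$contigs), "contigs,", nrow(metag$hits), "gene hits\n")
cat("fixture written to", dir, "\n")
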