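test_that("host tree generation is seeded, binary and labeled", {
  # only one topology exists on two leaves
  expect_identical(ape::write.tree(simulate_host_tree(2, seed = 1)),
                   "(h1,h2);")
  t1 <- simulate_host_tree(8, seed = 42)
  t2 <- simulate_host_tree(8, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(length(t1$tip.label), 8L)
  expect_identical(t1$Nnode, 7L)  # rooted binary: n - 1 internal nodes
  expect_false(anyDuplicated(t1$tip.label) > 0)
  expect_error(simulate_host_tree(1, seed = 1), ">= 2")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(hit_error_rate = 1.2), "probability")
  expect_error(sim_config(n_origins = 0), "n_origins")
  expect_error(sim_config(n_hosts = 1), "n_hosts")
  expect_error(sim_config(otu_depth_range = c(500, 100)), "otu_depth_range")
  expect_error(sim_config(coverage_log2_sd = 0), "coverage_log2_sd")
})

test_that("without clade expansion every origin is one strain", {
  cfg <- sim_config(seed = 5, n_hosts = 10, n_origins = 3,
                    clade_expansion_prob = 0, double_infection_rate = 0)
  sym <- simulate_symbiosis(simulate_host_tree(10, seed = 5), cfg)
  expect_identical(nrow(sym$association), 3L)
  expect_identical(sym$ground_truth$n_origins, 3L)
  expect_length(sym$ground_truth$clades, 0)
})

test_that("forced expansion into 2-host clades doubles the strain count", {
  cfg <- sim_config(seed = 6, n_hosts = 12, n_origins = 3,
                    clade_expansion_prob = 1, max_clade_size = 2)
  sym <- simulate_symbiosis(simulate_host_tree(12, seed = 6), cfg)
  expect_identical(nrow(sym$association), 6L)          # 3 clades x 2 strains
  expect_identical(sym$ground_truth$n_origins, 3L)
  expect_length(sym$ground_truth$clades, 3)
  # each constructed clade is congruent by construction: the counter
  # recovers the truth exactly
  ht <- simulate_host_tree(12, seed = 6)
  clades <- list()
  for (g in names(sym$genus_trees)) {
    ag <- sym$association[sym$association$genus == g, ]
    clades <- c(clades, find_coevolving_clades(sym$genus_trees[[g]], ht, ag))
  }
  expect_identical(count_origins(sym$association, clades)$total, 3L)
})

test_that("symbiosis simulation is reproducible and validates feasibility", {
  cfg <- sim_config(seed = 9, n_hosts = 10, n_origins = 4)
  ht <- simulate_host_tree(10, seed = 9)
  s1 <- simulate_symbiosis(ht, cfg)
  s2 <- simulate_symbiosis(ht, cfg)
  expect_identical(s1$association, s2$association)
  expect_identical(lapply(s1$genus_trees, ape::write.tree),
                   lapply(s2$genus_trees, ape::write.tree))
  expect_error(simulate_symbiosis(simulate_host_tree(3, seed = 1),
                                  sim_config(n_origins = 4, n_hosts = 3)),
               "origins")
})

test_that("error-free metagenomes report only true genera", {
  cfg <- sim_config(seed = 14, n_hosts = 8, n_origins = 3,
                    hit_error_rate = 0, euk_contig_rate = 0,
                    contigs_per_strain = 8)
  sym <- simulate_symbiosis(simulate_host_tree(8, seed = 14), cfg)
  mg <- simulate_metagenome(sym$association, cfg)
  strain_genus <- setNames(sym$association$genus, sym$association$strain_id)
  truth_genus <- setNames(mg$ground_truth$genus, mg$ground_truth$contig_id)
  expect_true(all(mg$hits$hit_genus == truth_genus[mg$hits$contig_id]))
  expect_true(all(mg$hits$hit_superkingdom == "Bacteria"))
})

test_that("double-infection coverage is bimodal with well-separated modes", {
  cfg <- sim_config(seed = 15, n_hosts = 8, n_origins = 4,
                    clade_expansion_prob = 0, double_infection_rate = 1,
                    euk_contig_rate = 0, contigs_per_strain = 200,
                    coverage_log2_means = c(6, 2), coverage_log2_sd = 0.3)
  sym <- simulate_symbiosis(simulate_host_tree(8, seed = 15), cfg)
  mg <- simulate_metagenome(sym$association, cfg)
  truth <- merge(mg$contigs, mg$ground_truth, by = "contig_id")
  hi <- log2(truth$coverage[truth$truth == "HIGH"])
  lo <- log2(truth$coverage[truth$truth == "LOW"])
  expect_gt(length(hi), 0)
  expect_gt(length(lo), 0)
  # the two modes sit at least 8-fold apart
  expect_gte(mean(hi) - mean(lo), 3)
})

test_that("fixture files are byte-identical across reruns", {
  cfg <- sim_config(seed = 16, n_hosts = 8, n_origins = 3,
                    contigs_per_strain = 5)
  ht <- simulate_host_tree(8, seed = 16)
  md5_of_run <- function() {
    sym <- simulate_symbiosis(ht, cfg)
    mg <- simulate_metagenome(sym$association, cfg)
    dir <- file.path(tempfile(), "fx")
    write_fixture(list(association = sym$association,
                       host_tree = ht, genus_trees = sym$genus_trees,
                       metagenome = mg), dir)
    files <- list.files(dir, full.names = TRUE)
    setNames(tools::md5sum(files), basename(files))
  }
  expect_identical(md5_of_run(), md5_of_run())
})

test_that("gene matrix ground truth matches the scoring rules at the edges", {
  genomes <- paste0("g", 1:4)
  none <- simulate_gene_matrix(genomes,
                               cfg = sim_config(seed = 17,
                                                pathway_loss_rate = 0,
                                                pseudogene_rate = 0))
  expect_true(all(none$ground_truth$call == "FUNCTIONAL"))
  all_lost <- simulate_gene_matrix(genomes,
                                   cfg = sim_config(seed = 18,
                                                    pathway_loss_rate = 1))
  expect_true(all(all_lost$ground_truth$call == "NONFUNCTIONAL"))
})

test_that("simulated OTU tables are symbiont-dominated and reproducible", {
  cfg <- sim_config(seed = 21, n_hosts = 6, n_origins = 1,
                    clade_expansion_prob = 0)
  sym <- simulate_symbiosis(simulate_host_tree(6, seed = 21), cfg)
  # single-symbiont sample: its OTU tops every other OTU in >= 95% of seeds
  wins <- 0L
  for (s in 1:100) {
    ot <- simulate_otu_table(sym$association,
                             sim_config(seed = 21, n_hosts = 6, n_origins = 1,
                                        otu_depth_range = c(1000L, 1000L)),
                             seed = 500 + s)
    smp <- sym$association$host_id[1]
    sym_otu <- paste0("OTU_", sym$association$genus[1])
    col <- ot$counts[, smp]
    if (col[sym_otu] >= max(col[names(col) != sym_otu])) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
  # zero background rate leaves only symbiont OTUs
  ot0 <- simulate_otu_table(sym$association,
                            sim_config(seed = 21, n_hosts = 6, n_origins = 1,
                                       background_rate = 0))
  expect_true(all(startsWith(rownames(ot0$counts), "OTU_")))
  expect_true(all(rownames(ot0$counts) %in%
                    paste0("OTU_", sym$association$genus)))
  # fixed seed reproduces the identical table
  o1 <- simulate_otu_table(sym$association, cfg, seed = 77)
  o2 <- simulate_otu_table(sym$association, cfg, seed = 77)
  expect_identical(o1$counts, o2$counts)
})
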