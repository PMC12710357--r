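test_that("majority-vote classification follows the tally rules", {
  # plurality genus wins despite a eukaryotic hit
  cl <- classify_contig(make_hits("c1",
                                  c("Wolbachia", "Wolbachia", "Wolbachia",
                                    "Wolbachia", "Wolbachia", "Sodalis",
                                    "Sodalis", "Homo"),
                                  c(rep("Bacteria", 7), "Eukaryota")))
  expect_identical(cl$verdict, "Wolbachia")
  expect_identical(cl$euk_hits, 1L)

  # predominant eukaryotic hits exclude the contig
  cl <- classify_contig(make_hits("c2",
                                  c("Homo", "Homo", "Homo", "Homo",
                                    "Wolbachia", "Wolbachia", "Wolbachia"),
                                  c(rep("Eukaryota", 4), rep("Bacteria", 3))))
  expect_identical(cl$verdict, "EUKARYOTIC_EXCLUDED")

  # no evidence, or an exact tie, gives UNCLASSIFIED
  expect_identical(classify_contig(make_hits("c3"))$verdict, "UNCLASSIFIED")
  cl <- classify_contig(make_hits("c4",
                                  c("Wolbachia", "Wolbachia",
                                    "Sodalis", "Sodalis")))
  expect_identical(cl$verdict, "UNCLASSIFIED")

  # archaeal and viral hits count for neither side
  cl <- classify_contig(make_hits("c5",
                                  c("Wolbachia", "Methanococcus", "Phage"),
                                  c("Bacteria", "Archaea", "Viruses")))
  expect_identical(cl$verdict, "Wolbachia")
  expect_identical(sum(cl$tally), 1L)
})

test_that("classification agrees with the brute-force tally oracle", {
  set.seed(101)
  for (i in 1:300) {
    h <- random_hits()
    expect_identical(classify_contig(h)$verdict, oracle_classify(h),
                     info = paste("case", i))
  }
})

test_that("recruitment returns exactly the contigs with a target-genus hit", {
  set.seed(7)
  hits <- do.call(rbind, lapply(1:100, function(i) {
    genera <- sample(c("Wolbachia", "Sodalis", "Homo", "Escherichia"),
                     sample(1:4, 1), replace = TRUE)
    make_hits(sprintf("ctg%03d", i), genera,
              ifelse(genera == "Homo", "Eukaryota", "Bacteria"))
  }))
  targets <- c("Wolbachia", "Sodalis")
  expected <- sort(unique(hits$contig_id[hits$hit_genus %in% targets]))
  expect_identical(recruit_contigs(hits, targets), expected)
  expect_identical(recruit_contigs(make_hits("x"), targets), character(0))
  expect_error(recruit_contigs(hits, character(0)), "nonempty")
})

test_that("bins partition classified contigs by genus", {
  hits <- rbind(make_hits("w1", rep("Wolbachia", 3)),
                make_hits("w2", rep("Wolbachia", 2)),
                make_hits("w3", "Wolbachia"),
                make_hits("s1", rep("Sodalis", 2)),
                make_hits("s2", rep("Sodalis", 4)),
                make_hits("u1", c("Wolbachia", "Sodalis")),
                make_hits("e1", rep("Homo", 3), rep("Eukaryota", 3)))
  contigs <- data.frame(contig_id = unique(hits$contig_id),
                        stringsAsFactors = FALSE)
  calls <- classify_contigs(hits)
  bins <- build_bins(calls, contigs)
  expect_identical(bins$Wolbachia, c("w1", "w2", "w3"))
  expect_identical(bins$Sodalis, c("s1", "s2"))
  expect_false(any(c("u1", "e1") %in% unlist(bins)))
  # bins are disjoint
  expect_identical(anyDuplicated(unlist(bins)), 0L)
  # all-unclassified input gives an empty mapping
  tie <- classify_contigs(make_hits("t1", c("A", "B")))
  expect_length(build_bins(tie, data.frame(contig_id = "t1")), 0)
  # dangling contig id is an input-consistency error
  expect_error(build_bins(calls, contigs[-1, , drop = FALSE]), "w1")
})

test_that("genome summary computes size, GC and CDS union density", {
  one <- data.frame(contig_id = "c1", sequence = "GGCC",
                    stringsAsFactors = FALSE)
  gs <- genome_summary(one, data.frame(contig_id = "c1", start = 1, end = 4))
  expect_identical(gs$genome_size_bp, 4L)
  expect_equal(gs$gc_percent, 100)
  expect_equal(gs$coding_density_percent, 100)

  at <- data.frame(contig_id = "c1", sequence = "ATATATAT",
                   stringsAsFactors = FALSE)
  gs <- genome_summary(at, data.frame(contig_id = "c1", start = 1, end = 4))
  expect_equal(gs$gc_percent, 0)
  expect_equal(gs$coding_density_percent, 50)

  # overlapping CDS intervals are counted once: union of [1,6] and [4,8] is 8
  ten <- data.frame(contig_id = "c1", sequence = "ACGTACGTAC",
                    stringsAsFactors = FALSE)
  gs <- genome_summary(ten, data.frame(contig_id = c("c1", "c1"),
                                       start = c(1, 4), end = c(6, 8)))
  expect_equal(gs$coding_density_percent, 80)
  expect_identical(gs$cds_count, 2L)

  expect_error(
    genome_summary(ten, data.frame(contig_id = "c1", start = 5, end = 11)),
    "outside")
})

test_that("error-free synthetic metagenomes bin perfectly", {
  cfg <- sim_config(seed = 19, n_hosts = 8, n_origins = 3,
                    hit_error_rate = 0, euk_contig_rate = 0,
                    contigs_per_strain = 10)
  ht <- simulate_host_tree(cfg$n_hosts, seed = cfg$seed)
  sym <- simulate_symbiosis(ht, cfg)
  mg <- simulate_metagenome(sym$association, cfg)
  calls <- classify_contigs(mg$hits)
  merged <- merge(calls, mg$ground_truth, by = "contig_id")
  expect_true(all(merged$verdict == merged$genus))

  # eukaryotic contigs carry only eukaryotic hits and never enter a bin
  cfg2 <- sim_config(seed = 20, n_hosts = 8, n_origins = 3,
                     hit_error_rate = 0, euk_contig_rate = 0.3,
                     contigs_per_strain = 10)
  sym2 <- simulate_symbiosis(simulate_host_tree(8, seed = 20), cfg2)
  mg2 <- simulate_metagenome(sym2$association, cfg2)
  calls2 <- classify_contigs(mg2$hits)
  bins2 <- build_bins(calls2, mg2$contigs)
  euk_ids <- mg2$ground_truth$contig_id[mg2$ground_truth$truth == "EUK"]
  expect_gt(length(euk_ids), 0)
  expect_false(any(euk_ids %in% unlist(bins2)))
})
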