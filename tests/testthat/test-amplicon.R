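test_that("taxonomic filter removes organelle and non-bacterial OTUs only", {
  counts <- matrix(10L, nrow = 10, ncol = 2,
                   dimnames = list(paste0("otu", 1:10), c("s1", "s2")))
  tax <- c(otu1 = "Bacteria;Proteobacteria;;;;Wolbachia",
           otu2 = "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast;;",
           otu3 = "Eukaryota;Ascomycota;;;;",
           otu4 = "Archaea;Euryarchaeota;;;;",
           otu5 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria;",
           otu6 = "Bacteria;Firmicutes;;;;Staphylococcus",
           otu7 = "d__Bacteria;p__Proteobacteria;;;;g__Sodalis",
           otu8 = "Unassigned",
           otu9 = "Bacteria;Proteobacteria;;;;Serratia",
           otu10 = "Bacteria;Bacteroidota;;;;Flavobacterium")
  filtered <- taxonomic_filter(otu_table(counts, tax))
  # otu2 (chloroplast), otu3 (eukaryote), otu4 (archaeon), otu5 (mitochondria)
  expect_setequal(rownames(filtered$counts),
                  c("otu1", "otu6", "otu7", "otu8", "otu9", "otu10"))
  expect_identical(attr(filtered, "otus_removed_taxonomy"), 4L)

  # a purely bacterial table passes through unchanged
  bact <- otu_table(counts[c(1, 6), , drop = FALSE], tax[c(1, 6)])
  expect_identical(taxonomic_filter(bact)$counts, bact$counts)
})

test_that("abundance floor zeroes strictly-below-threshold cells per sample", {
  counts <- cbind(sA = c(9L, 10L, 981L), sB = c(400L, 100L, 500L))
  rownames(counts) <- c("low", "edge", "big")
  out <- abundance_floor(otu_table(counts))
  # 9/1000 < 1% -> zeroed; 10/1000 == 1% exactly -> retained
  expect_identical(out$table$counts["low", "sA"], 0L)
  expect_identical(out$table$counts["edge", "sA"], 10L)
  # same OTU abundant in sB is untouched there (no cross-sample rescue)
  expect_identical(out$table$counts["low", "sB"], 400L)
  expect_identical(out$report$cells_zeroed, 1L)
})

test_that("abundance floor handles zero-total samples and is idempotent", {
  counts <- cbind(empty = c(0L, 0L), mixed = c(3L, 997L))
  rownames(counts) <- c("a", "b")
  once <- abundance_floor(otu_table(counts))
  expect_identical(once$table$counts[, "empty"], c(a = 0L, b = 0L))
  twice <- abundance_floor(once$table)
  expect_identical(twice$table$counts, once$table$counts)
  expect_identical(twice$report$cells_zeroed, 0L)
  # floor never increases any cell
  expect_true(all(once$table$counts <= counts))
})

test_that("abundance floor is idempotent on random tables", {
  set.seed(42)
  for (i in 1:20) {
    counts <- matrix(rpois(30, lambda = sample(c(2, 50, 500), 1)),
                     nrow = 6,
                     dimnames = list(paste0("o", 1:6), paste0("s", 1:5)))
    tab <- otu_table(counts)
    once <- abundance_floor(tab)$table
    twice <- abundance_floor(once)$table
    expect_identical(twice$counts, once$counts)
    expect_true(all(once$counts <= counts))
  }
})

test_that("rarefaction subsamples to exact depth and drops shallow samples", {
  counts <- cbind(deep = c(9000L, 1000L), exact = c(300L, 700L),
                  shallow = c(500L, 300L))
  rownames(counts) <- c("A", "B")
  out <- rarefy(otu_table(counts), depth = 1000, seed = 5)
  expect_setequal(colnames(out$table$counts), c("deep", "exact"))
  expect_identical(out$report$samples_dropped, "shallow")
  expect_true(all(colSums(out$table$counts) == 1000L))
  # a sample at exactly the target depth is returned unchanged
  expect_identical(out$table$counts[, "exact"], counts[, "exact"])
  # seed reproducibility
  again <- rarefy(otu_table(counts), depth = 1000, seed = 5)
  expect_identical(again$table$counts, out$table$counts)
})

test_that("rarefaction of an empty table returns an empty table", {
  counts <- matrix(integer(0), nrow = 0, ncol = 2,
                   dimnames = list(character(0), c("s1", "s2")))
  out <- rarefy(otu_table(counts), depth = 10, seed = 1)
  expect_identical(nrow(out$table$counts), 0L)
  expect_setequal(out$report$samples_dropped, c("s1", "s2"))
})

test_that("dominant OTUs are ranked by total with lexicographic ties", {
  counts <- cbind(s1 = c(20L, 30L, 10L, 20L), s2 = c(30L, 0L, 10L, 30L))
  rownames(counts) <- c("zeta", "beta", "gamma", "alpha")  # totals 50/30/20/50
  dom <- dominant_otus(otu_table(counts), k = 3)
  expect_identical(dom$otu_ids, c("alpha", "zeta", "beta"))
  expect_false(dom$truncated)
  # per-sample relative abundances never exceed 1
  expect_true(all(colSums(dom$rel_abund) <= 1 + 1e-12))
  # k beyond the table returns everything and flags it
  all_dom <- dominant_otus(otu_table(counts), k = 13)
  expect_identical(length(all_dom$otu_ids), 4L)
  expect_true(all_dom$truncated)
  # single-OTU table
  single <- dominant_otus(otu_table(counts[1, , drop = FALSE]), k = 1)
  expect_identical(single$otu_ids, "zeta")
})

test_that("screening pipeline applies filter before the floor", {
  # chloroplast reads dominate sample s1; the bacterial OTU is 0.9% of the
  # raw total but 9% of the post-filter total, so it must survive the floor
  counts <- cbind(s1 = c(9L, 900L, 91L), s2 = c(2000L, 0L, 0L))
  rownames(counts) <- c("bact1", "chloro", "bact2")
  tax <- c(bact1 = "Bacteria;;;;;Wolbachia",
           chloro = "Bacteria;Cyanobacteria;;Chloroplast;;",
           bact2 = "Bacteria;;;;;Sodalis")
  out <- amplicon_pipeline(otu_table(counts, tax), depth = 100, seed = 2)
  expect_false("chloro" %in% rownames(out$table$counts))
  expect_true(out$table$counts["bact1", "s1"] > 0)
  expect_identical(out$report$otus_removed_taxonomy, 1L)
})
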