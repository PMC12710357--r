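make_def <- function(id, genes, alt = rep(FALSE, length(genes))) {
  list(pathway_id = id,
       steps = lapply(seq_along(genes), function(i) {
         list(step_id = names(genes)[i] %||% genes[[i]][1],
              genes = genes[[i]],
              has_known_alternative_enzymes = alt[i])
       }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mat_row <- function(genome, gene, status, copy = seq_along(status)) {
  data.frame(genome_id = genome, gene_symbol = gene, copy_index = copy,
             status = status, stringsAsFactors = FALSE)
}

test_that("gene status collapses copies with complementation", {
  # a duplicated operon complements: one intact copy is enough
  expect_identical(gene_status(c("DISRUPTED", "INTACT")), "INTACT")
  expect_identical(gene_status("ABSENT"), "ABSENT")
  expect_identical(gene_status(c("DISRUPTED", "DISRUPTED")), "DISRUPTED")
  expect_identical(gene_status(c("ABSENT", "DISRUPTED")), "DISRUPTED")
  expect_error(gene_status(character(0)), "empty")
  expect_error(gene_status("BROKEN"), "invalid")
})

test_that("step satisfaction requires one intact gene among alternatives", {
  mat <- rbind(mat_row("g1", "panE", "INTACT"),
               mat_row("g1", "bioB", "DISRUPTED"),
               mat_row("g2", "panD", "ABSENT"))
  step_pan <- list(step_id = "pan", genes = c("panD", "panE"),
                   has_known_alternative_enzymes = FALSE)
  step_bio <- list(step_id = "bioB", genes = "bioB",
                   has_known_alternative_enzymes = FALSE)
  expect_true(step_satisfied("g1", step_pan, mat))
  # disrupted-only does not satisfy; unlisted genes count as absent
  expect_false(step_satisfied("g1", step_bio, mat))
  expect_false(step_satisfied("g2", step_pan, mat))
  expect_false(step_satisfied("g3", step_pan, mat))
})

test_that("cohort absence profile uses a strict majority", {
  def <- make_def("p", list(s1 = "x", s2 = "y"))
  genomes <- paste0("g", 1:22)
  # 13 of 22 genomes lack gene x; everyone has y
  mat <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    rbind(if (i > 13) mat_row(genomes[i], "x", "INTACT"),
          mat_row(genomes[i], "y", "INTACT"))
  }))
  prof <- cohort_absence_profile(mat, list(p = def), genomes)
  expect_identical(prof$step_id, "s1")
  # absent in exactly half the cohort stays out (strict inequality)
  mat_half <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    rbind(if (i > 11) mat_row(genomes[i], "x", "INTACT"),
          mat_row(genomes[i], "y", "INTACT"))
  }))
  expect_identical(nrow(cohort_absence_profile(mat_half, list(p = def),
                                               genomes)), 0L)
  # a single-genome cohort yields an empty profile with a warning
  expect_warning(
    p1 <- cohort_absence_profile(mat[mat$genome_id == "g1", ],
                                 list(p = def), "g1"),
    "fewer than 2")
  expect_identical(nrow(p1), 0L)
})

test_that("pathway scoring applies the excusal rules", {
  defs <- default_pathways()
  rib_genes <- unlist(lapply(defs$riboflavin$steps, `[[`, "genes"))
  # complete riboflavin pathway -> FUNCTIONAL
  full <- do.call(rbind, lapply(rib_genes, mat_row,
                                genome = "g1", status = "INTACT"))
  expect_identical(score_pathway("g1", defs$riboflavin, full)$call,
                   "FUNCTIONAL")
  # canonical dephosphorylation gene missing, step flagged for alternative
  # enzymes -> PUTATIVELY_FUNCTIONAL
  noderib <- full[!full$gene_symbol %in% c("yigB", "ybjI"), ]
  pc <- score_pathway("g1", defs$riboflavin, noderib)
  expect_identical(pc$call, "PUTATIVELY_FUNCTIONAL")
  expect_identical(unname(pc$excusals["dephosphorylation"]), "ALT_ENZYME")
  # two unexcusable missing steps -> NONFUNCTIONAL
  broken <- full[!full$gene_symbol %in% c("ribA", "ribB"), ]
  pc <- score_pathway("g1", defs$riboflavin, broken)
  expect_identical(pc$call, "NONFUNCTIONAL")
  expect_setequal(pc$missing_steps, c("ribA", "ribB"))
})

test_that("cohort-absent steps are excused only in otherwise intact pathways", {
  def <- make_def("p", list(s1 = "a", s2 = "b", s3 = "c"))
  profile <- data.frame(pathway_id = "p", step_id = "s2",
                        stringsAsFactors = FALSE)
  # missing only the cohort-absent step -> excused
  mat <- rbind(mat_row("g1", "a", "INTACT"), mat_row("g1", "c", "INTACT"))
  pc <- score_pathway("g1", def, mat, profile)
  expect_identical(pc$call, "PUTATIVELY_FUNCTIONAL")
  expect_identical(unname(pc$excusals["s2"]), "COHORT_ABSENT")
  # an additional inexcusable gap voids the cohort excusal
  mat2 <- mat_row("g1", "a", "INTACT")
  pc2 <- score_pathway("g1", def, mat2, profile)
  expect_identical(pc2$call, "NONFUNCTIONAL")
  expect_identical(unname(pc2$excusals["s2"]), "none")
  # a wholly missing pathway is never excused, even if every step is
  # cohort-absent
  prof_all <- data.frame(pathway_id = "p", step_id = c("s1", "s2", "s3"))
  pc3 <- score_pathway("g1", def,
                       mat_row("g1", "zzz", "INTACT"), prof_all)
  expect_identical(pc3$call, "NONFUNCTIONAL")
})

test_that("cross-symbiont complementation combines partial pathways", {
  def <- make_def("p", list(s1 = "a", s2 = "b", s3 = "c"))
  mat <- rbind(mat_row("r1", "a", "INTACT"), mat_row("r1", "b", "INTACT"),
               mat_row("r2", "c", "INTACT"))
  expect_identical(score_pathway("r1", def, mat)$call, "NONFUNCTIONAL")
  expect_identical(score_pathway("r2", def, mat)$call, "NONFUNCTIONAL")
  comb <- complementation_call(c("r1", "r2"), def, mat)
  expect_identical(comb$call, "FUNCTIONAL")
  expect_identical(comb$genome_id, "r1+r2")
  # single resident: identical to its own call
  expect_identical(complementation_call("r1", def, mat)$call,
                   score_pathway("r1", def, mat)$call)
  expect_error(complementation_call(character(0), def, mat), "at least one")
})

test_that("combined host call never falls below the best resident call", {
  set.seed(55)
  defs <- default_pathways()
  lv <- c(NONFUNCTIONAL = 1, PUTATIVELY_FUNCTIONAL = 2, FUNCTIONAL = 3)
  for (i in 1:25) {
    mat <- random_gene_matrix(c("r1", "r2"))
    def <- defs[[sample(names(defs), 1)]]
    best <- max(lv[score_pathway("r1", def, mat)$call],
                lv[score_pathway("r2", def, mat)$call])
    comb <- lv[complementation_call(c("r1", "r2"), def, mat)$call]
    expect_gte(comb, best)
  }
})

test_that("upgrading a copy status never downgrades a call (fixed profile)", {
  set.seed(77)
  defs <- default_pathways()
  lv <- c(NONFUNCTIONAL = 1, PUTATIVELY_FUNCTIONAL = 2, FUNCTIONAL = 3)
  upgrade <- c(ABSENT = "DISRUPTED", DISRUPTED = "INTACT",
               INTACT = "INTACT")
  for (i in 1:25) {
    mat <- random_gene_matrix("g1")
    profile <- cohort_absence_profile(
      rbind(mat, random_gene_matrix("g2")), defs, c("g1", "g2"))
    r <- sample(nrow(mat), 1)
    mat2 <- mat
    mat2$status[r] <- upgrade[mat$status[r]]
    for (def in defs) {
      before <- lv[score_pathway("g1", def, mat, profile)$call]
      after <- lv[score_pathway("g1", def, mat2, profile)$call]
      expect_gte(after, before)
    }
  }
})

test_that("calls are independent of row and iteration order", {
  set.seed(88)
  mat <- random_gene_matrix(c("gA", "gB", "gC"))
  vm1 <- vitamin_matrix(mat)
  vm2 <- vitamin_matrix(mat[sample(nrow(mat)), ])
  expect_identical(vm1$calls, vm2$calls)
})

test_that("production scorer matches the straight-line reference", {
  set.seed(99)
  defs <- default_pathways()
  for (i in 1:20) {
    mat <- random_gene_matrix(c("g1", "g2", "g3"))
    vm <- vitamin_matrix(mat, defs)
    ref <- reference_vitamin_calls(mat, defs, c("g1", "g2", "g3"))
    expect_identical(vm$calls, ref, info = paste("matrix", i))
  }
})

test_that("double infections are scored as one composite entry", {
  def <- make_def("p", list(s1 = "a", s2 = "b"))
  # two co-resident strains, each with half the pathway
  mat <- rbind(mat_row("w_high", "a", "INTACT"),
               mat_row("w_high", "b", "DISRUPTED"),
               mat_row("w_low", "b", "INTACT"),
               mat_row("other", "a", "INTACT"),
               mat_row("other", "b", "INTACT"))
  vm <- vitamin_matrix(mat, list(p = def),
                       composites = list(host1 = c("w_high", "w_low")))
  expect_setequal(unique(vm$calls$genome_id), c("host1", "other"))
  expect_identical(vm$calls$call[vm$calls$genome_id == "host1"], "FUNCTIONAL")
  # merged copies are renumbered per gene
  merged <- combine_gene_matrix(mat, c("w_high", "w_low"), "host1")
  b_rows <- merged[merged$genome_id == "host1" &
                     merged$gene_symbol == "b", ]
  expect_identical(sort(b_rows$copy_index), c(1L, 2L))
})
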