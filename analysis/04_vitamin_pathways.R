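#!/usr/bin/env Rscript
# B-vitamin pathway functionality calls for the simulated cohort. Double
# infections are merged into composite entries before scoring; the
# cohort-absence profile and every excusal are written with the calls, and
# the calls are checked cell-by-cell against the simulation's ground truth.

suppressPackageStartupMessages(library(cimsym))

sim_dir <- file.path("results", "sim")
mat <- read_gene_matrix(file.path(sim_dir, "gene_matrix.tsv"))
assoc <- read_association(file.path(sim_dir, "association.tsv"))

key <- paste(assoc$genus, assoc$host_id, sep = "|")
composites <- list()
for (k in unique(key[duplicated(key)])) {
  composites[[paste0(gsub("\\|", "_", k), "_composite")]] <-
    assoc$strain_id[key == k]
}
cat(length(composites), "double infection(s) merged into composite entries\n")

vm <- vitamin_matrix(mat, default_pathways(), composites = composites)
tab <- table(vm$calls$pathway_id, vm$calls$call)
print(tab)

# sanity: on the raw (non-composite) matrix the production calls must equal
# the ground truth the straight-line reference scorer computed at
# simulation time
truth <- jsonlite::read_json(file.path(sim_dir, "ground_truth.json"),
                             simplifyVector = TRUE)$pathway_truth
raw <- vitamin_matrix(mat, default_pathways())$calls
merged <- merge(raw, truth, by = c("genome_id", "pathway_id"),
                suffixes = c("", "_truth"))
cat("production vs reference ground truth:",
    sum(merged$call == merged$call_truth), "of", nrow(merged),
    "cells identical\n")
stopifnot(all(merged$call == merged$call_truth))

out_dir <- file.path("results", "vitamins")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
utils::write.table(vm$calls, file.path(out_dir, "calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
audit <- lapply(vm$detail, function(pc) {
  list(genome_id = pc$genome_id, pathway_id = pc$pathway_id, call = pc$call,
       missing_steps = pc$missing_steps, excusals = as.list(pc$excusals))
})
write_report_json(list(profile = vm$profile, calls = unname(audit)),
                  file.path(out_dir, "calls_audit.json"))
cat("calls written to", file.path(out_dir, "calls.tsv"), "\n")
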