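# End-to-end driver chaining simulate -> amplicon-filter -> bin ->
# deconvolve -> vitamins -> origins. Each stage is independently invocable
# through its exported function; run_pipeline only wires them together,
# logs progress, and writes one consolidated JSON report. Reports carry no
# timestamps (those go to the log), so reruns with the same config and seed
# are byte-identical.

default_run_config <- function() {
  list(
    out_dir = file.path("results", "run"),
    seed = 1L,
    input_dir = NULL,
    stages = list(simulate = TRUE, amplicon = TRUE, bin = TRUE,
                  deconvolve = TRUE, vitamins = TRUE, origins = TRUE),
    sim = list(),
    amplicon = list(threshold = 0.01, depth = 1000, top_k = 13),
    bin = list(target_genera = NULL),
    deconvolve = list(band_fraction = 0.2, dup_threshold = 0.2),
    vitamins = list(majority_fraction = 0.5, defs_path = NULL),
    origins = list(min_clade_size = 2, use_packaged_data = FALSE)
  )
}

#' Run the full analysis pipeline
#'
#' Stages run in a fixed order: simulate, amplicon filtering, contig
#' binning, strain deconvolution, vitamin-pathway scoring, origin counting.
#' Any stage can be toggled off. When the simulate stage is off, the
#' remaining stages read their inputs from `input_dir` (the interchange
#' files written by [write_fixture()]); missing input files are reported by
#' name before any stage runs. The consolidated report embeds each stage's
#' report and is written to `<out_dir>/report.json`.
#'
#' @param config A nested list, or a path to a YAML/JSON file with the same
#'   structure; unspecified entries fall back to defaults (see Details in
#'   the package vignette). Top-level entries: `out_dir`, `seed`,
#'   `input_dir`, `stages`, and per-stage parameter lists `sim`, `amplicon`,
#'   `bin`, `deconvolve`, `vitamins`, `origins`.
#' @param quiet Suppress log messages (default FALSE).
#' @return The consolidated report, invisibly.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    if (!quiet) message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  # pre-flight input check: every enabled non-simulate stage must find its
  # files when nothing is simulated in-memory
  data <- list()
  if (!isTRUE(cfg$stages$simulate)) {
    needed <- character(0)
    if (isTRUE(cfg$stages$amplicon)) needed <- c(needed, "otu_table.tsv")
    if (isTRUE(cfg$stages$bin)) needed <- c(needed, "hits.tsv", "coverage.tsv")
    if (isTRUE(cfg$stages$deconvolve)) {
      needed <- c(needed, "orthogroups.tsv", "coverage.tsv", "hits.tsv")
    }
    if (isTRUE(cfg$stages$vitamins)) {
      needed <- c(needed, "gene_matrix.tsv", "association.tsv")
    }
    if (isTRUE(cfg$stages$origins) &&
        !isTRUE(cfg$origins$use_packaged_data)) {
      needed <- c(needed, "association.tsv", "host_tree.nwk")
    }
    needed <- unique(needed)
    if (length(needed) > 0) {
      if (is.null(cfg$input_dir)) {
        stop("input_dir must be set when the simulate stage is disabled",
             call. = FALSE)
      }
      paths <- file.path(cfg$input_dir, needed)
      absent <- paths[!file.exists(paths)]
      if (length(absent) > 0) {
        stop("missing input file(s): ", paste(absent, collapse = ", "),
             call. = FALSE)
      }
      data <- read_fixture_inputs(cfg$input_dir)
    }
  }

  report <- list(seed = cfg$seed,
                 stages_run = names(Filter(isTRUE, cfg$stages)))

  if (isTRUE(cfg$stages$simulate)) {
    log_msg("stage simulate: generating synthetic study")
    scfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                  as.list(cfg$sim)))
    host_tree <- simulate_host_tree(scfg$n_hosts, seed = scfg$seed)
    sym <- simulate_symbiosis(host_tree, scfg)
    metag <- simulate_metagenome(sym$association, scfg)
    gm <- simulate_gene_matrix(sym$association$strain_id, cfg = scfg)
    otu <- simulate_otu_table(sym$association, scfg)
    data <- list(host_tree = host_tree, association = sym$association,
                 genus_trees = sym$genus_trees, metagenome = metag,
                 gene_matrix = gm, otu = otu,
                 ground_truth = sym$ground_truth)
    write_fixture(c(data, list(ground_truth = sym$ground_truth)),
                  file.path(cfg$out_dir, "sim"))
    report$simulate <- list(
      n_hosts = scfg$n_hosts,
      n_strains = nrow(sym$association),
      true_origins = sym$ground_truth$n_origins)
  }

  if (isTRUE(cfg$stages$amplicon)) {
    log_msg("stage amplicon: taxonomic filter, abundance floor, rarefaction")
    amp <- amplicon_pipeline(data$otu, threshold = cfg$amplicon$threshold,
                             depth = cfg$amplicon$depth, seed = cfg$seed,
                             k = cfg$amplicon$top_k)
    report$amplicon <- c(amp$report,
                         list(dominant_otus = amp$dominant$otu_ids))
    data$otu_filtered <- amp$table
  }

  calls <- NULL
  if (isTRUE(cfg$stages$bin)) {
    log_msg("stage bin: majority-vote contig classification")
    targets <- cfg$bin$target_genera
    hits <- data$metagenome$hits
    if (!is.null(targets)) {
      recruited <- recruit_contigs(hits, targets)
      hits <- hits[hits$contig_id %in% recruited, , drop = FALSE]
    }
    calls <- classify_contigs(hits)
    bins <- build_bins(calls, data$metagenome$contigs)
    report$bin <- list(
      n_contigs = nrow(data$metagenome$contigs),
      n_classified = sum(!(calls$verdict %in%
                             c("UNCLASSIFIED", "EUKARYOTIC_EXCLUDED"))),
      n_unclassified = sum(calls$verdict == "UNCLASSIFIED"),
      n_eukaryotic_excluded = sum(calls$verdict == "EUKARYOTIC_EXCLUDED"),
      bin_sizes = lapply(bins, length))
    data$bins <- bins
    data$calls <- calls
  }

  if (isTRUE(cfg$stages$deconvolve)) {
    log_msg("stage deconvolve: double-infection detection and coverage split")
    og <- data$metagenome$orthogroups
    cov <- stats::setNames(data$metagenome$contigs$coverage,
                           data$metagenome$contigs$contig_id)
    host_of_contig <- if (!is.null(data$metagenome$contigs$host_id)) {
      stats::setNames(data$metagenome$contigs$host_id,
                      data$metagenome$contigs$contig_id)
    } else {
      NULL
    }
    groups <- unique(og[, c("host_id", "genus")])
    dec <- list()
    for (i in seq_len(nrow(groups))) {
      h <- groups$host_id[i]; g <- groups$genus[i]
      prof <- og[og$host_id == h & og$genus == g, ]
      dd <- detect_double_infection(prof,
                                    cfg$deconvolve$dup_threshold)
      entry <- list(host_id = h, genus = g, double_infection = dd$flag,
                    duplicated_fraction = dd$duplicated_fraction)
      if (dd$flag && !is.null(data$calls) && !is.null(host_of_contig)) {
        ids <- data$calls$contig_id[data$calls$verdict == g]
        ids <- ids[host_of_contig[ids] == h]
        if (length(ids) >= 4) {
          sp <- split_by_coverage(cov[ids],
                                  band_fraction = cfg$deconvolve$band_fraction)
          entry$split <- if (sp$refused) {
            list(refused = TRUE, reason = sp$reason)
          } else {
            list(refused = FALSE,
                 threshold_log2 = sp$threshold_log2,
                 n_high = sum(sp$assignment == "HIGH"),
                 n_low = sum(sp$assignment == "LOW"),
                 n_excluded = sum(sp$assignment == "EXCLUDED_INTERMEDIATE"))
          }
        }
      }
      dec[[length(dec) + 1L]] <- entry
    }
    report$deconvolve <- dec
  }

  if (isTRUE(cfg$stages$vitamins)) {
    log_msg("stage vitamins: pathway functionality scoring")
    defs <- if (is.null(cfg$vitamins$defs_path)) {
      default_pathways()
    } else {
      read_pathway_defs(cfg$vitamins$defs_path)
    }
    assoc <- data$association
    key <- paste(assoc$genus, assoc$host_id, sep = "|")
    composites <- list()
    for (k in unique(key[duplicated(key)])) {
      members <- assoc$strain_id[key == k]
      composites[[paste0(gsub("\\|", "_", k), "_composite")]] <- members
    }
    vm <- vitamin_matrix(data$gene_matrix$matrix, defs,
                         composites = if (length(composites)) composites,
                         majority_fraction = cfg$vitamins$majority_fraction)
    report$vitamins <- list(
      n_entries = length(unique(vm$calls$genome_id)),
      calls_by_level = as.list(table(vm$calls$call)),
      cohort_absent_steps = if (nrow(vm$profile) > 0) {
        paste(vm$profile$pathway_id, vm$profile$step_id, sep = ":")
      } else {
        character(0)
      })
    data$vitamin_calls <- vm
  }

  if (isTRUE(cfg$stages$origins)) {
    log_msg("stage origins: coevolving-clade collapse and acquisition count")
    if (isTRUE(cfg$origins$use_packaged_data)) {
      rep_or <- cimicid_origin_report(min_size = cfg$origins$min_clade_size)
    } else {
      clades <- list()
      for (g in names(data$genus_trees)) {
        assoc_g <- data$association[data$association$genus == g, ]
        clades <- c(clades, find_coevolving_clades(
          data$genus_trees[[g]], data$host_tree, assoc_g,
          min_size = cfg$origins$min_clade_size))
      }
      rep_or <- count_origins(data$association, clades)
    }
    report$origins <- list(
      per_genus = rep_or$per_genus,
      total = rep_or$total,
      n_clades_collapsed = length(rep_or$clades))
    if (!is.null(data$ground_truth)) {
      report$origins$true_total <- data$ground_truth$n_origins
    }
    data$origin_report <- rep_or
  }

  write_report_json(report, file.path(cfg$out_dir, "report.json"))
  log_msg("pipeline complete; report written to ",
          file.path(cfg$out_dir, "report.json"))
  invisible(c(report, list(data = data)))
}

# Load interchange files written by write_fixture() for a file-driven run.
read_fixture_inputs <- function(dir) {
  data <- list()
  f <- function(name) file.path(dir, name)
  if (file.exists(f("association.tsv"))) {
    data$association <- read_association(f("association.tsv"))
  }
  if (file.exists(f("host_tree.nwk"))) {
    data$host_tree <- read_newick(f("host_tree.nwk"))
  }
  trees <- list.files(dir, pattern = "^tree_.*\\.nwk$", full.names = TRUE)
  if (length(trees) > 0 && !is.null(data$association)) {
    genera <- unique(data$association$genus)
    gt <- list()
    for (g in genera) {
      p <- f(paste0("tree_", tolower(g), ".nwk"))
      if (file.exists(p)) gt[[g]] <- read_newick(p)
    }
    data$genus_trees <- gt
  }
  if (file.exists(f("hits.tsv"))) {
    data$metagenome$hits <- read_hits(f("hits.tsv"))
  }
  if (file.exists(f("coverage.tsv"))) {
    data$metagenome$contigs <- utils::read.delim(f("coverage.tsv"),
                                                 stringsAsFactors = FALSE)
  }
  if (file.exists(f("orthogroups.tsv"))) {
    data$metagenome$orthogroups <- utils::read.delim(f("orthogroups.tsv"),
                                                     stringsAsFactors = FALSE)
  }
  if (file.exists(f("gene_matrix.tsv"))) {
    data$gene_matrix <- list(matrix = read_gene_matrix(f("gene_matrix.tsv")))
  }
  if (file.exists(f("otu_table.tsv"))) {
    data$otu <- read_otu_tsv(f("otu_table.tsv"))
  }
  data
}
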