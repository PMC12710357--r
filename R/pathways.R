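# B-vitamin pathway functionality scoring. A pathway is FUNCTIONAL when every
# step has at least one intact gene copy; a missing step can be excused
# either because the step is known to be catalyzed by alternative enzymes
# outside the canonical definition, or because it is absent across most of
# the symbiont cohort within an otherwise intact pathway (suggesting the gene
# is nonessential in this system). A pathway whose every missing step is
# excused is PUTATIVELY_FUNCTIONAL; anything else is NONFUNCTIONAL.
# Disrupted copies (premature stop codons) never satisfy a step but are
# reported distinctly from absence.

.call_levels <- c("NONFUNCTIONAL", "PUTATIVELY_FUNCTIONAL", "FUNCTIONAL")

#' Load pathway step definitions
#'
#' Reads a JSON or YAML pathway definition file. The expected structure is a
#' top-level `pathways` list; each pathway has a `pathway_id` and ordered
#' `steps`, and each step a `step_id`, a nonempty `genes` vector of
#' interchangeable gene symbols, and a logical
#' `has_known_alternative_enzymes`.
#'
#' @param path File path (`.json`, `.yaml`/`.yml`).
#' @return Named list of pathway definitions.
#' @export
read_pathway_defs <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  pws <- raw$pathways
  if (is.null(pws)) stop("no 'pathways' entry in ", path, call. = FALSE)
  defs <- lapply(pws, function(p) {
    steps <- lapply(p$steps, function(s) {
      genes <- unlist(s$genes)
      if (length(genes) == 0) {
        stop("pathway '", p$pathway_id, "' has a step without genes",
             call. = FALSE)
      }
      list(step_id = s$step_id, genes = as.character(genes),
           has_known_alternative_enzymes =
             isTRUE(s$has_known_alternative_enzymes))
    })
    if (length(steps) == 0) {
      stop("pathway '", p$pathway_id, "' has no steps", call. = FALSE)
    }
    list(pathway_id = p$pathway_id, steps = steps)
  })
  stats::setNames(defs, vapply(defs, `[[`, character(1), "pathway_id"))
}

#' Default B-vitamin pathway definitions shipped with the package
#'
#' Curated definitions for biotin, riboflavin (dephosphorylation step flagged
#' as having alternative enzymes), folate, thiamine, pyridoxal, pantothenate,
#' nicotinate, cobalamin and lipoic acid. These are editable configuration,
#' not ground truth; see the packaged `pathways.json`.
#'
#' @return Named list of pathway definitions.
#' @export
default_pathways <- function() {
  read_pathway_defs(system.file("extdata", "pathways.json",
                                package = "cimsym", mustWork = TRUE))
}

#' Collapse the copy statuses of one gene
#'
#' A duplicated gene is intact when any copy is intact (copy-level
#' complementation, as in a duplicated operon whose two copies carry
#' disruptions in different genes); otherwise disrupted if any copy is
#' disrupted; otherwise absent.
#'
#' @param copies Nonempty character vector with values `INTACT`, `DISRUPTED`,
#'   `ABSENT`.
#' @return One of `"INTACT"`, `"DISRUPTED"`, `"ABSENT"`.
#' @export
gene_status <- function(copies) {
  if (length(copies) == 0) {
    stop("empty copy-status list", call. = FALSE)
  }
  bad <- setdiff(copies, c("INTACT", "DISRUPTED", "ABSENT"))
  if (length(bad) > 0) {
    stop("invalid copy status: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(copies == "INTACT")) return("INTACT")
  if (any(copies == "DISRUPTED")) return("DISRUPTED")
  "ABSENT"
}

# Status of one gene in one genome; genes unlisted in the matrix are ABSENT.
gene_status_in <- function(matrix, genome, gene) {
  st <- matrix$status[matrix$genome_id == genome &
                        matrix$gene_symbol == gene]
  if (length(st) == 0) return("ABSENT")
  gene_status(st)
}

#' Is a pathway step satisfied in a genome?
#'
#' TRUE iff at least one of the step's interchangeable gene symbols has an
#' intact copy in the genome. Genes unlisted in the matrix count as absent.
#'
#' @param genome Genome id.
#' @param step A step definition (list with `genes`).
#' @param matrix Gene copy-status matrix (long data frame; see
#'   [read_gene_matrix()]).
#' @return Logical.
#' @export
step_satisfied <- function(genome, step, matrix) {
  any(vapply(step$genes, function(g) {
    gene_status_in(matrix, genome, g) == "INTACT"
  }, logical(1)))
}

#' Steps absent across most of the symbiont cohort
#'
#' A (pathway, step) pair enters the cohort-absence profile when the step is
#' unsatisfied in strictly more than `majority_fraction` of the analyzed
#' genomes. Such steps are candidates for the nonessential-gene excusal.
#'
#' @param matrix Gene copy-status matrix.
#' @param defs Pathway definitions ([default_pathways()] or
#'   [read_pathway_defs()]).
#' @param genomes Cohort genome ids (default: all in `matrix`). A
#'   single-genome cohort yields an empty profile with a warning, since
#'   "absent in most symbionts" is meaningless for one genome.
#' @param majority_fraction Strict threshold, default 0.5.
#' @return Data frame with columns `pathway_id`, `step_id`.
#' @export
cohort_absence_profile <- function(matrix, defs, genomes = NULL,
                                   majority_fraction = 0.5) {
  if (is.null(genomes)) {
    genomes <- sort(unique(matrix$genome_id))
  }
  empty <- data.frame(pathway_id = character(0), step_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(genomes) < 2) {
    warning("cohort has fewer than 2 genomes; returning empty absence profile")
    return(empty)
  }
  rows <- list()
  for (def in defs) {
    for (step in def$steps) {
      unsat <- sum(!vapply(genomes, step_satisfied, logical(1),
                           step = step, matrix = matrix))
      if (unsat / length(genomes) > majority_fraction) {
        rows[[length(rows) + 1L]] <-
          data.frame(pathway_id = def$pathway_id, step_id = step$step_id,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) empty else do.call(rbind, rows)
}

#' Score one pathway in one genome
#'
#' Missing steps are the unsatisfied ones. Each missing step is assessed
#' individually: it is excused as `ALT_ENZYME` when the step is flagged as
#' having known alternative enzymes, or as `COHORT_ABSENT` when it is in the
#' cohort-absence profile and the pathway is otherwise intact (every step
#' outside the profile is satisfied and at least one step of the pathway is
#' satisfied, so a wholly missing pathway is never excused). The call is
#' `FUNCTIONAL` with no
#' missing steps, `PUTATIVELY_FUNCTIONAL` when every missing step is excused,
#' and `NONFUNCTIONAL` otherwise.
#'
#' @param genome Genome id.
#' @param def One pathway definition.
#' @param matrix Gene copy-status matrix.
#' @param profile Cohort-absence profile from [cohort_absence_profile()]
#'   (default: empty).
#' @return Object of class `pathway_call`: list with `genome_id`,
#'   `pathway_id`, `call`, `missing_steps`, `excusals` (named character:
#'   `ALT_ENZYME`, `COHORT_ABSENT` or `none` per missing step).
#' @export
score_pathway <- function(genome, def, matrix, profile = NULL) {
  sat <- vapply(def$steps, step_satisfied, logical(1),
                genome = genome, matrix = matrix)
  score_satisfaction(genome, def, sat, profile)
}

# Shared core: score a pathway from a per-step satisfaction vector.
score_satisfaction <- function(genome_id, def, sat, profile = NULL) {
  step_ids <- vapply(def$steps, `[[`, character(1), "step_id")
  alt <- vapply(def$steps, `[[`, logical(1), "has_known_alternative_enzymes")
  in_profile <- if (is.null(profile) || nrow(profile) == 0) {
    rep(FALSE, length(step_ids))
  } else {
    step_ids %in% profile$step_id[profile$pathway_id == def$pathway_id]
  }

  missing <- step_ids[!sat]
  # "otherwise intact": every step outside the cohort-absence profile is
  # satisfied, so the only gaps are the cohort-wide ones. A pathway with no
  # intact step at all is wholly missing, not "otherwise intact", and gets
  # no cohort excusal.
  otherwise_intact <- all(sat[!in_profile]) && any(sat)

  excusals <- vapply(seq_along(step_ids), function(i) {
    if (sat[i]) return(NA_character_)
    if (alt[i]) return("ALT_ENZYME")
    if (in_profile[i] && otherwise_intact) return("COHORT_ABSENT")
    "none"
  }, character(1))
  names(excusals) <- step_ids
  excusals <- excusals[!sat]

  call <- if (length(missing) == 0) {
    "FUNCTIONAL"
  } else if (all(excusals != "none")) {
    "PUTATIVELY_FUNCTIONAL"
  } else {
    "NONFUNCTIONAL"
  }
  structure(list(genome_id = genome_id, pathway_id = def$pathway_id,
                 call = call, missing_steps = missing, excusals = excusals),
            class = "pathway_call")
}

#' @export
print.pathway_call <- function(x, ...) {
  cat(sprintf("[%s] %s: %s", x$genome_id, x$pathway_id, x$call))
  if (length(x$missing_steps) > 0) {
    cat("  missing:",
        paste(sprintf("%s(%s)", x$missing_steps, x$excusals), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Host-level pathway call across co-resident symbionts
#'
#' Scores a pathway on the per-step union of satisfaction across all
#' symbionts resident in one host: a step counts as satisfied when any
#' resident satisfies it. This captures cross-symbiont complementation,
#' where two partial pathways combine into a functional one. The combined
#' call is never worse than the best individual resident's call.
#'
#' @param genomes Character vector of resident genome ids (at least one).
#' @param def One pathway definition.
#' @param matrix Gene copy-status matrix.
#' @param profile Cohort-absence profile (default: empty).
#' @return A `pathway_call` whose `genome_id` is the residents joined by
#'   `"+"`.
#' @export
complementation_call <- function(genomes, def, matrix, profile = NULL) {
  if (length(genomes) == 0) {
    stop("at least one resident symbiont is required", call. = FALSE)
  }
  sat <- vapply(def$steps, function(step) {
    any(vapply(genomes, step_satisfied, logical(1),
               step = step, matrix = matrix))
  }, logical(1))
  score_satisfaction(paste(genomes, collapse = "+"), def, sat, profile)
}

#' Merge genomes of a double infection into one composite matrix entry
#'
#' Reassigns all copy rows of `genome_ids` to `composite_id`, renumbering
#' `copy_index` per gene, so a double infection is scored as a single entry.
#'
#' @param matrix Gene copy-status matrix.
#' @param genome_ids Genomes to merge.
#' @param composite_id Id of the merged entry.
#' @return The modified matrix.
#' @export
combine_gene_matrix <- function(matrix, genome_ids, composite_id) {
  sel <- matrix$genome_id %in% genome_ids
  merged <- matrix[sel, , drop = FALSE]
  rest <- matrix[!sel, , drop = FALSE]
  if (nrow(merged) > 0) {
    merged$genome_id <- composite_id
    merged <- merged[order(merged$gene_symbol), , drop = FALSE]
    merged$copy_index <- stats::ave(seq_len(nrow(merged)), merged$gene_symbol,
                                    FUN = seq_along)
  }
  out <- rbind(rest, merged)
  rownames(out) <- NULL
  out
}

#' Score every genome against every pathway
#'
#' Builds the genome x pathway call matrix for a cohort. Double infections
#' are first merged into composite entries (one entry per host, pooling all
#' copies of each gene across the co-resident strains); the cohort-absence
#' profile is then computed over the resulting entries and applied to each
#' call. Results are independent of genome or pathway iteration order.
#'
#' @param matrix Gene copy-status matrix.
#' @param defs Pathway definitions (default: [default_pathways()]).
#' @param composites Optional named list: composite id -> character vector of
#'   genome ids to merge (e.g. the two strains of a double infection).
#' @param majority_fraction Passed to [cohort_absence_profile()].
#' @return List with `calls` (data frame `genome_id`, `pathway_id`, `call`),
#'   `detail` (list of `pathway_call` objects), and `profile`.
#' @export
vitamin_matrix <- function(matrix, defs = default_pathways(),
                           composites = NULL, majority_fraction = 0.5) {
  matrix <- validate_gene_matrix(matrix)
  if (!is.null(composites)) {
    for (cid in names(composites)) {
      matrix <- combine_gene_matrix(matrix, composites[[cid]], cid)
    }
  }
  genomes <- sort(unique(matrix$genome_id))
  profile <- cohort_absence_profile(matrix, defs, genomes,
                                    majority_fraction = majority_fraction)
  defs <- defs[order(names(defs))]
  detail <- list()
  rows <- list()
  for (g in genomes) {
    for (def in defs) {
      pc <- score_pathway(g, def, matrix, profile)
      detail[[paste(g, def$pathway_id, sep = "|")]] <- pc
      rows[[length(rows) + 1L]] <-
        data.frame(genome_id = g, pathway_id = def$pathway_id,
                   call = pc$call, stringsAsFactors = FALSE)
    }
  }
  list(calls = do.call(rbind, rows), detail = detail, profile = profile)
}
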