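# Straight-line reference implementation of the pathway scoring rules, used
# to compute ground truth for simulated gene matrices and as the independent
# oracle in tests. Deliberately naive (explicit loops, no shared helpers
# with the production scorer in pathways.R); keep it that way.

#' Reference pathway call (naive implementation)
#'
#' Recomputes the call for one (genome, pathway) pair from first principles:
#' a step is satisfied when any of its genes has at least one INTACT row; a
#' step is cohort-absent when listed in `profile_steps`; a missing step is
#' excused by the alternative-enzyme flag, or by cohort absence provided all
#' steps outside `profile_steps` are satisfied.
#'
#' @param genome Genome id.
#' @param def One pathway definition.
#' @param matrix Gene copy-status matrix (long data frame).
#' @param profile_steps Character vector of cohort-absent step ids for this
#'   pathway.
#' @return One of `"FUNCTIONAL"`, `"PUTATIVELY_FUNCTIONAL"`,
#'   `"NONFUNCTIONAL"`.
#' @export
reference_pathway_call <- function(genome, def, matrix, profile_steps = character(0)) {
  n_steps <- length(def$steps)
  sat <- logical(n_steps)
  for (i in 1:n_steps) {
    ok <- FALSE
    for (gene in def$steps[[i]]$genes) {
      statuses <- character(0)
      for (r in seq_len(nrow(matrix))) {
        if (matrix$genome_id[r] == genome && matrix$gene_symbol[r] == gene) {
          statuses <- c(statuses, matrix$status[r])
        }
      }
      has_intact <- FALSE
      for (s in statuses) {
        if (s == "INTACT") has_intact <- TRUE
      }
      if (has_intact) ok <- TRUE
    }
    sat[i] <- ok
  }

  all_non_profile_ok <- TRUE
  for (i in 1:n_steps) {
    if (!(def$steps[[i]]$step_id %in% profile_steps) && !sat[i]) {
      all_non_profile_ok <- FALSE
    }
  }
  any_sat <- FALSE
  for (i in 1:n_steps) {
    if (sat[i]) any_sat <- TRUE
  }

  n_missing <- 0
  n_excused <- 0
  for (i in 1:n_steps) {
    if (!sat[i]) {
      n_missing <- n_missing + 1
      if (def$steps[[i]]$has_known_alternative_enzymes) {
        n_excused <- n_excused + 1
      } else if (def$steps[[i]]$step_id %in% profile_steps &&
                 all_non_profile_ok && any_sat) {
        n_excused <- n_excused + 1
      }
    }
  }

  if (n_missing == 0) {
    "FUNCTIONAL"
  } else if (n_missing == n_excused) {
    "PUTATIVELY_FUNCTIONAL"
  } else {
    "NONFUNCTIONAL"
  }
}

#' Reference genome x pathway calls (naive implementation)
#'
#' Computes the cohort-absence profile and all calls with explicit loops.
#'
#' @param matrix Gene copy-status matrix.
#' @param defs Pathway definitions.
#' @param genomes Cohort genome ids.
#' @param majority_fraction Strict cohort-absence threshold (default 0.5).
#' @return Data frame with `genome_id`, `pathway_id`, `call`.
#' @export
reference_vitamin_calls <- function(matrix, defs, genomes,
                                    majority_fraction = 0.5) {
  step_unsat <- function(genome, step) {
    for (gene in step$genes) {
      for (r in seq_len(nrow(matrix))) {
        if (matrix$genome_id[r] == genome &&
            matrix$gene_symbol[r] == gene &&
            matrix$status[r] == "INTACT") {
          return(FALSE)
        }
      }
    }
    TRUE
  }

  profile <- list()
  if (length(genomes) >= 2) {
    for (def in defs) {
      absent_steps <- character(0)
      for (step in def$steps) {
        n_unsat <- 0
        for (g in genomes) {
          if (step_unsat(g, step)) n_unsat <- n_unsat + 1
        }
        if (n_unsat / length(genomes) > majority_fraction) {
          absent_steps <- c(absent_steps, step$step_id)
        }
      }
      profile[[def$pathway_id]] <- absent_steps
    }
  } else {
    for (def in defs) profile[[def$pathway_id]] <- character(0)
  }

  out <- NULL
  for (g in sort(genomes)) {
    for (pid in sort(names(defs))) {
      call <- reference_pathway_call(g, defs[[pid]], matrix, profile[[pid]])
      out <- rbind(out, data.frame(genome_id = g, pathway_id = pid,
                                   call = call, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
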