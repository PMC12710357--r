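# Counting the minimum number of independent symbiont acquisitions on the
# host phylogeny. A group of strains forming a clade in the symbiont tree is
# collapsed into a single acquisition when it shows a cospeciation signal:
# its hosts form a monophyletic group on the host tree and the two induced
# topologies are identical (unrooted RF = 0). Everything else is a singleton
# acquisition.

#' Find host-congruent coevolving clades in a symbiont genus tree
#'
#' Searches the genus tree top-down for maximal clades that carry a
#' cospeciation signal. A clade of strains qualifies when
#' \enumerate{
#'   \item it has at least `min_size` strains, each mapped to a distinct host
#'     sample (a clade containing both strains of a double infection never
#'     qualifies);
#'   \item its hosts form a monophyletic group on the host tree (the symbiont
#'     lineage is associated with a group of closely related hosts, the
#'     hallmark of cospeciation as opposed to repeated horizontal
#'     acquisition);
#'   \item the clade's topology, relabeled strain-to-host, is identical to the
#'     induced host subtree ([rf_distance()] of 0 on the unrooted induced
#'     topologies).
#' }
#' Clades of two strains are topologically congruent by construction (only one
#' topology exists on two leaves) and are flagged `trivial = TRUE`; for them
#' the host-monophyly condition carries the whole signal. The search is
#' greedy from the root: the largest qualifying clades are accepted first and
#' their interiors are not revisited, which guarantees the returned clades are
#' maximal and disjoint.
#'
#' @param genus_tree `phylo`; leaves are strain ids of one symbiont genus.
#' @param host_tree `phylo`; leaves are host sample ids.
#' @param assoc Association data frame with columns `strain_id`, `host_id`,
#'   `genus` (see [read_association()]).
#' @param min_size Minimum number of strains in a reported clade (default 2).
#' @return A list of coevolving clades, each a list with elements `genus`,
#'   `strain_ids`, `host_ids`, `size`, `trivial`.
#' @export
find_coevolving_clades <- function(genus_tree, host_tree, assoc, min_size = 2) {
  stopifnot(inherits(genus_tree, "phylo"), inherits(host_tree, "phylo"))
  assoc <- validate_association(assoc)
  host_of <- stats::setNames(assoc$host_id, assoc$strain_id)
  genus_of <- stats::setNames(assoc$genus, assoc$strain_id)

  unmapped <- setdiff(genus_tree$tip.label, names(host_of))
  if (length(unmapped) > 0) {
    stop("strain(s) with no host mapping in the association table: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  missing_hosts <- setdiff(host_of[genus_tree$tip.label], host_tree$tip.label)
  if (length(missing_hosts) > 0) {
    stop("host(s) absent from the host tree: ",
         paste(missing_hosts, collapse = ", "), call. = FALSE)
  }

  ntip <- length(genus_tree$tip.label)
  clades <- list()

  qualifies <- function(tips) {
    hosts <- unname(host_of[tips])
    if (anyDuplicated(hosts)) {
      return(FALSE)
    }
    if (length(hosts) < length(host_tree$tip.label)) {
      if (!ape::is.monophyletic(host_tree, hosts)) {
        return(FALSE)
      }
    }
    sub_g <- induced_subtree(genus_tree, tips)
    sub_g$tip.label <- unname(host_of[sub_g$tip.label])
    sub_h <- induced_subtree(host_tree, hosts)
    rf_distance(sub_g, sub_h) == 0L
  }

  recurse <- function(node) {
    if (node <= ntip) {
      return(invisible(NULL))
    }
    tips <- node_tips(genus_tree, node)
    if (length(tips) >= min_size && qualifies(tips)) {
      clades[[length(clades) + 1L]] <<- list(
        genus = unname(unique(genus_of[tips])),
        strain_ids = sort(tips),
        host_ids = sort(unname(host_of[tips])),
        size = length(tips),
        trivial = length(tips) == 2L
      )
      return(invisible(NULL))
    }
    for (ch in node_children(genus_tree, node)) {
      recurse(ch)
    }
    invisible(NULL)
  }

  recurse(ntip + 1L)
  clades
}

#' Count independent symbiont acquisitions
#'
#' Minimum-acquisition arithmetic: per genus, every strain not covered by a
#' coevolving clade is one independent acquisition, and every clade collapses
#' to one. Genera detected only via amplicon screening (a single strain, no
#' genome tree) contribute one acquisition.
#'
#' @param assoc Association data frame (`strain_id`, `host_id`, `genus`).
#' @param clades List of coevolving clades as returned by
#'   [find_coevolving_clades()] (possibly concatenated over genera); may be
#'   empty.
#' @return An object of class `origin_report`: list with `per_genus` (data
#'   frame with columns `genus`, `n_strains`, `n_clades`, `n_singletons`,
#'   `origins`), `total`, `clades`, and `singletons` (named list of strain
#'   ids per genus).
#' @export
count_origins <- function(assoc, clades = list()) {
  assoc <- validate_association(assoc)

  clade_strains <- unlist(lapply(clades, `[[`, "strain_ids"))
  if (anyDuplicated(clade_strains)) {
    stop("overlapping clades: strain(s) ",
         paste(unique(clade_strains[duplicated(clade_strains)]), collapse = ", "),
         " appear in more than one clade", call. = FALSE)
  }
  unknown <- setdiff(clade_strains, assoc$strain_id)
  if (length(unknown) > 0) {
    stop("clade strain(s) missing from the association table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  genera <- sort(unique(assoc$genus))
  clade_genus <- vapply(clades, function(cl) cl$genus[1], character(1))

  singletons <- list()
  rows <- lapply(genera, function(g) {
    strains <- assoc$strain_id[assoc$genus == g]
    g_clades <- clades[clade_genus == g]
    in_clade <- unlist(lapply(g_clades, `[[`, "strain_ids"))
    single <- setdiff(strains, in_clade)
    singletons[[g]] <<- sort(single)
    data.frame(genus = g,
               n_strains = length(strains),
               n_clades = length(g_clades),
               n_singletons = length(single),
               origins = length(single) + length(g_clades),
               stringsAsFactors = FALSE)
  })
  per_genus <- do.call(rbind, rows)

  structure(list(per_genus = per_genus,
                 total = sum(per_genus$origins),
                 clades = clades,
                 singletons = singletons),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat("Independent symbiont acquisitions\n")
  print(x$per_genus, row.names = FALSE)
  cat("total:", x$total, "origins;",
      length(x$clades), "coevolving clade(s) collapsed\n")
  for (cl in x$clades) {
    cat("  clade [", cl$genus, "] ", cl$size, " strains: ",
        paste(cl$strain_ids, collapse = ", "),
        if (isTRUE(cl$trivial)) "  (2-leaf: trivially congruent)" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a strain-host association table
#'
#' Per-genus accounting of strains, host samples, and double infections
#' (host samples carrying two or more strains of the same genus).
#'
#' @param assoc Association data frame (`strain_id`, `host_id`, `genus`).
#' @return Data frame with columns `genus`, `n_strains`, `n_hosts`,
#'   `n_double_infection_hosts`.
#' @export
association_summary <- function(assoc) {
  assoc <- validate_association(assoc)
  genera <- sort(unique(assoc$genus))
  do.call(rbind, lapply(genera, function(g) {
    hosts <- assoc$host_id[assoc$genus == g]
    tab <- table(hosts)
    data.frame(genus = g,
               n_strains = length(hosts),
               n_hosts = length(tab),
               n_double_infection_hosts = sum(tab >= 2),
               stringsAsFactors = FALSE)
  }))
}

validate_association <- function(assoc) {
  if (!is.data.frame(assoc)) {
    stop("association table must be a data frame", call. = FALSE)
  }
  need <- c("strain_id", "host_id", "genus")
  miss <- setdiff(need, names(assoc))
  if (length(miss) > 0) {
    stop("association table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(assoc$strain_id)) {
    stop("strain_id values must be unique", call. = FALSE)
  }
  assoc$strain_id <- as.character(assoc$strain_id)
  assoc$host_id <- as.character(assoc$host_id)
  assoc$genus <- as.character(assoc$genus)
  assoc
}
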