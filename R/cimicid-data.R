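# Packaged cimicid data set: topologies of the host phylogeny and of the
# symbiont genus trees (cimicid strains only), plus the sample-symbiont
# association table, transcribed from a published survey of nutritional
# symbionts across 14 bed bug (Cimicidae) samples. Within-group resolutions
# that the survey's verbal descriptions leave open are encoded conservatively:
# the seven non-coevolving Wolbachia strains are arranged on a pectinate
# backbone interleaving the same-host double-infection partners, and the three
# non-Cacodmus Symbiopectobacterium strains as a polytomy. These encodings
# carry no cospeciation signal of their own, which is exactly what "clustered
# without correspondence to the host phylogeny" means operationally.

#' Path to the packaged cimicid data set
#'
#' @param file Optional file name within the data set directory.
#' @return Absolute path.
#' @export
cimicid_fixture_path <- function(file = "") {
  system.file("extdata", "cimicidae", file, package = "cimsym",
              mustWork = TRUE)
}

#' Load the packaged cimicid data set
#'
#' Loads the transcribed host tree (14 cimicid samples, 13 species, five
#' subfamilies), the cimicid-strain genus trees for \emph{Wolbachia} (14
#' strains), \emph{Symbiopectobacterium} (5) and \emph{Sodalis} (3), and the
#' association table (24 strains; \emph{Serratia} has a single sequenced
#' strain and \emph{Tisiphia} a single amplicon-only detection, so neither
#' needs a tree).
#'
#' @return List with elements `host_tree` (`phylo`), `genus_trees` (named list
#'   of `phylo`), `associations` (data frame), `samples` (data frame with host
#'   species and subfamily).
#' @export
#' @examples
#' cim <- load_cimicid_data()
#' association_summary(cim$associations)
load_cimicid_data <- function() {
  list(
    host_tree = read_newick(cimicid_fixture_path("host_tree.nwk")),
    genus_trees = list(
      Wolbachia = read_newick(cimicid_fixture_path("wolbachia_tree.nwk")),
      Symbiopectobacterium =
        read_newick(cimicid_fixture_path("symbiopectobacterium_tree.nwk")),
      Sodalis = read_newick(cimicid_fixture_path("sodalis_tree.nwk"))
    ),
    associations = read_association(cimicid_fixture_path("associations.tsv")),
    samples = utils::read.delim(cimicid_fixture_path("samples.tsv"),
                                stringsAsFactors = FALSE)
  )
}

#' Acquisition counting on the packaged cimicid data set
#'
#' Runs [find_coevolving_clades()] on each genus tree of the packaged data
#' set and feeds the collapsed clades to [count_origins()].
#'
#' @param min_size Minimum clade size passed to [find_coevolving_clades()].
#' @return An `origin_report`.
#' @export
cimicid_origin_report <- function(min_size = 2) {
  cim <- load_cimicid_data()
  clades <- list()
  for (g in names(cim$genus_trees)) {
    assoc_g <- cim$associations[cim$associations$genus == g, ]
    clades <- c(clades,
                find_coevolving_clades(cim$genus_trees[[g]], cim$host_tree,
                                       assoc_g, min_size = min_size))
  }
  count_origins(cim$associations, clades)
}
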