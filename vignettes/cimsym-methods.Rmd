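---
title: "Methods: symbiont screening, deconvolution, pathway scoring and acquisition counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbiont screening, deconvolution, pathway scoring and acquisition counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimsym)
```

This vignette is the package's own account of its methods: what each stage
computes, which rules were genuinely open and how they were decided, what
the synthetic-data generator does and does not emulate, and what the test
suite does and does not establish.

## The system

Obligate blood feeders such as bed bugs (Cimicidae) rely on bacterial
endosymbionts for B vitamins. A family-wide survey of these symbioses
produces four kinds of evidence: a 16S amplicon OTU table (which taxa are
where), metagenome assemblies (draft symbiont genomes, sometimes two
co-resident strains of one genus in a single host — a *double infection*),
gene-level annotations (is each biosynthesis pathway still functional?),
and host plus symbiont phylogenies (how often was each symbiont acquired
independently?). `cimsym` implements the computational steps connecting
these, each behind a small, separately testable function.

## Amplicon screening

The screening stage treats amplicon data purely as a presence/dominance
overview, so it is deliberately aggressive. Fixed order:
`taxonomic_filter()` → `abundance_floor()` → `rarefy()`.

* **Taxonomic filter.** An OTU is removed when any rank of its
  semicolon-delimited lineage equals (case-insensitively, tolerating
  `d__`-style prefixes) Archaea, Eukaryota, Mitochondria or Chloroplast.
  Matching whole rank tokens rather than substrings avoids false hits such
  as lineages containing "Archaeplastida".
* **Abundance floor.** Within each sample independently, an OTU below
  1 % of the sample's reads is set to zero. The comparison is strict
  (`count/total < threshold`): a cell at exactly 1 % survives. Presence in
  other samples is deliberately ignored — symbiont OTUs are expected to be
  dominant, and cross-sample rescue would re-admit low-level carry-over.
  The sample totals used are those *after* the taxonomic filter: the floor
  is meant to act on the bacterial community, not on host organelle reads,
  so a sample swamped by chloroplast reads does not spuriously zero its
  true symbiont. The operation is idempotent; both properties are tested.
* **Rarefaction.** Classic subsampling without replacement to 1,000 reads
  per sample (via `vegan::rrarefy`, behind the `rarefy()` surface), seeded
  for reproducibility; samples below the target depth are excluded and
  listed in the report. The per-cell expectation is hypergeometric, which
  the test suite verifies to within 1 % over 10,000 seeds.
* **Dominant OTUs.** Ranking is by total count over samples; ties break
  lexicographically by OTU id so output never depends on storage order.
  The default of 13 reported OTUs matches the usual size of a screening
  overview figure.

## Contig binning by majority vote

Each annotated gene on a candidate contig contributes one vote — its single
best reference hit. `classify_contig()` tallies bacterial votes per genus
and takes the strict plurality. Three decisions were open and are resolved
conservatively:

* *Predominant eukaryotic hits* exclude the contig; "predominant" is
  operationalized as eukaryotic hits strictly exceeding the best bacterial
  tally.
* An exact tie for the best bacterial genus gives `UNCLASSIFIED` rather
  than an arbitrary winner.
* Archaeal and viral hits vote for neither side.

Votes are counted once per annotated gene (its best hit), not per local
alignment. A brute-force tally oracle re-derives every verdict on 1,000
random hit multisets in the test suite. `genome_summary()` computes bin
statistics with GC over non-N bases and coding density as the union of
CDS intervals (1-based inclusive, GFF convention), so overlapping CDS are
counted once.

## Strain deconvolution

Two strains of one genus in one host leave two signatures: an excess of
duplicated orthogroups, and bimodal contig coverage.

* `detect_double_infection()` computes the duplicated fraction
  d = |{OG: copies ≥ 2}| / |{OG: copies ≥ 1}| and flags d ≥ 0.2. "Excess"
  has no canonical definition, so the threshold is exposed; d is monotone
  in added duplications.
* `split_by_coverage()` works on log2 coverage, where a log-normal
  coverage model becomes Gaussian. The threshold maximizes between-class
  variance (Otsu's criterion in one dimension, exhaustive over the n − 1
  cut points of the sorted values; the first maximum wins, making ties
  deterministic). Two guards:
  * **Bimodality**: if the resulting class means differ by less than
    log2(1.5) the bin is treated as unimodal and the function *refuses* —
    a distinct, non-error result — because Otsu always returns some
    threshold, even on unimodal data.
  * **Intermediate band**: contigs within 0.2 · (μ_high − μ_low) of the
    threshold are excluded rather than guessed. The band scales with the
    mode separation, so it adapts to how distinguishable the strains are.
  The split is invariant to contig order and equivariant under rescaling
  all coverages (both tested). Contigs are assigned atomically; no attempt
  is made to split chimeric contigs, matching the premise that the two
  genomes cannot be fully separated at assembly level.
* `composite_genome()` pools the genes of co-resident same-genus strains,
  duplicates retained, for metabolic analysis: pathway questions are asked
  of the host's symbiont complement of that genus, not of strains the
  assembly cannot cleanly separate.

## B-vitamin pathway scoring

The gene matrix records per genome, gene and copy one of INTACT,
DISRUPTED (pseudogenized, e.g. a premature stop), ABSENT. Rules:

* **Copy collapse** (`gene_status`): INTACT if any copy is intact — this is
  copy-level complementation, as in a duplicated biotin operon whose two
  copies carry disruptions in different genes. DISRUPTED never satisfies a
  step but is reported distinctly from ABSENT.
* **Steps** are sets of interchangeable gene symbols; one intact member
  satisfies the step. Genes unlisted in the matrix are ABSENT.
* **Excusals** are assessed per missing step: `ALT_ENZYME` when the step
  definition carries the alternative-enzymes flag (shipped defaults flag
  only the riboflavin dephosphorylation step — the conservative reading;
  definitions are editable data, `inst/extdata/pathways.json`);
  `COHORT_ABSENT` when the step is unsatisfied in a strict majority
  (> 50 %, configurable) of the analyzed cohort *and* the pathway is
  otherwise intact. "Otherwise intact" means every step outside the
  cohort-absence profile is satisfied **and at least one step is
  satisfied**: without the second clause, a genome lacking an entire
  pathway that the whole cohort also lacks would have every gap excused
  vacuously, and a wholly missing pathway is plainly not "otherwise
  intact". This boundary behaviour (total loss ⇒ NONFUNCTIONAL) is pinned
  by tests.
* **Calls**: FUNCTIONAL iff no step is missing; PUTATIVELY_FUNCTIONAL iff
  every missing step is excused; otherwise NONFUNCTIONAL.
* **Cohort and composites** (`vitamin_matrix`): double infections are
  merged into composite entries *before* the cohort-absence profile is
  computed, so a double-infected host counts once in the cohort, and the
  profile then applies to every call. Results are independent of row and
  iteration order (tested).
* **Cross-symbiont complementation** (`complementation_call`): the
  host-level call scores the per-step union of satisfaction across
  co-resident symbionts; it can be FUNCTIONAL although every resident
  alone is NONFUNCTIONAL, and is never worse than the best resident.

One caveat on monotonicity: upgrading a copy status never downgrades any
call *at a fixed cohort-absence profile* (tested). Across a profile
recomputation the guarantee cannot hold in general — repairing a gene in
enough genomes removes the step from the profile and with it the excusal
other genomes relied on. That is a property of the cohort rule itself, not
of this implementation.

A deliberately naive straight-line scorer (`reference_pathway_call`,
explicit loops, no shared helpers) provides ground truth for simulated
matrices and an independent oracle in tests (200 random matrices in the
acceptance suite).

## Acquisition counting

Inputs are topologies only: a rooted host tree, one rooted tree per
symbiont genus (leaves = strains), and the strain→host association table.
Branch lengths and support values are ignored throughout.

A clade of strains is collapsed into a single acquisition
(`find_coevolving_clades`) when:

1. all its hosts are distinct — a clade containing both strains of a
   double infection can never be one acquisition;
2. its hosts form a **monophyletic group** on the host tree;
3. the clade relabeled strain→host has unrooted Robinson–Foulds distance 0
   to the induced host subtree.

Condition 2 deserves justification, since one might think condition 3
suffices. Unrooted topologies on two or three leaves are all identical, so
RF alone certifies *any* small clade on distinct hosts, however scattered
those hosts are across the family — under RF alone, three strains on three
mutually distant hosts would count as one coevolving acquisition. The
biological signature of cospeciation is a symbiont lineage tracking *a
group of closely related hosts*; host-side monophyly is the topological
statement of exactly that, and with it a pair of strains on sister hosts
qualifies (flagged `trivial`, since two-leaf congruence carries no
topological information of its own) while a pair on distant hosts does
not. For clades of four or more, condition 3 adds real discriminatory
power: the tests verify that swapping the hosts of two non-sister strains
breaks congruence, and that random host permutations of a seven-strain
congruent clade break it in the overwhelming majority of cases.

The search is greedy from the genus-tree root, accepting the largest
qualifying clade first and not descending into it — this guarantees the
returned clades are maximal and disjoint. Per genus, the acquisition count
is (strains outside any clade) + (number of clades); genera known from a
single strain (or amplicon detection only) count one.

RF distance itself is a standard primitive and is delegated to
`phangorn::RF.dist` behind `rf_distance()`; a hand-written bipartition
symmetric-difference oracle checks it on 500 random eight-leaf tree pairs.

## The packaged cimicid data set

`inst/extdata/cimicidae/` transcribes a survey of 14 cimicid samples
(13 species, five subfamilies): the host topology, the cimicid-strain
subtrees of the *Wolbachia* (14 strains), *Symbiopectobacterium* (5) and
*Sodalis* (3) trees, and the 24-row association table (*Serratia* and
*Tisiphia* are single detections and need no tree). Structural features —
Cimicinae monophyly with *Paracimex* inside *Cimex*, the
Cacodminae/Haematosiphoninae paraphyly, the basal Primicimicinae, the
supergroup-F *Wolbachia* clade mirroring Cimicinae, the *Cacodmus*
*Symbiopectobacterium* sister pair, the Haematosiphoninae *Sodalis* pair
with the *Primicimex* strain placed separately — follow the survey's
verbal descriptions. Resolutions those descriptions leave open are encoded
conservatively so they carry no cospeciation signal of their own: the
seven non-coevolving *Wolbachia* strains sit on a pectinate backbone with
the same-host double-infection partners interleaved, and the three
non-*Cacodmus* *Symbiopectobacterium* strains form a polytomy. On this
data set the pipeline reports 16 acquisitions (8 *Wolbachia*, 4
*Symbiopectobacterium*, 2 *Sodalis*, 1 *Serratia*, 1 *Tisiphia*) with
three collapsed clades; `scripts/acceptance.R` recomputes this from
scratch. The two-strain *Sodalis* clade is reported with the `trivial`
flag: on two leaves, host-sisterhood is the entire evidence, and
cospeciation versus two independent acquisitions cannot be distinguished
topologically.

## The synthetic-data generator

`sim_config()` fixes the study conditions; defaults describe a
cimicid-scale survey: 14 hosts, five candidate genera, double-infection
coverage modes at log2 means 6 and 2 (a 16-fold ratio) with sd 0.3 log2
units, 2 % hit misassignment, 5 % eukaryotic contamination, amplicon
depths of 1,000–20,000 reads with symbionts taking 70 % of a sample in
expectation.

* **Host trees**: random sequential leaf attachment (Yule-like); branch
  lengths are irrelevant to every downstream analysis and are omitted.
* **Acquisitions** (`simulate_symbiosis`): each origin either stays a
  singleton or expands into a coevolving clade built as an exact relabeled
  copy of an induced host subtree — congruent by construction. Genus trees
  assemble the origins on a pectinate backbone. Because chance can still
  produce additional host-congruent groupings (e.g. two singleton origins
  landing on sister hosts and ending up adjacent), the generator checks
  every clade of the built trees with a flat scan and redraws on
  collision; the simulated origin count is therefore exactly recoverable,
  which the acceptance suite verifies on 100 random scenarios.
* **Coverage**: log-normal per contig around the strain mean; the model is
  a choice (coverage is positive and right-skewed), not an estimated fit.
* **Gene matrices**: per-gene absence, per-copy disruption, occasional
  duplication; ground truth comes from the straight-line reference scorer,
  never from the production scorer.
* **OTU tables**: multinomial per sample with a fixed background panel that
  includes chloroplast, mitochondrial, eukaryotic and archaeal labels, so
  the taxonomic filter is exercised.

What the generator does **not** emulate: read-level error, assembly
artefacts (chimeras, fragmented genes), incomplete genome drafts,
intragenomic 16S variation, compositional amplicon biases, and host trees
with meaningful branch lengths. Green tests therefore establish the
correctness of the *rules* on data satisfying the stated statistical
structure, not robustness to assembly or annotation failure modes.

## Problem sizes and tolerances in the test suite

The suite runs the oracle comparisons at 1,000 random hit multisets, 500
random eight-leaf tree pairs and 200 random gene matrices; parameter
recovery at 100 random acquisition scenarios and 100 coverage-split seeds
(40 + 40 contigs each, at the default coverage conditions); and the
rarefaction expectation at 10,000 seeds with a 1 % tolerance — sizes
chosen to keep the full suite around a minute on one CPU while leaving
each stochastic check ample resolution.

## Known limitations

* Congruence is binary (RF = 0); near-congruent clades with one misplaced
  strain decompose into smaller clades and singletons rather than being
  scored as "almost cospeciating". Event-based cophylogenetic
  reconciliation (duplications, losses, host switches) is out of scope.
* The greedy top-down clade search returns maximal disjoint clades; it
  does not enumerate alternative decompositions of equal size.
* Pathway definitions are curated approximations of KEGG modules
  (cobalamin especially); they are configuration, and conclusions about a
  specific pathway should be read against the definition used.
* The coverage split assumes exactly two strains; three-way infections
  would need a multi-class extension.
* Genome summaries (size, GC, CDS, coding density) describe the binned
  draft, not the true genome; completeness assessment is out of scope.
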