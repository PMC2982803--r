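---
title: "Community phylogenetics from 16S amplicon reads: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phylogenetics from 16S amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the method

`phylosym` tests a phylosymbiosis hypothesis: that the composition of
host-associated (gut) microbial communities tracks the phylogeny of the host
species, so that a tree built from community composition alone reproduces the
host tree. The analysis treats each microbial species — operationalised as a
99.5%-identity OTU of 16S amplicon reads detected in at least two host
samples — as a single phylogenetic character. The normalized frequency of
that OTU in each host sample is coded into one of six **ordered** states
reflecting log-unit (order-of-magnitude) abundance differences, with absence
as state 0. The samples-by-OTUs matrix is then analysed by ordered (Wagner)
maximum parsimony: transitions between distant abundance states cost
proportionally more (`cost(i, j) = |i - j|`), exactly as morphometric
characters are treated in classical cladistics. Congruence between the
resulting community tree and the host tree, and the apportionment of change
between species-discriminating internal branches and individual terminal
branches, are the scientific readouts.

All stages live in this package as plain functions: read simulation
(`simulate_dataset()`), quality control (`process_reads()`), OTU clustering
(`cluster_otus()`), character coding (`build_character_matrix()`), parsimony
inference (`heuristic_search()`, `bootstrap_parsimony()`) and comparative
metrics (`rf_distance()`, `congruence_probability()`,
`branch_apportionment()`, `internal_branch_correlation()`,
`replicate_overlap()`). The numbered scripts under `analysis/` run them as a
narrative workflow and write their tables under `results/`.

# The synthetic-data generator

Raw reads from wild-host studies of this design are not bundled with the
package, so every stage is exercised on synthetic data whose statistical
structure matches what the analysis assumes. The generator is first-class,
tested code, not a fixture.

**Host design.** The default `host_spec()` mirrors a five-species,
two-individuals-per-species great-ape-like design (10 samples): one outgroup
species (human-like), a sister pair (chimpanzee/bonobo-like) and a second
sister pair (two gorilla-like species), on an unrooted species tree with
branch lengths in arbitrary time units. `simulate_host_tree()` expands each
species tip into a clade of individuals and converts lengths into expected
log10-divergence units by multiplying by `divergence_scale` (epsilon floor
`1e-8` so lengths stay positive). The emitted tree is the *planted truth*
against which recovery is measured.

**Community model.** Log10 relative abundances of `n_otus` lineages evolve by
Brownian motion along the species-level branches: the variance accumulated
over a branch equals (time-unit length) x `divergence_scale`^2, i.e. emitted
length x scale. Presence/absence toggles as a Poisson process (`turnover` per
unit branch length), modelling lineage gain/loss. Individuals receive only
i.i.d. Gaussian noise (`indiv_sigma`, log10 units) on top of their species'
value — Brownian motion is deliberately switched off on within-species
branches so that with `indiv_sigma = 0` and `turnover = 0` conspecifics have
identical profiles, making the within/between-species variance decomposition
fully controllable. Frequencies below a detection floor (`1e-5`) are set to
absent and profiles renormalized. No claim is made that real gut communities
diverge by Brownian motion; the model exists to give the pipeline a planted
signal whose strength is a dial, and nothing downstream depends on its
biological realism.

**Defaults as study conditions.** The strong-signal defaults — 5 species x 2
individuals, 200 OTUs, 5,000 reads/sample, `divergence_scale = 1.5`,
`indiv_sigma = 0.15`, `turnover = 0.05` — were fixed once, before any
downstream result was inspected, to represent a regime where between-species
divergence clearly dominates individual noise (roughly 1.5 log-units of
expected between-species drift against 0.15 log-units of individual scatter).
The zero-divergence control uses the same machinery with
`divergence_scale = 0`, at a reduced size (10 samples, 100 OTUs, 500
reads/sample, 100 bootstrap replicates) chosen so that twenty replicate
control runs remain a routine desktop computation; the control's claim (no
spuriously supported species clade) does not depend on depth.

**References and reads.** `synthesize_references()` builds a labelled
reference taxonomy (default 8 bacterial phyla, one class each, plus a
designated chloroplast class in Cyanobacteria) by substitution-only mutation
of per-class ancestors (20% root-to-ancestor, 3% ancestor-to-taxon), so
within-class identity always exceeds between-class identity and all
references share one coordinate system. References default to 400 nt — long
enough to hold every read window with margin, short enough to keep
semi-global alignment cheap. `generate_reads()` emits
`barcode + primer + payload` reads: the payload is a window of the source
reference (length ~ N(220, 12²), start drawn inside the accepted window),
with per-base substitutions (0.002), insertions and deletions (5e-4 each)
applied, and Phred+33 qualities encoding the configured error probabilities.
A configurable fraction of reads carries a degraded 3' tail (error 0.02 over
the last 20 bases) to exercise quality trimming.

**Planted violations.** Per sample, exact counts (fractions rounded once) of
reads are planted to violate each downstream filter: corrupted
barcode/primer prefixes (die at demultiplexing), short reads (100-149 nt,
substitution errors only so an indel can never push one across the 150-nt
boundary), wrong-region reads (start in a window far outside the accepted
one) and chloroplast contaminants. Legitimate reads start two columns inside
the accepted window so a terminal indel — even compounded by local
reference-vs-representative divergence — cannot shift them out; with
pairwise-Hamming-≥2 barcodes, a single corrupted base can never convert one
barcode into another. These conventions make the planted per-rule counts
exactly recoverable — the fidelity the tests assert. Low-confidence
classification (filter rule ii) is an emergent property of the classifier
and cannot be planted by construction; the default regime is chosen so that
all legitimate reads pass it, and the rule's boundary and precedence are
tested with constructed assignment tables instead.

**Technical replicate.** One sample (default: the first) is resequenced with
fresh error draws from the same true profile at 3.5x depth, mirroring a
deep technical-replicate design, and is excluded from the phylogenetic
analysis; it exists to measure how many reads of the original sample lack a
(near-)identical partner in a deeper resequencing run.

# Quality control

* **Trimming** (`trim_low_quality_ends()`): the longest contiguous window
  whose terminal bases have error probability <= 0.5% and whose mean error
  probability is <= 0.5% (an accuracy-threshold end trim). Ties go to the
  earliest start.
* **Demultiplexing** (`demultiplex()`): exact `barcode + primer` prefix match
  only; the prefix is stripped. Prefix-free barcode sets are enforced.
* **Classification** (`classify_reads()`): a word-frequency naive-Bayes
  classifier over 8-mer presence features with add-half smoothing,
  `P(w|class) = (n_refs_with_w + 0.5) / (n_refs + 1)`; confidence is the
  percentage of 100 bootstrap subsamples (each `floor(W/8)` of the read's
  `W` 8-mers, drawn with replacement) agreeing with the full-read
  assignment. Subsample score ties are broken at random (under the seed):
  a subsample containing no discriminating word splits its vote, so reads
  carrying no class signal concentrate near chance-level confidence instead
  of inheriting the full-read winner.
* **Start location** (`locate_starts()`): semi-global alignment (global in
  the read, local in the reference; match 1, mismatch -1, gap open 2, gap
  extend 1) of each read to its class representative — the lexicographically
  first reference of the class; the reported start is the subject column of
  the read's first base. Alignments scoring under 0.4 x read length give an
  unknown position.
* **Filtering** (`filter_reads()`): keep iff length >= 150 **and** confidence
  strictly > 70% **and** start inside the domain's inclusive window **and**
  class is not chloroplast. Removals are tallied under the first violated
  rule, in that order, so QC reports are reproducible. The length check runs
  after barcode/primer stripping (recorded in the QC report). The default
  windows (844-850 for Archaea, 851-857 for Bacteria) are the classical 16S
  reference-alignment coordinates; the pipeline passes the synthetic
  alignment's own window instead, since coordinates are only meaningful
  relative to whichever reference alignment is in use.

# OTU clustering

Reads are dereplicated with the trim-to-shorter rule: reads identical after
truncating the longer to the shorter's length merge into one unique type
whose canonical sequence is the longest member. (Prefix-chains are resolved
by merging each sequence into its lexicographic successor when it is a
prefix of it, applied transitively — deterministic, and exact for the common
case of same-template reads of different lengths.) Types are aligned to
their class representative and pairwise identities computed with terminal
gaps excluded: columns inside either row's terminal-gap run are not
compared, a column where exactly one row has an internal gap counts as one
difference, and columns where both rows are gapped are not compared (the
rule the 99.5% threshold was designed around: at 200 comparable columns one
mismatch or one-column indel is exactly 0.5% divergence, and the boundary is
inclusive). Cross-class pairs are never compared.

The >= 99.5% similarity graph (edge weight = identity, self-loops at 100)
is clustered with Markov clustering at inflation 1.5: the column-stochastic
flow matrix is alternately expanded (matrix square) and inflated
(elementwise power 1.5, column renormalization, pruning at 1e-12) until the
largest entry change drops below 1e-6 or 100 iterations pass — components
are processed independently (MCL can never merge components), densely when
small and sparsely above 64 nodes, which matters because abundant OTUs
accumulate hundreds of one-error satellite types. Clusters are the connected
components of the limit matrix's nonzero pattern; a node attracted to
several clusters joins the one holding most of its column mass (ties to the
smallest node id). Edge weights are identities (not binary) by default;
convergence tolerance and weighting are configuration.

One OTU per cluster: per-sample counts are summed type multiplicities, the
representative is the longest member read (ties broken lexicographically),
and OTUs present in >= 2 samples are *shared* — only those carry
phylogenetic information and enter the character matrix.

# Character coding

Frequencies are per-sample normalized counts: shared-OTU reads at species
rank, all classifiable filtered reads at phylum rank (both denominators
recorded). `code_states()` maps frequency f to state 0 iff f = 0, and
otherwise through descending log10 edges `1e-1, 1e-2, 1e-3, 1e-4`: state 5
for f >= 0.1 down to state 1 for f < 1e-4, with every boundary belonging to
the higher state (so state 5 is reachable at exactly the top edge). The
anchor is configuration: six states spanning four decades cover the range
that deep amplicon samples actually occupy (from detection-floor rarities to
dominant lineages at tens of percent), and raw-count binning can be had by
normalizing with a constant depth. Constant characters are retained — they
add zero parsimony length. Matrices are written as TSV, relaxed PHYLIP and
NEXUS with an ordered-characters (`DEFTYPE=ORD`) assumptions block.

# The parsimony engine

`sankoff_score()` computes, per character, the minimum total transition cost
over all internal-state assignments by Sankoff dynamic programming, rooting
the unrooted tree at an arbitrary internal node (the score is
rooting-invariant; this is asserted by tests). The inner loop is C++.

`exhaustive_search()` enumerates all `(2n-5)!!` unrooted binary topologies by
sequential leaf insertion (refusing above 9 taxa) and returns *every* optimum
— it is the oracle against which the heuristic is validated, and the
machinery behind exact topology counting. `heuristic_search()` uses
random-addition stepwise insertion followed by steepest-descent hill
climbing under NNI or SPR until no rearrangement improves the score,
collecting all distinct best topologies across starts. Defaults (10
random-addition starts, SPR) are this package's stand-in for a conventional
"default settings" heuristic search; they attain the exhaustive optimum on
at least 95 of 100 random 7-taxon matrices in the acceptance suite.

`bootstrap_parsimony()` resamples characters with replacement to the
original count, reruns the search per pseudo-replicate (2 starts by
default), and tallies bipartitions of one best tree per replicate — ties are
resolved by a draw from the replicate's own RNG stream, so uninformative
matrices yield scattered, unsupported bipartitions rather than a spuriously
"supported" arbitrary tree. Support is the percentage of replicates
containing a bipartition; the majority-rule consensus carries supports as
node labels. The production default is 1,000 replicates; the bundled
analysis uses 200, which bounds the Monte-Carlo standard error of a support
value by about 3.5 percentage points while keeping the whole workflow inside
a desktop time budget.

`assign_branch_lengths()` backtracks one minimal-cost state assignment
(root state = lowest-index minimiser; each child takes the lowest-index
state minimising transition + subtree cost) and sums the implied changes per
branch; the lengths are integers summing exactly to the p-score, which the
tests assert as a conservation law.

# Tree comparison and combinatorics

Bipartition keys (the leaf set on the side away from a fixed reference
leaf) drive `rf_distance()`, bootstrap tallies and congruence testing.
`is_congruent()` requires each constrained group, and each sister-pair
union, to be separated by some bipartition — monophyly in the unrooted
sense. `count_topologies()` is the double factorial `(2n-5)!!`;
`congruence_probability()` counts constraint-satisfying topologies exactly
by collapsing each group to a supertaxon (multiplying by the `(2k-3)!!`
rooted arrangements inside each group, and by one for each sister join) —
an explicit-enumeration path cross-checks the collapse on small trees. For
the five-conspecific-pairs-plus-two-sisterhoods constraint set on ten
leaves the numerator is 1 against 2,027,025 topologies.

`branch_apportionment()` reports the fraction of total tree length on
terminal (leaf-adjacent) branches and on *species-discriminating* internal
branches — internal branches whose bipartition splits the samples into whole
species groups (the seven such branches of the ten-sample design). The two
fractions need not sum to one. Computation is on the unrooted tree; no
root-side path is singled out. `internal_branch_correlation()` matches
internal branches of two topologically identical trees by bipartition,
normalizes each tree's internal lengths to sum 1 (relative lengths; a
raw-length mode exists behind a flag), and returns Pearson r and r²; fewer
than three internal branches or zero variance is refused/flagged rather
than silently reported.

`replicate_overlap()` measures, for a sample and its deeper technical
replicate, the fraction of original-sample reads with no counterpart in the
replicate at a given divergence allowance, under exactly the OTU-clustering
identity rules; several allowances share one classification/alignment pass.

# Numerical choices, degenerate inputs, known limitations

* Ordered costs `|i - j|` satisfy symmetry, zero diagonal and the triangle
  inequality (validated); unit-cost (Fitch) scoring is available and can
  never exceed the ordered score.
* Ties everywhere are broken deterministically (lowest state index in the
  backtrace, lexicographic representative, smallest node id in MCL), and
  every stochastic stage takes an explicit seed and restores the caller's
  RNG state.
* Degenerate inputs: empty trimmed reads are legal and die at the length
  filter; types with no alignable region are flagged and excluded from the
  graph; alignment-row pairs with no comparable columns get no edge; samples
  with zero reads make normalization fail loudly; trees below four leaves
  are refused where an unrooted binary tree is required.
* The generator's error model is uniform per base (no homopolymer-specific
  pyrosequencing model, no chimeras) and applies errors to the payload only;
  passing tests therefore certify the pipeline's logic under its stated
  assumptions, not robustness to every real-world artifact.
* Problem sizes in the bundled analysis (5,000 reads/sample, 200 bootstrap
  replicates, 20 zero-divergence control runs at 500 reads/sample) are the
  package's own choices for a reproducible desktop run; all are parameters.
* The identity rule weighs a multi-column gap as one difference per column;
  with 454-style data most indel artifacts are single-column, so the choice
  is immaterial at the 99.5% threshold but is recorded here because other
  conventions exist.
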