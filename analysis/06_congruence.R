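#!/usr/bin/env Rscript

# Stage 6 — congruence of the microbiota tree with the host phylogeny.
#
# Tests topological congruence (conspecific pairs, gorilla and Pan
# sisterhoods), computes the exact probability of congruence by chance,
# apportions branch lengths between species-discriminating internal branches
# and terminal branches in both trees, correlates relative internal branch
# lengths, and measures the technical-replicate overlap at exact and 0.5%
# divergence matching.

suppressPackageStartupMessages(library(phylosym))

ds <- read_dataset("results/data")
micro <- read_newick("results/trees/microbiota_tree.nwk")
host <- ds$tree
smap <- attr(host, "species_map")
if (is.null(smap)) {
  smap <- setNames(sub("_[0-9]+$", "", host$tip.label), host$tip.label)
}

cc <- great_ape_constraints(smap)
rf <- rf_distance(micro, host)
congruent <- is_congruent(micro, cc)
pr <- congruence_probability(length(host$tip.label), cc)

# parsimony branch lengths for the host tree as well, so both trees carry
# lengths on the same scale when apportioning; the host tree already has
# divergence-scaled lengths from the generator
ap_host <- branch_apportionment(host, smap)
ap_micro <- branch_apportionment(micro, smap)
corr <- if (rf == 0L) internal_branch_correlation(host, micro) else
  list(r = NA, r_squared = NA)

kept <- read.delim("results/qc/filtered_reads.tsv")
rp <- ds$ground_truth$replicate_pair
A <- kept[kept$sample_id == rp[["original"]], ]
B <- kept[kept$sample_id == rp[["replicate"]], ]
fr <- replicate_overlap(A, B, ds$references, max_divergence = c(0, 0.5))
f_exact <- fr[["0%"]]
f_half <- fr[["0.5%"]]

metrics <- list(
  rf_distance = rf,
  congruent_with_host_tree = congruent,
  congruence_probability = pr$probability,
  congruent_topologies = pr$numerator,
  total_topologies = pr$denominator,
  host_internal_fraction = ap_host$internal_fraction,
  host_terminal_fraction = ap_host$terminal_fraction,
  microbiota_internal_fraction = ap_micro$internal_fraction,
  microbiota_terminal_fraction = ap_micro$terminal_fraction,
  internal_branch_r = corr$r,
  internal_branch_r_squared = corr$r_squared,
  replicate_unmatched_exact = f_exact,
  replicate_unmatched_half_percent = f_half)

dir.create("results/metrics", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(metrics, "results/metrics/congruence.json",
                     auto_unbox = TRUE, digits = NA)

cat("RF distance to the host tree:      ", rf, "\n")
cat("congruent (species + sisterhoods): ", congruent, "\n")
cat(sprintf("chance congruence probability:      %d/%d = %.3g\n",
            pr$numerator, pr$denominator, pr$probability))
cat(sprintf("host tree:       %.0f%% species-discriminating / %.0f%% terminal\n",
            100 * ap_host$internal_fraction, 100 * ap_host$terminal_fraction))
cat(sprintf("microbiota tree: %.0f%% species-discriminating / %.0f%% terminal\n",
            100 * ap_micro$internal_fraction,
            100 * ap_micro$terminal_fraction))
cat(sprintf("internal-branch correlation: r = %.3f (r^2 = %.3f)\n",
            corr$r, corr$r_squared))
cat(sprintf("replicate overlap: %.1f%% unmatched exact, %.1f%% at 0.5%%\n",
            100 * f_exact, 100 * f_half))
cat("metrics written to results/metrics/congruence.json\n")
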