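#' Simulate a complete amplicon dataset
#'
#' Bundles the generator stages: planted host tree, community profiles evolved
#' along it, a reference taxonomy, and barcoded error-bearing reads with
#' ground truth. The defaults give the strong-signal study design: 5 host
#' species x 2 individuals (10 samples), 200 planted OTUs, 5,000 reads per
#' sample, plus a 3.5x technical replicate of the first sample.
#'
#' @param spec a [host_spec()].
#' @param n_otus number of true OTUs.
#' @param depth_per_sample reads per sample.
#' @param seed integer seed driving every stage.
#' @param n_phyla,seq_length,divergence reference-taxonomy settings
#'   ([synthesize_references()]).
#' @param ... further arguments passed to [generate_reads()].
#' @return list with `tree`, `profiles`, `references`, `reads`, `manifest`,
#'   `ground_truth`.
#' @export
simulate_dataset <- function(spec = host_spec(), n_otus = 200L,
                             depth_per_sample = 5000L, seed = 1L,
                             n_phyla = 8L, seq_length = 400L,
                             divergence = 0.2, ...) {
  tree <- simulate_host_tree(spec, seed = seed)
  profiles <- evolve_profiles(tree, n_otus, spec, seed = seed + 1L)
  references <- synthesize_references(n_otus, n_phyla = n_phyla,
                                      seq_length = seq_length,
                                      divergence = divergence,
                                      seed = seed + 2L)
  gen <- generate_reads(profiles, references,
                        depth_per_sample = depth_per_sample,
                        seed = seed + 3L, ...)
  list(tree = tree, profiles = profiles, references = references,
       reads = gen$reads, manifest = gen$manifest,
       ground_truth = gen$ground_truth)
}

#' Quality-control stage: trim, demultiplex, classify, locate, filter
#'
#' @param dataset a [simulate_dataset()] result (or a list with `reads`,
#'   `manifest`, `references` and window metadata).
#' @param min_length,min_confidence filter settings ([filter_reads()]).
#' @param accept_window accepted start window on the synthetic class
#'   alignment (defaults to the generator's window from the ground truth).
#' @param k,n_bootstrap classifier settings.
#' @param seed seed for the classifier bootstrap.
#' @return list with `kept`, `assignments` (kept reads), `counts` (per-rule
#'   removals), `n_demux_removed`, `qc`.
#' @export
process_reads <- function(dataset, min_length = 150L, min_confidence = 70,
                          accept_window = NULL, k = 8L, n_bootstrap = 100L,
                          seed = 1L) {
  if (is.null(accept_window)) {
    accept_window <- dataset$ground_truth$accept_window
  }
  primer <- dataset$ground_truth$primer
  barcode_map <- dataset$ground_truth$barcode_map
  trimmed <- trim_low_quality_ends(dataset$reads)
  demux <- demultiplex(trimmed, barcode_map, primer)
  asn <- classify_reads(demux, dataset$references, k = k,
                        n_bootstrap = n_bootstrap, seed = seed)
  asn <- locate_starts(demux, asn, dataset$references)
  res <- filter_reads(demux, asn, min_length = min_length,
                      min_confidence = min_confidence,
                      bacteria_window = accept_window)
  kept <- res$kept
  ka <- res$kept_assignments
  kept$class <- ka$class
  list(kept = kept, assignments = ka, counts = res$counts,
       n_demux_removed = attr(demux, "n_removed"),
       qc = c(res$qc, list(n_raw = nrow(dataset$reads),
                           n_demultiplexed = nrow(demux))))
}

#' OTU-clustering stage: dereplicate, align, graph, MCL, partition
#'
#' Runs class by class: unique types are aligned to the class representative,
#' pairwise identities (terminal gaps excluded) feed a >= `threshold`
#' similarity graph, MCL at the given inflation yields clusters, and clusters
#' become OTUs with per-sample counts.
#'
#' @param reads filtered reads (with `sample_id`, `class`).
#' @param references reference taxonomy (class representatives).
#' @param threshold percent identity threshold (default 99.5).
#' @param inflation MCL inflation (default 1.5).
#' @return an `otu_set` over all classes.
#' @export
cluster_otus <- function(reads, references, threshold = 99.5,
                         inflation = 1.5) {
  reps <- class_representatives(references)
  phylum_of <- setNames(references$phylum[!duplicated(references$class)],
                        references$class[!duplicated(references$class)])
  samples <- sort(unique(reads$sample_id))
  all_otus <- list()
  for (cl in sort(unique(reads$class))) {
    sub <- reads[reads$class == cl, , drop = FALSE]
    types <- dereplicate(sub)
    al <- align_class(types, reps[[cl]])
    pairs <- similar_pairs(al, threshold)
    g <- build_similarity_graph(pairs, n_nodes = length(types$sequence),
                                multiplicities = rowSums(types$counts),
                                threshold = threshold)
    cl_res <- mcl_cluster(g, inflation = inflation)
    otus <- make_otus(cl_res$clusters, types)
    otus$info$phylum <- unname(phylum_of[otus$info$class])
    all_otus[[cl]] <- otus
  }
  # merge class-wise OTU sets over the common sample set
  counts <- do.call(rbind, lapply(all_otus, function(o) {
    m <- matrix(0L, nrow(o$counts), length(samples),
                dimnames = list(NULL, samples))
    m[, colnames(o$counts)] <- o$counts
    m
  }))
  info <- do.call(rbind, lapply(all_otus, function(o) o$info))
  rownames(counts) <- sprintf("OTU_%05d", seq_len(nrow(counts)))
  info$otu_id <- rownames(counts)
  info$shared <- rowSums(counts > 0L) >= 2L
  rownames(info) <- NULL
  structure(list(counts = counts, info = info,
                 members = unlist(lapply(all_otus, function(o) o$members),
                                  recursive = FALSE)),
            class = "otu_set")
}

#' Run the full community-phylogenetics pipeline
#'
#' Synthetic reads -> QC -> OTUs -> six-state character matrix -> ordered
#' parsimony search (+ optional bootstrap) -> congruence metrics against the
#' planted host tree.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param bootstrap_reps bootstrap pseudo-replicates (0 to skip).
#' @param n_starts,rearrangement heuristic-search settings.
#' @param boot_starts,boot_rearrangement per-replicate search settings for
#'   the bootstrap.
#' @param seed analysis seed (classifier + searches).
#' @return list with `qc`, `otus`, `char_matrix`, `search`, `best_tree`
#'   (branch lengths = parsimony changes), `boot` (or NULL), `rf_to_planted`,
#'   `species_support` (per-species clade bootstrap percent, if bootstrap
#'   run).
#' @export
run_pipeline <- function(dataset, bootstrap_reps = 200L, n_starts = 10L,
                         rearrangement = "SPR", boot_starts = 2L,
                         boot_rearrangement = "SPR", seed = 1L) {
  qc <- process_reads(dataset, seed = seed)
  kept <- qc$kept
  # the technical replicate supports the overlap analysis only
  main <- if (is.null(dataset$ground_truth$replicate_pair)) kept else
    kept[kept$sample_id != dataset$ground_truth$replicate_pair["replicate"], ,
         drop = FALSE]
  otus <- cluster_otus(main, dataset$references)
  ab <- species_abundance(otus)
  cm <- build_character_matrix(ab)
  search <- heuristic_search(cm, n_starts = n_starts,
                             rearrangement = rearrangement, seed = seed)
  best <- search$trees[[1L]]
  best_bl <- assign_branch_lengths(best, cm)
  planted <- ape::keep.tip(dataset$tree, rownames(cm))
  boot <- NULL
  species_support <- NULL
  if (bootstrap_reps > 0L) {
    boot <- bootstrap_parsimony(cm, n_reps = bootstrap_reps,
                                n_starts = boot_starts,
                                rearrangement = boot_rearrangement,
                                seed = seed + 1L)
    smap <- attr(dataset$tree, "species_map")
    smap <- smap[rownames(cm)]
    species_support <- vapply(
      split(names(smap), unname(smap)),
      function(tips) clade_support(boot, tips, rownames(cm)), numeric(1))
    species_support <- species_support[
      vapply(split(names(smap), unname(smap)), length, integer(1)) >= 2L]
  }
  list(qc = qc, otus = otus, char_matrix = cm, search = search,
       best_tree = best_bl, boot = boot,
       rf_to_planted = rf_distance(best, planted),
       species_support = species_support)
}
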