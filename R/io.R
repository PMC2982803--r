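#' Read and write amplicon datasets on disk
#'
#' `write_dataset()` materializes a simulated dataset in standard formats:
#' reads as FASTQ, references as FASTA plus a taxonomy TSV (taxon id, phylum,
#' class), a sample manifest TSV (sample id, species, barcode, replicate
#' flag), the true host tree as Newick, and the ground truth as JSON.
#' `read_fastq()` loads a FASTQ into the read data.frame the pipeline uses.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `write_dataset`: the directory, invisibly; `read_fastq`: a
#'   data.frame with `read_id`, `sequence`, `quality`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(dataset$reads, file.path(dir, "reads.fastq"))
  refs <- Biostrings::DNAStringSet(setNames(dataset$references$sequence,
                                            dataset$references$taxon_id))
  Biostrings::writeXStringSet(refs, file.path(dir, "references.fasta"))
  write.table(dataset$references[, c("taxon_id", "phylum", "class")],
              file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(dataset$tree, file.path(dir, "host_tree.nwk"))
  gt <- dataset$ground_truth
  gt$profiles <- NULL # stored separately below
  # named atomic vectors must become JSON objects, not bare arrays
  gt <- lapply(gt, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(data.frame(sample = rownames(dataset$profiles),
                         dataset$profiles, check.names = FALSE),
              file.path(dir, "true_profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param reads read data.frame (`read_id`, `sequence`, `quality`).
#' @param file FASTQ path.
#' @export
write_fastq <- function(reads, file) {
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(dna, file, format = "fastq", qualities = qual)
  invisible(file)
}

#' @rdname write_dataset
#' @param file FASTQ path.
#' @export
read_fastq <- function(file) {
  dna <- Biostrings::readDNAStringSet(file, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(read_id = names(dna),
             sequence = as.character(dna),
             quality = as.character(S4Vectors::mcols(dna)$qualities))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  reads <- read_fastq(file.path(dir, "reads.fastq"))
  refs <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  tax <- read.delim(file.path(dir, "taxonomy.tsv"))
  references <- data.frame(taxon_id = tax$taxon_id, phylum = tax$phylum,
                           class = tax$class,
                           sequence = as.character(refs[tax$taxon_id]))
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  tree <- read_newick(file.path(dir, "host_tree.nwk"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  gt <- lapply(gt, function(x) if (is.list(x)) unlist(x) else x)
  gt$accept_window <- as.integer(gt$accept_window)
  prof <- read.delim(file.path(dir, "true_profiles.tsv"), check.names = FALSE)
  profiles <- as.matrix(prof[, -1, drop = FALSE])
  rownames(profiles) <- prof$sample
  list(tree = tree, profiles = profiles, references = references,
       reads = reads, manifest = manifest, ground_truth = gt)
}

#' Write an OTU table and representative sequences
#'
#' @param otus an `otu_set`.
#' @param file TSV path for the table; a sibling `.fasta` holds the
#'   representatives.
#' @export
write_otu_table <- function(otus, file) {
  df <- data.frame(otus$info[, c("otu_id", "class")],
                   shared = otus$info$shared, otus$counts,
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  fasta <- sub("\\.tsv$", ".fasta", file)
  reps <- Biostrings::DNAStringSet(setNames(otus$info$representative,
                                            otus$info$otu_id))
  Biostrings::writeXStringSet(reps, fasta)
  invisible(file)
}
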