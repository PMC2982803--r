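#' Normalize counts to per-sample relative frequencies
#'
#' @param counts samples x features non-negative integer matrix.
#' @param sample_depths per-sample denominators (named or in row order);
#'   defaults to the row sums.
#' @param rank rank label carried in the result.
#' @return an `abundance_matrix`: list with `counts`, `freq` (rows sum to 1),
#'   `rank`.
#' @export
normalize_abundance <- function(counts, sample_depths = NULL,
                                rank = c("species", "phylum")) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  if (is.null(sample_depths)) sample_depths <- rowSums(counts)
  if (!is.null(names(sample_depths))) {
    sample_depths <- sample_depths[rownames(counts)]
  }
  if (any(sample_depths <= 0)) stop("sample with zero total reads")
  freq <- counts / sample_depths
  structure(list(counts = counts, freq = freq, rank = rank),
            class = "abundance_matrix")
}

#' Code a frequency as one of six ordered states
#'
#' State 0 iff the feature is absent (frequency exactly 0); otherwise states
#' 1-5 by descending log10 bins with default edges 10^-1, 10^-2, 10^-3,
#' 10^-4: state 5 for frequency >= 10^-1, 4 for `[10^-2, 10^-1)`, ..., 1 for
#' `(0, 10^-4)`. A boundary belongs to the higher state.
#'
#' @param frequency numeric vector of frequencies in `[0, 1]`.
#' @param bin_edges four strictly descending thresholds.
#' @return integer state vector (0-5).
#' @export
code_states <- function(frequency, bin_edges = c(1e-1, 1e-2, 1e-3, 1e-4)) {
  if (any(frequency < 0 | frequency > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (any(diff(bin_edges) >= 0)) stop("bin edges must be strictly descending")
  state <- 1L + vapply(frequency, function(f) sum(f >= bin_edges), integer(1))
  state[frequency == 0] <- 0L
  state
}

#' Build the ordered six-state character matrix
#'
#' One character per feature (shared OTU at species rank, phylum at phylum
#' rank), one row per sample; every cell is the coded log-abundance state of
#' that feature in that sample. Constant characters are retained (they
#' contribute zero parsimony length).
#'
#' @param abund an `abundance_matrix` from [normalize_abundance()].
#' @param bin_edges passed to [code_states()].
#' @return integer matrix samples x characters with attributes `rank` and
#'   `bin_edges`.
#' @export
build_character_matrix <- function(abund, bin_edges = c(1e-1, 1e-2, 1e-3, 1e-4)) {
  stopifnot(inherits(abund, "abundance_matrix"))
  if (nrow(abund$freq) < 4L) {
    stop("need at least 4 samples for an unrooted tree")
  }
  m <- apply(abund$freq, 2L, code_states, bin_edges = bin_edges)
  m <- matrix(as.integer(m), nrow(abund$freq), ncol(abund$freq),
              dimnames = dimnames(abund$freq))
  attr(m, "rank") <- abund$rank
  attr(m, "bin_edges") <- bin_edges
  m
}

#' Species-rank abundance from an OTU set (shared OTUs only)
#'
#' @param otus an `otu_set`; only shared OTUs enter, and per-sample
#'   denominators are the shared-OTU read totals.
#' @return an `abundance_matrix` (samples x shared OTUs).
#' @export
species_abundance <- function(otus) {
  shared <- partition_otus(otus)$shared
  normalize_abundance(t(shared$counts), rank = "species")
}

#' Phylum-rank abundance from filtered read assignments
#'
#' Collapses all classifiable filtered reads by phylum; denominators are the
#' per-sample totals of all such reads.
#'
#' @param reads filtered reads (with `sample_id`).
#' @param assignments their assignment table (with `phylum`).
#' @return an `abundance_matrix` (samples x phyla).
#' @export
phylum_abundance <- function(reads, assignments) {
  tab <- table(reads$sample_id, assignments$phylum)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  normalize_abundance(counts, rank = "phylum")
}

#' Write a character matrix as TSV, relaxed PHYLIP, or NEXUS
#'
#' The NEXUS output carries an assumptions block declaring the characters
#' ordered (states 0-5), so the matrix can be consumed by standard parsimony
#' software.
#'
#' @param m character matrix from [build_character_matrix()].
#' @param file output path.
#' @name write_character_matrix
#' @export
write_character_tsv <- function(m, file) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_character_matrix
#' @export
write_phylip <- function(m, file) {
  lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
             sprintf("%s  %s", rownames(m),
                     apply(m, 1L, paste, collapse = "")))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_character_matrix
#' @export
read_phylip <- function(file) {
  lines <- readLines(file)
  header <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- rows[lengths(rows) == 2L]
  m <- do.call(rbind, lapply(rows, function(r) {
    as.integer(strsplit(r[2L], "")[[1L]])
  }))
  rownames(m) <- vapply(rows, `[`, character(1), 1L)
  stopifnot(nrow(m) == header[1L], ncol(m) == header[2L])
  m
}

#' @rdname write_character_matrix
#' @export
write_nexus <- function(m, file) {
  rows <- sprintf("    %s  %s", rownames(m), apply(m, 1L, paste, collapse = ""))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"012345\" MISSING=? GAP=-;",
    "  MATRIX", rows, "  ;", "END;",
    "BEGIN ASSUMPTIONS;",
    "  OPTIONS DEFTYPE=ORD;",
    sprintf("  TYPESET * ordered = ord: 1-%d;", ncol(m)),
    "END;")
  writeLines(lines, file)
  invisible(file)
}
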