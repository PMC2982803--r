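#' Trim low-quality read ends
#'
#' For each read, keeps the longest contiguous subsequence whose terminal
#' bases both have error probability <= `max_error` and whose mean error
#' probability is <= `max_error` (accuracy-threshold end trimming). A read may
#' be trimmed to length zero; empty reads are removed by the downstream
#' length filter.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33).
#' @param max_error per-base error probability threshold (default 0.005,
#'   i.e. 0.5%).
#' @return `reads` with `sequence` and `quality` trimmed.
#' @export
trim_low_quality_ends <- function(reads, max_error = 0.005) {
  stopifnot(nrow(reads) > 0L)
  n <- nrow(reads)
  seqs <- reads$sequence
  quals <- reads$quality
  for (i in seq_len(n)) {
    err <- 10^(-(utf8ToInt(quals[i]) - 33) / 10)
    b <- .trim_bounds_cpp(err, max_error)
    if (b[1L] == 0L) {
      seqs[i] <- ""
      quals[i] <- ""
    } else if (b[1L] > 1L || b[2L] < length(err)) {
      seqs[i] <- substr(seqs[i], b[1L], b[2L])
      quals[i] <- substr(quals[i], b[1L], b[2L])
    }
  }
  reads$sequence <- seqs
  reads$quality <- quals
  reads
}

#' Demultiplex reads by exact barcode + primer prefix
#'
#' A read is kept iff its 5' end is exactly `barcode + primer` for some
#' sample; the matched prefix is then stripped from sequence and quality.
#' Reads with any mismatch in the prefix are removed.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param barcode_map named character vector, sample id -> barcode. Barcodes
#'   must be prefix-free against each other.
#' @param primer forward primer sequence following the barcode.
#' @return data.frame of kept reads with a `sample_id` column and stripped
#'   prefixes; the number removed is in attribute `n_removed`.
#' @export
demultiplex <- function(reads, barcode_map, primer) {
  bcs <- unname(barcode_map)
  if (anyDuplicated(bcs)) stop("duplicate barcodes")
  for (a in seq_along(bcs)) {
    for (b in seq_along(bcs)) {
      if (a != b && startsWith(bcs[b], bcs[a])) {
        stop("ambiguous barcode set: '", bcs[a], "' is a prefix of '",
             bcs[b], "'")
      }
    }
  }
  prefixes <- paste0(bcs, primer)
  sample_of <- rep(NA_character_, nrow(reads))
  strip <- integer(nrow(reads))
  for (k in seq_along(prefixes)) {
    hit <- is.na(sample_of) & startsWith(reads$sequence, prefixes[k])
    sample_of[hit] <- names(barcode_map)[k]
    strip[hit] <- nchar(prefixes[k])
  }
  keep <- !is.na(sample_of)
  out <- reads[keep, , drop = FALSE]
  out$sample_id <- sample_of[keep]
  out$sequence <- substr(out$sequence, strip[keep] + 1L, nchar(out$sequence))
  out$quality <- substr(out$quality, strip[keep] + 1L, nchar(out$quality))
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

BASE_CODE <- local({
  v <- integer(128)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v
})

# Integer k-mer codes of a sequence (NA-containing k-mers dropped).
kmer_codes <- function(seq, k) {
  v <- BASE_CODE[utf8ToInt(seq)] - 1L
  v[v < 0L] <- NA_integer_
  if (length(v) < k) return(integer(0))
  m <- stats::embed(v, k)
  codes <- as.integer(m %*% 4^(seq_len(k) - 1L))
  codes[!is.na(codes)]
}

#' Train the word-frequency naive-Bayes taxonomic classifier
#'
#' RDP-style classifier: features are k-mer presences in the reference
#' sequences of each class, with add-half smoothing:
#' `P(kmer | class) = (n_refs_with_kmer + 0.5) / (n_refs + 1)`.
#'
#' @param references reference data.frame (`taxon_id`, `phylum`, `class`,
#'   `sequence`).
#' @param k k-mer length (default 8).
#' @return classifier object (log-probability matrix over all 4^k words).
#' @export
build_classifier <- function(references, k = 8L) {
  if (nrow(references) == 0L) stop("empty reference set")
  classes <- sort(unique(references$class))
  n_words <- 4L^k
  logp <- matrix(NA_real_, n_words, length(classes),
                 dimnames = list(NULL, classes))
  for (cl in classes) {
    seqs <- references$sequence[references$class == cl]
    counts <- integer(n_words)
    for (s in seqs) {
      u <- unique(kmer_codes(s, k)) + 1L
      counts[u] <- counts[u] + 1L
    }
    logp[, cl] <- log((counts + 0.5) / (length(seqs) + 1))
  }
  phylum_of <- references$phylum[!duplicated(references$class)]
  names(phylum_of) <- references$class[!duplicated(references$class)]
  structure(list(logp = logp, k = k, classes = classes,
                 phylum_of = phylum_of), class = "nb_classifier")
}

#' Classify reads taxonomically with bootstrap confidence
#'
#' Assigns each read to the class with the maximum naive-Bayes posterior over
#' its k-mer presence features; the bootstrap confidence is the percentage of
#' `n_bootstrap` subsamples (each of `floor(W/k)` k-mers drawn with
#' replacement from the read's `W` k-mers) whose assignment agrees with the
#' full-read assignment.
#'
#' @param reads data.frame with `read_id`, `sequence` (sample-assigned or
#'   not).
#' @param references reference data.frame, or a prebuilt [build_classifier()].
#' @param k k-mer length (default 8); reads shorter than `k` receive an `NA`
#'   class with confidence 0.
#' @param n_bootstrap bootstrap subsamples per read (default 100).
#' @param seed integer seed for the bootstrap draws.
#' @return data.frame with `read_id`, `class`, `phylum`, `confidence`
#'   (percent) and `start` (`NA`, filled by [locate_starts()]).
#' @export
classify_reads <- function(reads, references, k = 8L, n_bootstrap = 100L,
                           seed = 1L) {
  clf <- if (inherits(references, "nb_classifier")) references
         else build_classifier(references, k)
  k <- clf$k
  logp <- clf$logp
  n_class <- ncol(logp)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  useqs <- unique(reads$sequence)
  cls <- rep(NA_character_, length(useqs))
  conf <- rep(0, length(useqs))
  for (i in seq_along(useqs)) {
    codes <- kmer_codes(useqs[i], k)
    if (length(codes) == 0L) next
    full <- colSums(logp[unique(codes) + 1L, , drop = FALSE])
    win <- which.max(full)
    cls[i] <- clf$classes[win]
    nb <- max(1L, length(codes) %/% k)
    draw <- matrix(codes[sample.int(length(codes), nb * n_bootstrap,
                                    replace = TRUE)] + 1L,
                   nrow = n_bootstrap * nb)
    sc <- rowsum(logp[draw[, 1L], , drop = FALSE],
                 group = rep(seq_len(n_bootstrap), each = nb))
    # random tie-breaks: a subsample with no discriminating word must split
    # its vote, not inherit the full-read winner
    agree <- max.col(sc, ties.method = "random") == win
    conf[i] <- 100 * mean(agree)
  }
  idx <- match(reads$sequence, useqs)
  data.frame(read_id = reads$read_id,
             class = cls[idx],
             phylum = unname(clf$phylum_of[cls[idx]]),
             confidence = conf[idx],
             start = NA_integer_)
}

#' Classify a single read
#'
#' @param read one-row data.frame (or list) with `read_id` and `sequence`.
#' @inheritParams classify_reads
#' @return one-row assignment data.frame (see [classify_reads()]).
#' @export
classify_read <- function(read, references, k = 8L, n_bootstrap = 100L,
                          seed = 1L) {
  classify_reads(data.frame(read_id = read$read_id,
                            sequence = read$sequence),
                 references, k = k, n_bootstrap = n_bootstrap, seed = seed)
}

#' Locate read start positions on the class alignment
#'
#' Semi-globally aligns each read (global in the read, local in the
#' reference) to its assigned class's representative sequence and reports the
#' 1-based reference column of the read's first base. Alignments scoring below
#' `min_score_frac * read length` yield `NA` (the read then fails the
#' position filter).
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param assignments assignment table from [classify_reads()].
#' @param references reference data.frame (for class representatives), or a
#'   named character vector class -> representative sequence.
#' @param min_score_frac score floor as a fraction of read length.
#' @return `assignments` with the `start` column filled.
#' @export
locate_starts <- function(reads, assignments, references,
                          min_score_frac = 0.4) {
  reps <- if (is.character(references)) references
          else class_representatives(references)
  key <- paste(reads$sequence, assignments$class, sep = "\r")
  ukey <- !duplicated(key) & !is.na(assignments$class)
  ustart <- rep(NA_integer_, sum(ukey))
  useq <- reads$sequence[ukey]
  ucls <- assignments$class[ukey]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (cl in unique(ucls)) {
    sel <- which(ucls == cl & nchar(useq) > 0L)
    if (!length(sel) || is.na(reps[cl])) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(useq[sel]),
      Biostrings::DNAString(reps[[cl]]),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 2, gapExtension = 1)
    st <- Biostrings::start(Biostrings::subject(aln))
    low <- Biostrings::score(aln) < min_score_frac * nchar(useq[sel])
    st[low] <- NA_integer_
    ustart[sel] <- st
  }
  assignments$start <- ustart[match(key, key[ukey])]
  assignments
}

#' Single-read start location
#' @inheritParams locate_starts
#' @param read one-row data.frame with `read_id`, `sequence`.
#' @param assignment one-row assignment for the read.
#' @return the 1-based reference column (or `NA`).
#' @export
locate_start <- function(read, assignment, references,
                         min_score_frac = 0.4) {
  a <- locate_starts(data.frame(read_id = read$read_id,
                                sequence = read$sequence),
                     assignment, references, min_score_frac)
  a$start[1L]
}

#' Quality-filter classified reads
#'
#' A read is kept iff (in this order of accounting): (i) its length is at
#' least `min_length`; (ii) its class bootstrap confidence is strictly
#' greater than `min_confidence`; (iii) its start position lies inside its
#' domain's accepted window (inclusive); and (iv) its class is not the
#' chloroplast class. Each removed read is counted under the first rule it
#' violates.
#'
#' @param reads demultiplexed read data.frame.
#' @param assignments assignment table with `start` filled.
#' @param min_length minimum read length in nt (applied after barcode/primer
#'   stripping; recorded in the QC report).
#' @param min_confidence bootstrap confidence threshold, percent (strict:
#'   kept requires confidence > 70 by default).
#' @param archaea_window,bacteria_window inclusive 1-based start windows per
#'   domain.
#' @param domain_map named character vector class -> `"Archaea"`/`"Bacteria"`
#'   (default: everything bacterial).
#' @param chloroplast_class class label identifying chloroplast reads.
#' @return list with `kept` (reads), `kept_assignments`, `counts` (named
#'   removals per rule: short, low_confidence, wrong_region, chloroplast) and
#'   `qc` (report list).
#' @export
filter_reads <- function(reads, assignments, min_length = 150L,
                         min_confidence = 70,
                         archaea_window = c(844L, 850L),
                         bacteria_window = c(851L, 857L),
                         domain_map = NULL,
                         chloroplast_class = "Chloroplast") {
  stopifnot(nrow(reads) == nrow(assignments))
  len <- nchar(reads$sequence)
  domain <- if (is.null(domain_map)) rep("Bacteria", nrow(reads))
            else unname(domain_map[assignments$class])
  lo <- ifelse(domain == "Archaea", archaea_window[1L], bacteria_window[1L])
  hi <- ifelse(domain == "Archaea", archaea_window[2L], bacteria_window[2L])
  bad_len <- len < min_length
  bad_conf <- !bad_len & (is.na(assignments$class) |
                            assignments$confidence <= min_confidence)
  bad_pos <- !bad_len & !bad_conf &
    (is.na(assignments$start) | assignments$start < lo |
       assignments$start > hi)
  bad_chl <- !bad_len & !bad_conf & !bad_pos &
    !is.na(assignments$class) & assignments$class == chloroplast_class
  keep <- !(bad_len | bad_conf | bad_pos | bad_chl)
  counts <- c(short = sum(bad_len), low_confidence = sum(bad_conf),
              wrong_region = sum(bad_pos), chloroplast = sum(bad_chl))
  list(kept = {
         out <- reads[keep, , drop = FALSE]; rownames(out) <- NULL; out
       },
       kept_assignments = {
         a <- assignments[keep, , drop = FALSE]; rownames(a) <- NULL; a
       },
       counts = counts,
       qc = list(n_input = nrow(reads), n_kept = sum(keep),
                 removed = counts,
                 length_check = "applied after barcode/primer stripping",
                 min_length = min_length, min_confidence = min_confidence,
                 archaea_window = archaea_window,
                 bacteria_window = bacteria_window))
}
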