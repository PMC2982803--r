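# Phred+33 quality character for an error probability.
phred_char <- function(p) {
  q <- pmin(pmax(round(-10 * log10(pmax(p, 1e-5))), 2L), 41L)
  intToUtf8(q + 33L, multiple = TRUE)
}

#' Per-base error probabilities from a Phred+33 quality string
#' @param quality quality string(s).
#' @return numeric vector (or list for multiple strings) of probabilities.
#' @export
error_probs <- function(quality) {
  one <- function(q) 10^(-(utf8ToInt(q) - 33) / 10)
  if (length(quality) == 1L) one(quality) else lapply(quality, one)
}

# Deterministic 4-nt barcodes with pairwise Hamming distance >= 2, so a
# single corrupted base can never convert one barcode into another.
default_barcodes <- function(n) {
  pool <- sort(apply(expand.grid(BASES, BASES, BASES, BASES), 1L,
                     paste, collapse = ""))
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }
  chosen <- character(0)
  for (cand in pool) {
    if (all(vapply(chosen, ham, integer(1), a = cand) >= 2L)) {
      chosen <- c(chosen, cand)
      if (length(chosen) == n) break
    }
  }
  if (length(chosen) < n) stop("barcode pool exhausted")
  chosen
}

# Apply substitutions/insertions/deletions to a payload character vector.
# Returns list(chars, n_mismatch).
apply_errors <- function(chars, n_mm, n_ins, n_del) {
  if (n_del > 0L && n_del < length(chars)) {
    chars <- chars[-sample.int(length(chars), n_del)]
  }
  if (n_mm > 0L) {
    pos <- sample.int(length(chars), min(n_mm, length(chars)))
    shift <- sample.int(3L, length(pos), replace = TRUE)
    cur <- match(chars[pos], BASES)
    chars[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    n_mm <- length(pos)
  }
  if (n_ins > 0L) {
    for (k in seq_len(n_ins)) {
      at <- sample.int(length(chars) + 1L, 1L)
      chars <- append(chars, sample(BASES, 1L), after = at - 1L)
    }
  }
  list(chars = chars, n_mismatch = n_mm)
}

#' Generate barcoded amplicon reads from community profiles
#'
#' Each read is `barcode + primer + payload`, where the payload is an
#' error-bearing window of its source reference sequence. Planted violations
#' of the downstream quality filters are generated at fixed per-sample counts
#' and recorded in the ground truth: corrupted barcode/primer prefixes
#' (removed at demultiplexing), short reads (< 150 nt), reads starting outside
#' the accepted alignment window, and chloroplast contaminants. A technical
#' replicate of one sample can be generated at a configurable depth ratio
#' (default 3.5x) with fresh error draws from the same true profile.
#'
#' Sequencing errors are applied to the payload only; the barcode/primer
#' prefix is error-free unless deliberately corrupted, so demultiplexing
#' losses match the planted counts exactly. Base qualities encode the
#' configured error probabilities (Phred+33); a configurable fraction of reads
#' carries a degraded 3' tail to exercise quality trimming.
#'
#' @param profiles samples x OTUs frequency matrix from [evolve_profiles()].
#' @param references reference data.frame from [synthesize_references()].
#' @param depth_per_sample reads generated per sample before any filtering.
#' @param error_rates named vector `c(mismatch=, insertion=, deletion=)` of
#'   per-base rates in `[0, 1)`.
#' @param barcode_map optional named character vector sample -> barcode
#'   (unique, equal length); autogenerated when `NULL`.
#' @param primer forward primer sequence present 5' of every payload.
#' @param accept_window inclusive 1-based reference window in which
#'   legitimate reads start.
#' @param off_window window used for planted wrong-region reads.
#' @param off_window_fraction,short_fraction,contaminant_fraction,
#'   corrupt_prefix_fraction per-sample fractions of planted violations
#'   (converted to exact counts with `round()`).
#' @param short_lengths length range of planted short reads.
#' @param read_length_mean,read_length_sd payload length distribution
#'   (normal, rounded, clamped to `[170, 260]`).
#' @param degraded_fraction fraction of clean reads given a low-quality 3'
#'   tail; `degraded_tail` bases at error `degraded_error`.
#' @param replicate_sample sample to resequence as a technical replicate
#'   (default: first sample; `NA` to disable).
#' @param replicate_ratio depth ratio of the replicate (default 3.5).
#' @param seed integer seed.
#' @return list with `reads` (data.frame: read_id, sequence, quality),
#'   `manifest` (sample_id, species, barcode, is_replicate), and
#'   `ground_truth` (see Details).
#' @export
generate_reads <- function(profiles, references,
                           depth_per_sample = 5000L,
                           error_rates = c(mismatch = 0.002,
                                           insertion = 5e-4, deletion = 5e-4),
                           barcode_map = NULL,
                           primer = "AAACTTAAAGGAATTGACGG",
                           accept_window = c(11L, 17L),
                           off_window = c(41L, 60L),
                           off_window_fraction = 0.02,
                           short_fraction = 0.02,
                           short_lengths = c(100L, 149L),
                           contaminant_fraction = 0.02,
                           corrupt_prefix_fraction = 0.01,
                           read_length_mean = 220, read_length_sd = 12,
                           degraded_fraction = 0.05, degraded_tail = 20L,
                           degraded_error = 0.02,
                           replicate_sample = NULL, replicate_ratio = 3.5,
                           seed = 1L) {
  if (any(error_rates < 0) || any(error_rates >= 1)) {
    stop("error rates must be in [0, 1)")
  }
  samples <- rownames(profiles)
  if (is.null(barcode_map)) {
    n_bc <- length(samples) + 1L # one spare for the technical replicate
    barcode_map <- setNames(default_barcodes(n_bc)[seq_along(samples)], samples)
    spare_barcode <- default_barcodes(n_bc)[n_bc]
  } else {
    spare_barcode <- NULL
  }
  if (anyDuplicated(barcode_map)) stop("duplicate barcodes")
  if (is.null(replicate_sample)) replicate_sample <- samples[1L]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ref_seq <- setNames(references$sequence, references$taxon_id)
  otu_ids <- colnames(profiles)
  chl_ids <- references$taxon_id[references$class == "Chloroplast"]
  seq_len_ref <- nchar(references$sequence[1L])

  jobs <- data.frame(sample = samples, depth = depth_per_sample,
                     is_replicate = FALSE, barcode = unname(barcode_map[samples]))
  if (!is.na(replicate_sample)) {
    rep_id <- paste0(replicate_sample, "R")
    rep_bc <- if (!is.null(spare_barcode)) spare_barcode else
      stop("supply a barcode for the replicate sample in barcode_map")
    jobs <- rbind(jobs, data.frame(
      sample = rep_id, depth = as.integer(round(replicate_ratio * depth_per_sample)),
      is_replicate = TRUE, barcode = rep_bc))
    barcode_map <- c(barcode_map, setNames(rep_bc, rep_id))
  }

  all_reads <- vector("list", nrow(jobs))
  gt_rows <- vector("list", nrow(jobs))
  n_mm_total <- 0L
  n_bases_total <- 0L
  counter <- 0L
  m_rate <- error_rates[["mismatch"]]
  i_rate <- error_rates[["insertion"]]
  d_rate <- error_rates[["deletion"]]
  base_p <- m_rate + i_rate + d_rate
  qc_main <- phred_char(base_p)
  qc_bad <- phred_char(degraded_error)
  qc_prefix <- phred_char(0.001)

  for (j in seq_len(nrow(jobs))) {
    sam <- jobs$sample[j]
    depth <- jobs$depth[j]
    prof_sample <- if (jobs$is_replicate[j]) replicate_sample else sam
    prob <- profiles[prof_sample, ]
    n_corrupt <- round(corrupt_prefix_fraction * depth)
    n_short <- round(short_fraction * depth)
    n_off <- round(off_window_fraction * depth)
    n_contam <- round(contaminant_fraction * depth)
    cat_lab <- rep("none", depth)
    cat_lab[seq_len(n_corrupt)] <- "corrupt_prefix"
    cat_lab[n_corrupt + seq_len(n_short)] <- "short"
    cat_lab[n_corrupt + n_short + seq_len(n_off)] <- "wrong_region"
    cat_lab[n_corrupt + n_short + n_off + seq_len(n_contam)] <- "chloroplast"
    cat_lab <- sample(cat_lab)

    otu <- sample(otu_ids, depth, replace = TRUE, prob = prob)
    otu[cat_lab == "chloroplast"] <- sample(chl_ids, sum(cat_lab == "chloroplast"),
                                            replace = TRUE)
    # legitimate starts stay two columns inside the accepted window: a
    # terminal indel, possibly compounded by reference-vs-representative
    # divergence right at the window edge, can shift the located start by
    # up to two columns without crossing the filter boundary
    start <- sample(seq(accept_window[1L] + 2L, accept_window[2L] - 2L),
                    depth, replace = TRUE)
    off <- cat_lab == "wrong_region"
    start[off] <- sample(seq(off_window[1L], off_window[2L]), sum(off),
                         replace = TRUE)
    len <- pmin(pmax(round(rnorm(depth, read_length_mean, read_length_sd)),
                     170L), 260L)
    short <- cat_lab == "short"
    len[short] <- sample(seq(short_lengths[1L], short_lengths[2L]),
                         sum(short), replace = TRUE)
    len <- pmin(len, seq_len_ref - start + 1L)
    degraded <- cat_lab == "none" & runif(depth) < degraded_fraction
    len[degraded] <- pmax(len[degraded], 150L + degraded_tail + 10L)

    payload <- substr(ref_seq[otu], start, start + len - 1L)
    n_mm <- rbinom(depth, len, m_rate)
    n_ins <- rbinom(depth, len, i_rate)
    n_del <- rbinom(depth, len, d_rate)
    # planted short reads carry substitutions only, so an indel can never
    # carry one across the length-filter boundary
    n_ins[short] <- 0L
    n_del[short] <- 0L
    need_work <- which(n_mm + n_ins + n_del > 0L | degraded)
    qual <- strrep(qc_main, nchar(payload))
    for (i in need_work) {
      chars <- strsplit(payload[i], "", fixed = TRUE)[[1L]]
      res <- apply_errors(chars, n_mm[i], n_ins[i], n_del[i])
      chars <- res$chars
      n_mm[i] <- res$n_mismatch
      L <- length(chars)
      if (degraded[i]) {
        tail_idx <- seq(L - degraded_tail + 1L, L)
        flip <- tail_idx[runif(degraded_tail) < degraded_error]
        if (length(flip)) {
          cur <- match(chars[flip], BASES)
          chars[flip] <- BASES[((cur - 1L +
            sample.int(3L, length(flip), replace = TRUE)) %% 4L) + 1L]
        }
        qual[i] <- paste0(strrep(qc_main, L - degraded_tail),
                          strrep(qc_bad, degraded_tail))
      } else {
        qual[i] <- strrep(qc_main, L)
      }
      payload[i] <- paste(chars, collapse = "")
    }
    # mismatch-rate tally over non-degraded reads: realized substitutions vs
    # Bernoulli trials (one per pre-indel payload base)
    n_mm_total <- n_mm_total + sum(n_mm[!degraded])
    n_bases_total <- n_bases_total + sum(len[!degraded])

    prefix <- paste0(jobs$barcode[j], primer)
    seqs <- paste0(prefix, payload)
    quals <- paste0(strrep(qc_prefix, nchar(prefix)), qual)
    corrupt <- which(cat_lab == "corrupt_prefix")
    for (i in corrupt) {
      chars <- strsplit(substr(seqs[i], 1L, nchar(prefix)), "", fixed = TRUE)[[1L]]
      at <- sample.int(length(chars), 1L)
      cur <- match(chars[at], BASES)
      chars[at] <- BASES[((cur - 1L + sample.int(3L, 1L)) %% 4L) + 1L]
      seqs[i] <- paste0(paste(chars, collapse = ""),
                        substr(seqs[i], nchar(prefix) + 1L, nchar(seqs[i])))
    }
    ids <- sprintf("read_%07d", counter + seq_len(depth))
    counter <- counter + depth
    all_reads[[j]] <- data.frame(read_id = ids, sequence = seqs,
                                 quality = quals)
    gt_rows[[j]] <- data.frame(read_id = ids, sample = sam, otu = otu,
                               start = start, planted = cat_lab,
                               is_replicate = jobs$is_replicate[j])
  }

  reads <- do.call(rbind, all_reads)
  gt <- do.call(rbind, gt_rows)
  manifest <- data.frame(sample_id = jobs$sample,
                         species = sub("_[0-9]+R?$", "",
                                       sub("R$", "", jobs$sample)),
                         barcode = jobs$barcode,
                         is_replicate = jobs$is_replicate)
  ground_truth <- list(
    read_to_otu = setNames(gt$otu, gt$read_id),
    read_to_sample = setNames(gt$sample, gt$read_id),
    planted_rule = setNames(gt$planted, gt$read_id),
    true_start = setNames(gt$start, gt$read_id),
    contaminant_ids = gt$read_id[gt$planted == "chloroplast"],
    is_replicate_read = setNames(gt$is_replicate, gt$read_id),
    realized_mismatches = n_mm_total,
    mismatch_bases = n_bases_total,
    profiles = profiles,
    barcode_map = barcode_map,
    accept_window = accept_window,
    primer = primer,
    error_rates = error_rates,
    replicate_pair = if (!is.na(replicate_sample))
      c(original = replicate_sample, replicate = paste0(replicate_sample, "R"))
    else NULL)
  list(reads = reads, manifest = manifest, ground_truth = ground_truth)
}
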