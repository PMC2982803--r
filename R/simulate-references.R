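BASES <- c("A", "C", "G", "T")

# Substitute a fraction `rate` of positions with a different random base.
mutate_seq <- function(chars, rate) {
  n <- length(chars)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(chars)
  pos <- sample.int(n, k)
  shift <- sample.int(3L, k, replace = TRUE)
  cur <- match(chars[pos], BASES)
  chars[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  chars
}

random_seq <- function(n) sample(BASES, n, replace = TRUE)

#' Synthesize a reference taxonomy of 16S-like sequences
#'
#' Generates one labelled reference sequence per true OTU by mutating a
#' per-class ancestral sequence, so that within-class identity exceeds
#' between-class identity (the structure the naive-Bayes classifier and the
#' class-wise alignment assume). A designated chloroplast class (phylum
#' Cyanobacteria) is always included to support contaminant filtering.
#' Mutations are substitution-only, so all references share the ancestor's
#' coordinate system.
#'
#' @param n_otus number of regular (gut bacterial) reference taxa; taxon ids
#'   `otu_001`... match the columns of [evolve_profiles()].
#' @param n_phyla number of regular phyla (one class per phylum).
#' @param seq_length reference length in nt (must be >= 150 so reads can
#'   survive the length filter).
#' @param divergence per-site substitution rate from the root to each class
#'   ancestor, in (0, 0.5); controls between-class separation.
#' @param within_divergence per-site rate from class ancestor to each taxon.
#' @param n_chloroplast number of chloroplast reference taxa.
#' @param seed integer seed.
#' @return data.frame with columns `taxon_id`, `phylum`, `class`, `sequence`.
#' @export
synthesize_references <- function(n_otus, n_phyla = 8L, seq_length = 400L,
                                  divergence = 0.2, within_divergence = 0.03,
                                  n_chloroplast = 8L, seed = 1L) {
  if (n_phyla < 1L || n_otus < n_phyla) stop("need n_otus >= n_phyla >= 1")
  if (divergence <= 0 || divergence >= 0.5) stop("divergence must be in (0, 0.5)")
  if (seq_length < 150L) stop("seq_length must be >= 150")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  root <- random_seq(seq_length)
  phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
  classes <- sprintf("Class%02d", seq_len(n_phyla))
  ancestors <- lapply(seq_len(n_phyla + 1L), function(i) mutate_seq(root, divergence))
  otu_phy <- rep(seq_len(n_phyla), length.out = n_otus)
  rows <- vector("list", n_otus + n_chloroplast)
  for (i in seq_len(n_otus)) {
    p <- otu_phy[i]
    rows[[i]] <- data.frame(
      taxon_id = sprintf("otu_%03d", i), phylum = phyla[p], class = classes[p],
      sequence = paste(mutate_seq(ancestors[[p]], within_divergence),
                       collapse = ""))
  }
  for (i in seq_len(n_chloroplast)) {
    rows[[n_otus + i]] <- data.frame(
      taxon_id = sprintf("chl_%02d", i), phylum = "Cyanobacteria",
      class = "Chloroplast",
      sequence = paste(mutate_seq(ancestors[[n_phyla + 1L]], within_divergence),
                       collapse = ""))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Class representative sequences
#'
#' The representative of each class (used as the coordinate system for
#' read placement and class-wise alignment) is the sequence of the
#' lexicographically smallest taxon id in that class.
#'
#' @param references reference data.frame from [synthesize_references()].
#' @return named character vector, class -> representative sequence.
#' @export
class_representatives <- function(references) {
  refs <- references[order(references$taxon_id), ]
  refs <- refs[!duplicated(refs$class), ]
  setNames(refs$sequence, refs$class)
}
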