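# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env()

# Small but complete dataset: 60 OTUs, 600 reads/sample, all planted
# violation types present, 3.5x technical replicate of human_1.
small_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- simulate_dataset(n_otus = 60L, depth_per_sample = 600L,
                                     seed = 7L)
  }
  .fixtures$ds
}

small_qc <- function() {
  if (is.null(.fixtures$qc)) {
    .fixtures$qc <- process_reads(small_dataset(), seed = 3L)
  }
  .fixtures$qc
}

# Error-free dataset (no sequencing errors, no degraded tails): OTU counts
# must match ground-truth tallies exactly.
clean_dataset <- function() {
  if (is.null(.fixtures$clean)) {
    .fixtures$clean <- simulate_dataset(
      n_otus = 30L, depth_per_sample = 400L, seed = 19L,
      error_rates = c(mismatch = 0, insertion = 0, deletion = 0),
      degraded_fraction = 0, replicate_sample = NA)
  }
  .fixtures$clean
}

clean_qc <- function() {
  if (is.null(.fixtures$clean_qc)) {
    .fixtures$clean_qc <- process_reads(clean_dataset(), seed = 5L)
  }
  .fixtures$clean_qc
}

species_map_of <- function(dataset) attr(dataset$tree, "species_map")

# Random character matrix over six ordered states.
random_matrix <- function(n_taxa, n_char, seed) {
  set.seed(seed)
  matrix(sample(0:5, n_taxa * n_char, replace = TRUE), n_taxa, n_char,
         dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
}

# Brute-force Sankoff oracle for a quartet ((a,b),(c,d)): minimise over both
# internal states explicitly.
quartet_oracle <- function(states, costs) {
  total <- 0
  for (ch in seq_len(ncol(states))) {
    s <- states[, ch] + 1L
    best <- Inf
    for (x in seq_len(nrow(costs))) {
      for (y in seq_len(nrow(costs))) {
        v <- costs[x, s[1]] + costs[x, s[2]] + costs[x, y] +
          costs[y, s[3]] + costs[y, s[4]]
        if (v < best) best <- v
      }
    }
    total <- total + best
  }
  total
}
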