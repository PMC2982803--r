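mk_reads <- function(seqs, samples = "s1", ids = NULL) {
  data.frame(read_id = if (is.null(ids)) sprintf("r%03d", seq_along(seqs))
             else ids,
             sequence = seqs,
             sample_id = rep_len(samples, length(seqs)))
}

test_that("dereplication merges identical and prefix-identical reads", {
  t1 <- dereplicate(mk_reads(c("ACGTACGT", "ACGTACGT")))
  expect_equal(length(t1$sequence), 1L)
  expect_equal(sum(t1$counts), 2L)
  # length-trimming rule: a prefix merges into its extension
  t2 <- dereplicate(mk_reads(c("ACGTACGT", "ACGTAC")))
  expect_equal(t2$sequence, "ACGTACGT")
  expect_equal(sum(t2$counts), 2L)
  # 10 planted haplotypes replicated exactly -> exactly 10 types
  set.seed(11)
  hap <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  reads <- mk_reads(rep(hap, each = 5), samples = c("s1", "s2"))
  t3 <- dereplicate(reads)
  expect_equal(sort(t3$sequence), sort(hap))
  expect_true(all(rowSums(t3$counts) == 5L))
})

test_that("class alignment places types on reference coordinates", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 1100, replace = TRUE),
               collapse = "")
  a <- substr(ref, 851, 1050)
  al <- align_class(c(a, a), ref)
  expect_equal(al$rows[1L, ], al$rows[2L, ])
  occupied <- al$ref_column[which(al$rows[1L, ] > 0L)]
  expect_equal(occupied, 851:1050)
  # a planted 1-nt deletion leaves an internal gap at the deleted column
  del <- paste0(substr(ref, 851, 949), substr(ref, 951, 1050))
  al2 <- align_class(c(a, del), ref)
  gap_cols <- which(al2$rows[2L, ] == 0L &
                      seq_along(al2$ref_column) >= al2$first[2L] &
                      seq_along(al2$ref_column) <= al2$last[2L])
  expect_equal(al2$ref_column[gap_cols], 950L)
  # a planted 1-nt insertion gets its own insertion column
  ins <- paste0(substr(ref, 851, 950), "A", substr(ref, 951, 1050))
  al3 <- align_class(c(a, ins), ref)
  ins_cols <- which(is.na(al3$ref_column))
  expect_equal(length(ins_cols), 1L)
  expect_true(al3$rows[2L, ins_cols] > 0L)
  expect_equal(al3$rows[1L, ins_cols], 0L)
})

test_that("pairwise identity follows the terminal-gap and indel rules", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  # 200 comparable columns, one mismatch -> exactly 99.5 (meets threshold)
  a <- strrep("A", 200)
  b <- paste0(strrep("A", 100), "C", strrep("A", 99))
  expect_equal(pairwise_identity(a, b), 99.5)
  # 10-column 5' terminal gap, 150 comparable columns, one internal mismatch
  ra <- paste0(strrep("A", 160))
  rb <- paste0(strrep("-", 10), strrep("A", 75), "G", strrep("A", 74))
  expect_equal(pairwise_identity(ra, rb), 100 * 149 / 150)
  # an internal gap counts as one difference per column
  rc <- paste0(strrep("A", 80), "-", strrep("A", 79))
  rd <- strrep("A", 160)
  expect_equal(pairwise_identity(rc, rd), 100 * 159 / 160)
  # no overlap -> NA
  expect_true(is.na(pairwise_identity("AC--", "--GT")))
})

test_that("similarity graph applies an inclusive 99.5 threshold", {
  ident <- matrix(c(100, 99.5, 99.4,
                    99.5, 100, 98,
                    99.4, 98, 100), 3, 3)
  g <- build_similarity_graph(ident)
  el <- igraph::as_edgelist(g)
  el <- el[el[, 1L] != el[, 2L], , drop = FALSE] # drop self-loops
  expect_equal(nrow(el), 1L)
  expect_equal(sort(el[1L, ]), c(1, 2))
})

test_that("well-separated planted clusters come out exactly", {
  # clusters of radius <= 0.5% separated by >= 2%
  set.seed(21)
  base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  mut <- function(chars, k) {
    pos <- sample(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    chars
  }
  centers <- list(base, mut(base, 12), mut(mut(base, 24), 0))
  seqs <- unlist(lapply(centers, function(cc) {
    c(paste(cc, collapse = ""),
      paste(mut(cc, 1), collapse = ""),
      paste(mut(cc, 2), collapse = ""))
  }))
  al <- align_class(seqs, paste(base, collapse = ""))
  pairs <- similar_pairs(al, 99.5)
  g <- build_similarity_graph(pairs, n_nodes = 9L)
  res <- mcl_cluster(g)
  got <- lapply(res$clusters, sort)
  expect_equal(sort(vapply(got, paste, character(1), collapse = ",")),
               c("1,2,3", "4,5,6", "7,8,9"))
})

test_that("MCL handles components, singletons and weakly joined cliques", {
  # two disconnected edges -> two clusters
  ident <- matrix(0, 4, 4)
  ident[1, 2] <- ident[2, 1] <- 99.9
  ident[3, 4] <- ident[4, 3] <- 99.8
  diag(ident) <- 100
  g <- build_similarity_graph(ident)
  res <- mcl_cluster(g)
  expect_equal(sort(vapply(res$clusters, paste, character(1), collapse = ",")),
               c("1,2", "3,4"))
  # single node with self-loop -> one singleton
  g1 <- build_similarity_graph(matrix(100, 1, 1))
  expect_equal(mcl_cluster(g1)$clusters, list(1L))
  # two 4-cliques joined by one minimal-weight edge -> two clusters of 4,
  # verified against explicit matrix iteration of the 8x8 system
  A <- matrix(0, 8, 8)
  for (i in 1:4) for (j in 1:4) if (i != j) A[i, j] <- 99.9
  for (i in 5:8) for (j in 5:8) if (i != j) A[i, j] <- 99.9
  A[4, 5] <- A[5, 4] <- 99.5
  diag(A) <- 100
  g2 <- build_similarity_graph(A)
  res2 <- mcl_cluster(g2)
  expect_equal(sort(vapply(res2$clusters, paste, character(1), collapse = ",")),
               c("1,2,3,4", "5,6,7,8"))
  # independent oracle: plain-R expansion/inflation loop on the 8x8 matrix
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:200) {
    M <- M %*% M
    M <- M^1.5
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-14] <- 0
  }
  blocks <- igraph::components(igraph::graph_from_adjacency_matrix(
    (M + t(M)) > 1e-9, mode = "undirected"))$membership
  expect_equal(unname(blocks), rep(1:2, each = 4))
})

test_that("OTU assembly tracks counts, representatives and sharing", {
  reads <- mk_reads(c("ACGTACGTAA", "ACGTACGT", "TTTTACGTAC", "TTTTACGTAC",
                      "GGGGGGGGGG"),
                    samples = c("s1", "s2", "s1", "s1", "s2"))
  types <- dereplicate(reads)
  # cluster manually: types 1+2 together (they are one type after prefix
  # merging), others apart
  n <- length(types$sequence)
  clusters <- as.list(seq_len(n))
  otus <- make_otus(clusters, types)
  expect_equal(sum(otus$counts), 5L)
  expect_equal(otus$info$representative[otus$info$n_reads == 2L &
                                          otus$info$shared],
               "ACGTACGTAA")
  parts <- partition_otus(otus)
  expect_true(all(rowSums(parts$shared$counts > 0) >= 2L))
  expect_true(all(rowSums(parts$unique$counts > 0) == 1L))
  # {s1: 5} -> unique; {s1: 1, s2: 1} -> shared
  cm <- matrix(c(5L, 0L, 1L, 1L), 2, 2, byrow = TRUE,
               dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2")))
  o2 <- structure(list(counts = cm,
                       info = data.frame(otu_id = rownames(cm), class = "C",
                                         representative = "A", n_reads = c(5L, 2L),
                                         shared = rowSums(cm > 0) >= 2),
                       members = list(1L, 2L)), class = "otu_set")
  p2 <- partition_otus(o2)
  expect_equal(rownames(p2$unique$counts), "OTU_1")
  expect_equal(rownames(p2$shared$counts), "OTU_2")
})

test_that("error-free clustering reproduces the planted OTU occupancy", {
  ds <- clean_dataset()
  qc <- clean_qc()
  otus <- cluster_otus(qc$kept, ds$references)
  # read conservation
  expect_equal(sum(otus$counts), nrow(qc$kept))
  # ground-truth occupancy of kept reads by true OTU
  gt <- ds$ground_truth
  truth <- table(gt$read_to_otu[qc$kept$read_id], qc$kept$sample_id)
  expect_equal(nrow(otus$counts), nrow(truth))
  # per-OTU per-sample counts match after aligning OTU identities by
  # representative sequence
  refs <- setNames(ds$references$sequence, ds$references$taxon_id)
  rep_otu <- vapply(otus$info$representative, function(s) {
    names(refs)[vapply(refs, function(r) grepl(s, r, fixed = TRUE),
                       logical(1))][1L]
  }, character(1))
  got <- otus$counts
  rownames(got) <- rep_otu
  got <- got[rownames(truth), colnames(truth)]
  expect_equal(unclass(got), unclass(as.matrix(truth)),
               ignore_attr = TRUE)
  # shared/unique tallies match ground truth
  expect_equal(sum(otus$info$shared),
               sum(rowSums(truth > 0) >= 2L))
})

test_that("clustering does not depend on type input order", {
  set.seed(77)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  mut1 <- function(cc) {
    p <- sample(300, 1)
    cc[p] <- sample(setdiff(c("A", "C", "G", "T"), cc[p]), 1)
    paste(cc, collapse = "")
  }
  far <- base
  far[sample(300, 20)] <- "T"
  seqs <- c(paste(base, collapse = ""), mut1(base), mut1(base),
            paste(far, collapse = ""), mut1(far))
  ref <- paste(base, collapse = "")
  run <- function(ord) {
    al <- align_class(seqs[ord], ref)
    g <- build_similarity_graph(similar_pairs(al, 99.5),
                                n_nodes = length(ord))
    cl <- mcl_cluster(g)$clusters
    sort(vapply(cl, function(ix) paste(sort(ord[ix]), collapse = ","),
                character(1)))
  }
  base_part <- run(1:5)
  for (perm in list(5:1, c(3, 1, 5, 2, 4))) {
    expect_equal(run(perm), base_part)
  }
})

test_that("lowering the threshold never increases the cluster count", {
  set.seed(5)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  seqs <- vapply(1:8, function(i) {
    v <- base
    pos <- sample(300, i)
    v[pos] <- "A"
    paste(v, collapse = "")
  }, character(1))
  al <- align_class(seqs, paste(base, collapse = ""))
  prev <- Inf
  for (thr in c(100, 99.7, 99.5, 99, 98)) {
    pairs <- similar_pairs(al, thr)
    g <- build_similarity_graph(pairs, n_nodes = 8L, threshold = thr)
    k <- length(mcl_cluster(g)$clusters)
    expect_lte(k, prev)
    prev <- k
  }
})
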