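#' Dereplicate reads into unique sequence types
#'
#' Reads that are identical after truncating the longer to the shorter's
#' length are merged into one unique type whose canonical sequence is the
#' longest member. (In the sorted sequence list, a read that is a prefix of
#' its lexicographic successor is merged into the successor's type, applied
#' transitively; any sequence lexicographically between a prefix and its
#' extension necessarily shares that prefix.) Multiplicities are tracked per
#' sample.
#'
#' @param reads data.frame with `read_id`, `sequence`, `sample_id`, and
#'   optionally `class` (carried onto types).
#' @return a `seq_types` object: list with `sequence` (canonical, one per
#'   type), `class`, `counts` (types x samples integer matrix), `members`
#'   (list of read-id vectors), `longest_read` (the longest member read's
#'   sequence, = canonical).
#' @export
dereplicate <- function(reads) {
  stopifnot(nrow(reads) > 0L)
  us <- sort(unique(reads$sequence))
  n <- length(us)
  group <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (startsWith(us[i + 1L], us[i])) group[i] <- i + 1L
    }
    # path-compress the chains (rightmost element is the longest extension)
    for (i in seq(n - 1L, 1L)) group[i] <- group[group[i]]
  }
  gid <- match(group, sort(unique(group)))
  canon <- us[sort(unique(group))]
  read_type <- gid[match(reads$sequence, us)]
  samples <- sort(unique(reads$sample_id))
  counts <- matrix(0L, length(canon), length(samples),
                   dimnames = list(NULL, samples))
  tab <- table(read_type, reads$sample_id)
  counts[as.integer(rownames(tab)), colnames(tab)] <- as.integer(tab)
  members <- split(reads$read_id, read_type)
  cls <- if (!is.null(reads$class)) {
    vapply(split(reads$class, read_type), function(x) x[1L], character(1))
  } else rep(NA_character_, length(canon))
  structure(list(sequence = canon, class = unname(cls), counts = counts,
                 members = unname(members)),
            class = "seq_types")
}

ALIGN_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

#' Reference-guided multiple alignment of unique types within a class
#'
#' Each type is aligned pairwise (semi-globally) to the class representative;
#' rows are merged by reference coordinates, with insertions relative to the
#' reference stacked in dedicated insertion columns. Types whose alignment
#' score falls below the floor are flagged and excluded.
#'
#' @param types a `seq_types` object (all of one class) or a character vector
#'   of sequences.
#' @param class_reference the class representative sequence.
#' @param min_score_frac alignment score floor (fraction of type length).
#' @return list with `rows` (types x columns integer matrix, 0 = gap),
#'   `first`/`last` (per-row non-terminal-gap span), `ref_column` (reference
#'   position of each master column, NA for insertion columns), and
#'   `excluded` (indices of unalignable types).
#' @export
align_class <- function(types, class_reference, min_score_frac = 0.4) {
  seqs <- if (inherits(types, "seq_types")) types$sequence else types
  n <- length(seqs)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(class_reference),
    type = "global-local", substitutionMatrix = submat,
    gapOpening = 2, gapExtension = 1)
  ok <- Biostrings::score(aln) >= min_score_frac * nchar(seqs)
  pat <- as.character(Biostrings::pattern(aln))
  sbj <- as.character(Biostrings::subject(aln))
  sstart <- Biostrings::start(Biostrings::subject(aln))
  L <- nchar(class_reference)
  # per-type parse: reference position of every alignment column
  parsed <- vector("list", n)
  ins_width <- integer(L + 1L) # insertions *after* ref position r (0 = before 1)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    pv <- strsplit(pat[i], "", fixed = TRUE)[[1L]]
    sv <- strsplit(sbj[i], "", fixed = TRUE)[[1L]]
    refpos <- sstart[i] - 1L + cumsum(sv != "-")
    is_ins <- sv == "-"
    if (any(is_ins)) {
      runs <- rle(is_ins)
      ends <- cumsum(runs$lengths)
      for (rr in which(runs$values)) {
        at <- refpos[ends[rr]] # position after which the insertion sits
        ins_width[at + 1L] <- max(ins_width[at + 1L], runs$lengths[rr])
      }
    }
    parsed[[i]] <- list(pv = pv, refpos = refpos, is_ins = is_ins)
  }
  # master columns: for each ref position, its column, preceded by any
  # insertion block after the previous position
  offset <- integer(L + 1L)
  total <- 0L
  ref_column <- rep(NA_integer_, L + sum(ins_width))
  col_of_ref <- integer(L)
  pos <- 0L
  for (r in seq_len(L)) {
    pos <- pos + ins_width[r] # insertion block after position r-1
    pos <- pos + 1L
    col_of_ref[r] <- pos
    ref_column[pos] <- r
  }
  n_cols <- pos + ins_width[L + 1L]
  ref_column <- ref_column[seq_len(n_cols)]
  rows <- matrix(0L, n, n_cols)
  first <- rep(NA_integer_, n)
  last <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- parsed[[i]]
    if (is.null(p)) next
    code <- unname(ALIGN_CODE[p$pv])
    code[p$pv == "-"] <- 0L
    cols <- integer(length(p$pv))
    cols[!p$is_ins] <- col_of_ref[p$refpos[!p$is_ins]]
    if (any(p$is_ins)) {
      runs <- rle(p$is_ins)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (rr in which(runs$values)) {
        at <- p$refpos[ends[rr]]
        base_col <- if (at == 0L) 0L else col_of_ref[at]
        cols[starts[rr]:ends[rr]] <- base_col + seq_len(runs$lengths[rr])
      }
    }
    valid <- cols > 0L & code > 0L
    rows[i, cols[valid]] <- code[valid]
    nz <- which(rows[i, ] > 0L)
    first[i] <- nz[1L]
    last[i] <- nz[length(nz)]
  }
  list(rows = rows, first = first, last = last, ref_column = ref_column,
       excluded = which(!ok))
}

#' Percent identity between two alignment rows
#'
#' Columns inside either row's terminal-gap runs are excluded; columns where
#' both rows are gapped are not compared; a column where exactly one row has
#' an (internal) gap counts as one difference.
#'
#' @param row_a,row_b aligned sequences as character strings with `-` gaps,
#'   or integer-coded vectors (0 = gap).
#' @return percent identity, or `NA` if the rows share no comparable column.
#' @export
pairwise_identity <- function(row_a, row_b) {
  conv <- function(r) {
    if (is.character(r)) {
      v <- strsplit(r, "", fixed = TRUE)[[1L]]
      out <- unname(ALIGN_CODE[v])
      out[v == "-" | is.na(out)] <- 0L
      out
    } else as.integer(r)
  }
  a <- conv(row_a)
  b <- conv(row_b)
  stopifnot(length(a) == length(b))
  nz_a <- which(a > 0L)
  nz_b <- which(b > 0L)
  if (!length(nz_a) || !length(nz_b)) return(NA_real_)
  res <- .identity_one_cpp(a, b, nz_a[1L], nz_a[length(nz_a)],
                           nz_b[1L], nz_b[length(nz_b)])
  res[1L]
}

#' All within-class type pairs at or above an identity threshold
#'
#' @param alignment result of [align_class()].
#' @param threshold percent identity cutoff (inclusive).
#' @return data.frame `i`, `j`, `identity` (1-based type indices).
#' @export
similar_pairs <- function(alignment, threshold = 99.5) {
  first <- alignment$first
  last <- alignment$last
  excl <- is.na(first)
  first[excl] <- 1L
  last[excl] <- 0L # empty span: never compared
  res <- .identity_pairs_cpp(alignment$rows, first, last, threshold)
  data.frame(i = res$i, j = res$j, identity = res$identity)
}

#' Build the similarity graph over unique types
#'
#' Nodes are unique types weighted by multiplicity; an undirected edge joins
#' two types iff their identity is at or above the threshold (edge weight =
#' identity); every node carries a self-loop of weight 100.
#'
#' @param identities either a square identity matrix (NA = no overlap) or a
#'   data.frame `i`, `j`, `identity` as from [similar_pairs()].
#' @param n_nodes number of types (required with the data.frame form).
#' @param multiplicities per-type read counts (node weight attribute).
#' @param threshold percent identity threshold (inclusive, default 99.5).
#' @return an [igraph::graph] with edge attribute `weight` and vertex
#'   attribute `multiplicity`.
#' @export
build_similarity_graph <- function(identities, n_nodes = NULL,
                                   multiplicities = NULL, threshold = 99.5) {
  if (is.matrix(identities)) {
    n_nodes <- nrow(identities)
    idx <- which(upper.tri(identities) & !is.na(identities) &
                   identities >= threshold, arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1L], j = idx[, 2L],
                        identity = identities[idx])
  } else {
    stopifnot(!is.null(n_nodes))
    pairs <- identities[identities$identity >= threshold, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  ev <- c(rbind(pairs$i, pairs$j), rbind(seq_len(n_nodes), seq_len(n_nodes)))
  g <- igraph::add_edges(g, ev,
                         weight = c(pairs$identity, rep(100, n_nodes)))
  if (is.null(multiplicities)) multiplicities <- rep(1L, n_nodes)
  igraph::V(g)$multiplicity <- multiplicities
  g
}

# MCL iteration on one connected component's weighted adjacency matrix.
# Small components iterate densely with minimal pruning. Large components
# (abundant OTUs accumulate hundreds of one-error satellite types) use
# MCL-style pruning of vanishing flow entries and switch from dense (BLAS)
# to sparse products once the flow matrix has become nearly block diagonal;
# the attractor structure that the clusters are read from is unaffected.
mcl_component <- function(A, inflation, expansion, max_iter, tol,
                          big_from = 64L, big_prune = 1e-5) {
  n <- nrow(A)
  prune <- if (n > big_from) big_prune else 1e-12
  col_scale_dense <- function(M) M / rep(colSums(M), each = nrow(M))
  col_scale_sparse <- function(M) {
    cs <- Matrix::colSums(M)
    M@x <- M@x / rep.int(cs, diff(M@p))
    M
  }
  M <- col_scale_dense(A)
  sparse <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    if (sparse) {
      Minf <- Mexp
      Minf@x <- Minf@x^inflation
      Minf <- col_scale_sparse(Minf)
      Minf <- Matrix::drop0(Minf, tol = prune)
      delta <- max(abs(Minf - M))
    } else {
      Minf <- Mexp^inflation
      Minf <- col_scale_dense(Minf)
      Minf[Minf < prune] <- 0
      delta <- max(abs(Minf - M))
      if (n > big_from && mean(Minf > 0) < 0.05) {
        Minf <- Matrix::Matrix(Minf, sparse = TRUE)
        sparse <- TRUE
      }
    }
    M <- Minf
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(M = M, converged = converged)
}

#' Markov clustering (MCL) of the similarity graph
#'
#' The column-stochastic transition matrix of each connected component is
#' iterated by expansion (matrix power) and inflation (elementwise power with
#' column renormalization) until the maximum column change falls below `tol`
#' or `max_iter` is reached. Clusters are read off the attractor structure of
#' the limit matrix; a node attracted to more than one cluster joins the
#' cluster holding the largest share of its column mass (ties: smallest node
#' id). Components can never merge, so MCL runs per component.
#'
#' @param graph an [igraph::graph] from [build_similarity_graph()].
#' @param inflation inflation exponent (default 1.5).
#' @param expansion expansion power (default 2).
#' @param max_iter,tol convergence controls.
#' @return list with `clusters` (list of vertex-index vectors) and
#'   `converged` (FALSE if any component hit `max_iter`; clusters are then
#'   the current interpretation).
#' @export
mcl_cluster <- function(graph, inflation = 1.5, expansion = 2L,
                        max_iter = 100L, tol = 1e-6) {
  stopifnot(igraph::vcount(graph) > 0L)
  comp <- igraph::components(graph)
  adj <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  clusters <- list()
  all_converged <- TRUE
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    if (length(verts) == 1L) {
      clusters[[length(clusters) + 1L]] <- verts
      next
    }
    A <- as.matrix(adj[verts, verts, drop = FALSE])
    diag(A) <- pmax(diag(A), 100)
    res <- mcl_component(A, inflation, expansion, max_iter, tol)
    all_converged <- all_converged && res$converged
    M <- as.matrix(res$M)
    nz <- (M + t(M)) > 1e-9
    sg <- igraph::graph_from_adjacency_matrix(nz, mode = "undirected")
    mem <- igraph::components(sg)$membership
    # resolve columns whose mass is split across attractor groups: the
    # column joins the group holding most of its mass (ties: smallest group
    # id, i.e. the group containing the smallest node id)
    mass <- rowsum(M, group = mem)
    split_col <- colSums(mass > 1e-9) > 1L
    if (any(split_col)) {
      grp_ids <- sort(unique(mem))
      mem[split_col] <- grp_ids[max.col(t(mass[, split_col, drop = FALSE]),
                                        ties.method = "first")]
    }
    for (g in sort(unique(mem))) {
      clusters[[length(clusters) + 1L]] <- verts[mem == g]
    }
  }
  if (!all_converged) {
    warning("MCL did not converge on every component within max_iter")
  }
  list(clusters = clusters, converged = all_converged)
}

#' Assemble OTUs from clusters of unique types
#'
#' One OTU per cluster: per-sample read counts are the summed type
#' multiplicities; the representative is the longest member read's sequence
#' (ties broken lexicographically); the class label is inherited from the
#' member types.
#'
#' @param clusters list of type-index vectors from [mcl_cluster()].
#' @param types the `seq_types` the clusters index into.
#' @return an `otu_set`: list with `counts` (OTUs x samples), `info`
#'   (data.frame: otu_id, class, representative, n_reads, shared), `members`
#'   (type indices per OTU).
#' @export
make_otus <- function(clusters, types) {
  n <- length(clusters)
  counts <- matrix(0L, n, ncol(types$counts),
                   dimnames = list(sprintf("OTU_%05d", seq_len(n)),
                                   colnames(types$counts)))
  rep_seq <- character(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    idx <- clusters[[i]]
    counts[i, ] <- colSums(types$counts[idx, , drop = FALSE])
    cand <- types$sequence[idx]
    cand <- cand[order(-nchar(cand), cand)]
    rep_seq[i] <- cand[1L]
    cls[i] <- types$class[idx[1L]]
  }
  shared <- rowSums(counts > 0L) >= 2L
  structure(list(
    counts = counts,
    info = data.frame(otu_id = rownames(counts), class = cls,
                      representative = rep_seq,
                      n_reads = rowSums(counts), shared = shared),
    members = clusters), class = "otu_set")
}

#' Partition OTUs into shared and unique sets
#'
#' Shared OTUs are detected in two or more host samples; unique OTUs occur in
#' exactly one. Only shared OTUs are phylogenetically informative and enter
#' the character matrix.
#'
#' @param otus an `otu_set` from [make_otus()].
#' @return list of two `otu_set`s: `shared` and `unique`.
#' @export
partition_otus <- function(otus) {
  sel <- function(keep) {
    structure(list(counts = otus$counts[keep, , drop = FALSE],
                   info = otus$info[keep, , drop = FALSE],
                   members = otus$members[keep]), class = "otu_set")
  }
  list(shared = sel(otus$info$shared), unique = sel(!otus$info$shared))
}
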