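#' Ordered-state transition costs
#'
#' Cost matrix for ordered (Wagner) parsimony on `n_states` linearly ordered
#' states: `cost(i, j) = |i - j|`, so transitions between distant abundance
#' states are proportionally more costly than between adjacent ones.
#'
#' @param n_states number of ordered states (default 6, states 0-5).
#' @return an `n_states` x `n_states` numeric cost matrix.
#' @export
ordered_costs <- function(n_states = 6L) {
  s <- seq_len(n_states) - 1L
  abs(outer(s, s, "-"))
}

validate_costs <- function(costs) {
  if (!is.matrix(costs) || nrow(costs) != ncol(costs)) {
    stop("costs must be a square matrix")
  }
  if (any(costs < 0)) stop("costs must be non-negative")
  if (any(diag(costs) != 0)) stop("cost diagonal must be zero")
  if (!isTRUE(all.equal(costs, t(costs)))) stop("costs must be symmetric")
  n <- nrow(costs)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (any(costs[i, j] > costs[i, ] + costs[, j] + 1e-12)) {
        stop("cost matrix violates the triangle inequality")
      }
    }
  }
  invisible(costs)
}

# Coerce a samples x characters state matrix, checking states against costs.
as_state_matrix <- function(matrix, costs) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) stop("character matrix must have sample rownames")
  if (any(m < 0L) || any(m >= nrow(costs))) {
    stop("character states outside 0..", nrow(costs) - 1L)
  }
  m
}

# Resolve a tree argument (ape phylo or edge matrix) against matrix rows.
resolve_tree <- function(tree, m) {
  labels <- rownames(m)
  if (inherits(tree, "phylo")) {
    if (!setequal(tree$tip.label, labels)) {
      stop("tree tips and matrix samples differ")
    }
    phylo_to_utree(tree, labels)
  } else {
    tree
  }
}

#' Parsimony score of a tree (Sankoff dynamic programming)
#'
#' Minimum total transition cost of all characters on an unrooted tree: the
#' tree is rooted at an arbitrary internal node and scored bottom-up by the
#' Sankoff algorithm; the result does not depend on the rooting.
#'
#' @param tree an [ape::phylo] tree whose tips are the matrix's samples.
#' @param matrix integer matrix, samples x characters, states `0..5` (rownames
#'   are sample ids).
#' @param costs transition cost matrix, default [ordered_costs()].
#' @return the parsimony score (p-score), a single number.
#' @export
sankoff_score <- function(tree, matrix, costs = ordered_costs()) {
  validate_costs(costs)
  m <- as_state_matrix(matrix, costs)
  if (inherits(tree, "phylo") && length(tree$tip.label) == 2L) {
    i <- match(tree$tip.label, rownames(m))
    return(sum(costs[cbind(m[i[1L], ] + 1L, m[i[2L], ] + 1L)]))
  }
  edge <- resolve_tree(tree, m)
  utree_score(edge, m, costs)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all `(2n-5)!!` unrooted binary topologies on the matrix samples
#' and returns every topology attaining the minimum Sankoff score. Serves as
#' the exact oracle for [heuristic_search()] at small sample counts.
#'
#' @inheritParams sankoff_score
#' @param max_taxa refuse to enumerate above this many samples (default 9).
#' @return a list with elements `score`, `trees` (list of [ape::phylo]),
#'   and `n_scored` (number of topologies evaluated).
#' @export
exhaustive_search <- function(matrix, costs = ordered_costs(), max_taxa = 9L) {
  validate_costs(costs)
  m <- as_state_matrix(matrix, costs)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 samples")
  if (n > max_taxa) {
    stop("too many samples for exhaustive enumeration; use heuristic_search()")
  }
  env <- new.env()
  env$best <- Inf
  env$trees <- list()
  env$n <- 0L
  enumerate_utrees(seq_len(n), n, function(edge) {
    sc <- utree_score(edge, m, costs)
    env$n <- env$n + 1L
    if (sc < env$best - 1e-9) {
      env$best <- sc
      env$trees <- list(edge)
    } else if (sc < env$best + 1e-9) {
      env$trees[[length(env$trees) + 1L]] <- edge
    }
  })
  list(score = env$best,
       trees = lapply(env$trees, utree_to_phylo, n_tips = n,
                      labels = rownames(m)),
       n_scored = env$n)
}

# One stepwise-addition start plus hill-climbing. Returns list(edge, score,
# moves). Deterministic given the addition order.
climb_one <- function(m, costs, order, rearrangement) {
  n <- nrow(m)
  edge <- utree_start(order[1:3], n + 1L)
  next_internal <- n + 2L
  for (i in seq(4L, length.out = n - 3L)) {
    cand <- lapply(seq_len(nrow(edge)), function(r) {
      utree_insert(edge, r, order[i], next_internal)
    })
    scores <- vapply(cand, utree_score, numeric(1), states = m, costs = costs)
    edge <- cand[[which.min(scores)]]
    next_internal <- next_internal + 1L
  }
  score <- utree_score(edge, m, costs)
  moves <- 0L
  neighbor_fun <- if (rearrangement == "SPR") spr_neighbors else nni_neighbors
  repeat {
    nb <- neighbor_fun(edge, n)
    if (!length(nb)) break
    scores <- vapply(nb, utree_score, numeric(1), states = m, costs = costs)
    moves <- moves + length(nb)
    if (min(scores) < score - 1e-9) {
      edge <- nb[[which.min(scores)]]
      score <- min(scores)
    } else {
      break
    }
  }
  list(edge = edge, score = score, moves = moves)
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition stepwise insertion builds each starting tree; the tree is
#' then improved by NNI or SPR rearrangements until no move lowers the Sankoff
#' score. Distinct best topologies found across starts are all returned.
#'
#' @inheritParams sankoff_score
#' @param n_starts number of random-addition starting trees.
#' @param rearrangement `"SPR"` (default) or `"NNI"`.
#' @param seed integer seed controlling the random addition orders.
#' @return a list with `score`, `trees` (distinct best topologies as
#'   [ape::phylo]), `n_rearrangements`, and `seed`.
#' @export
heuristic_search <- function(matrix, costs = ordered_costs(), n_starts = 10L,
                             rearrangement = c("SPR", "NNI"), seed = 1L) {
  rearrangement <- match.arg(rearrangement)
  validate_costs(costs)
  m <- as_state_matrix(matrix, costs)
  n <- nrow(m)
  if (n < 4L) {
    res <- exhaustive_search(matrix, costs)
    return(list(score = res$score, trees = res$trees,
                n_rearrangements = 0L, seed = seed))
  }
  labels <- rownames(m)
  best <- Inf
  found <- list() # canonical key -> edge
  moves <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    order <- sample.int(n)
    res <- climb_one(m, costs, order, rearrangement)
    moves <- moves + res$moves
    if (res$score < best - 1e-9) {
      best <- res$score
      found <- list()
    }
    if (res$score < best + 1e-9) {
      key <- utree_key(res$edge, n, labels)
      if (is.null(found[[key]])) found[[key]] <- res$edge
    }
  }
  list(score = best,
       trees = lapply(found, utree_to_phylo, n_tips = n, labels = labels),
       n_rearrangements = moves, seed = seed)
}

#' Bootstrap support for parsimony trees
#'
#' Each pseudo-replicate resamples characters (columns) with replacement to
#' the original character count, reruns the heuristic search, and tallies the
#' bipartitions of one best tree per replicate (ties broken by the smallest
#' canonical topology key). Support is the percentage of replicates containing
#' a bipartition; the majority-rule consensus carries supports as node labels.
#'
#' @inheritParams heuristic_search
#' @param n_reps number of pseudo-replicates (default 1000).
#' @param n_starts random-addition starts per replicate search.
#' @return a list with `support` (named percent vector keyed by bipartition;
#'   see [clade_support()]), `consensus` (majority-rule [ape::phylo] with node
#'   labels giving support), `n_reps`, and `seed`.
#' @export
bootstrap_parsimony <- function(matrix, costs = ordered_costs(),
                                n_reps = 1000L, n_starts = 2L,
                                rearrangement = c("SPR", "NNI"), seed = 1L) {
  rearrangement <- match.arg(rearrangement)
  if (n_reps < 1L) stop("n_reps must be at least 1")
  validate_costs(costs)
  m <- as_state_matrix(matrix, costs)
  n <- nrow(m)
  labels <- rownames(m)
  tally <- new.env()
  rep_trees <- vector("list", n_reps)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mr <- m[, cols, drop = FALSE]
    res <- heuristic_search(mr, costs, n_starts = n_starts,
                            rearrangement = rearrangement,
                            seed = rep_seeds[r])
    # one tree per replicate; ties resolved by a draw from the replicate's
    # own RNG stream (deterministic under the bootstrap seed), so an
    # uninformative matrix yields scattered, unsupported bipartitions
    pick <- if (length(res$trees) == 1L) res$trees[[1L]] else
      res$trees[[sample.int(length(res$trees), 1L)]]
    rep_trees[[r]] <- pick
    for (k in utree_bipartitions(phylo_to_utree(pick, labels), n, labels)) {
      tally[[k]] <- (if (is.null(tally[[k]])) 0L else tally[[k]]) + 1L
    }
  }
  keys <- ls(tally)
  support <- setNames(
    vapply(keys, function(k) 100 * tally[[k]] / n_reps, numeric(1)), keys)
  class(rep_trees) <- "multiPhylo"
  cons <- ape::consensus(rep_trees, p = 0.5)
  cons <- label_supports(cons, support, labels)
  list(support = support, consensus = cons, n_reps = n_reps, seed = seed)
}

# Attach support percentages as node labels of a consensus tree.
label_supports <- function(cons, support, labels) {
  n <- length(cons$tip.label)
  nl <- rep("", cons$Nnode)
  sides <- prop_part_sides(cons)
  for (i in seq_along(sides)) {
    if (length(sides[[i]]) %in% c(1L, n)) next
    k <- split_key(cons$tip.label[sides[[i]]], labels)
    if (!is.na(support[k])) nl[i] <- format(round(support[k], 1))
  }
  cons$node.label <- nl
  cons
}

# Tip index sets descending from each internal node of a phylo tree.
prop_part_sides <- function(phy) {
  n <- length(phy$tip.label)
  res <- vector("list", phy$Nnode)
  post <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (r in seq_len(nrow(post$edge))) {
    p <- post$edge[r, 1L]; ch <- post$edge[r, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  for (v in seq_len(phy$Nnode)) res[[v]] <- sort(sets[[n + v]])
  res
}

#' Support for one clade (leaf set) in a bootstrap result
#'
#' @param boot result of [bootstrap_parsimony()].
#' @param tips character vector of tip labels forming the clade (in the
#'   unrooted sense: the bipartition separating them from everything else).
#' @param labels all tip labels of the analysis.
#' @return support percentage (0 if the bipartition was never observed).
#' @export
clade_support <- function(boot, tips, labels) {
  k <- split_key(tips, labels)
  s <- boot$support[k]
  if (is.na(s)) 0 else unname(s)
}

#' Assign parsimony branch lengths
#'
#' Branch length = total minimum-cost changes assigned to the branch, summed
#' over characters, under a deterministic Sankoff backtrace (ties resolved
#' toward the lowest-index state). Lengths sum exactly to the p-score.
#'
#' @inheritParams sankoff_score
#' @return `tree` with `edge.length` set to per-branch change totals.
#' @export
assign_branch_lengths <- function(tree, matrix, costs = ordered_costs()) {
  validate_costs(costs)
  m <- as_state_matrix(matrix, costs)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  phy <- if (length(tree$tip.label) > 2L && ape::is.rooted(tree)) {
    ape::unroot(tree)
  } else {
    tree
  }
  labels <- rownames(m)
  n <- length(phy$tip.label)
  edge <- phylo_to_utree(phy, labels)
  n_nodes <- max(edge)
  tip_row <- integer(n_nodes)
  tip_row[seq_len(n)] <- seq_len(n)
  root <- max(edge)
  changes <- .sankoff_branch_changes_cpp(edge, n_nodes, root, tip_row, m, costs)
  # map back to phy$edge rows: row r of `edge` derives from phy$edge row r
  phy$edge.length <- as.numeric(changes)
  phy
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so that all
#' tree I/O in the pipeline goes through one audited path. `read_newick`
#' accepts a file path or a literal Newick string.
#'
#' @param text Newick string or path to a Newick file.
#' @return `read_newick`: an [ape::phylo]; `write_newick`: a Newick string
#'   (invisibly, after writing when `file` is given).
#' @export
read_newick <- function(text) {
  tr <- if (file.exists(text)) {
    ape::read.tree(text)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("malformed Newick input")
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @param file optional path to write to.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
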