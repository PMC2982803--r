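# Internal unrooted-tree machinery used by the parsimony engine.
#
# Trees are plain integer edge matrices (two columns, unordered rows). Tip
# nodes are 1..n and double as row indices into the character matrix; internal
# nodes are numbered above n. All trees handled here are unrooted and binary
# (every internal node has degree three).

# Starting 3-leaf star: one internal node joined to three tips.
utree_start <- function(tips, internal_id) {
  cbind(rep(internal_id, 3L), as.integer(tips))
}

# Insert a new tip on edge row `row`: the edge (a,b) is subdivided by
# `new_internal` and the tip attached there.
utree_insert <- function(edge, row, tip, new_internal) {
  a <- edge[row, 1L]
  b <- edge[row, 2L]
  edge[row, ] <- c(a, new_internal)
  rbind(edge, c(new_internal, b), c(new_internal, tip))
}

# Score an edge-matrix tree against an integer state matrix (rows = tips in
# node-id order) under a transition cost matrix.
utree_score <- function(edge, states, costs) {
  n_nodes <- max(edge)
  n_tips <- nrow(states)
  tip_row <- integer(n_nodes)
  present <- unique(as.integer(edge[edge <= n_tips]))
  tip_row[present] <- present
  root <- max(edge) # internal nodes are numbered above all tips
  .sankoff_total_cpp(edge, n_nodes, root, tip_row, states, costs)
}

# Enumerate all unrooted binary topologies on the given tips by sequential
# insertion, invoking `fun(edge)` for each complete topology.
enumerate_utrees <- function(tips, n_tips_total, fun) {
  tips <- as.integer(tips)
  k <- length(tips)
  if (k < 3L) stop("need at least 3 tips to enumerate topologies")
  recurse <- function(edge, i, next_internal) {
    if (i > k) {
      fun(edge)
      return(invisible(NULL))
    }
    for (row in seq_len(nrow(edge))) {
      recurse(utree_insert(edge, row, tips[i], next_internal), i + 1L,
              next_internal + 1L)
    }
    invisible(NULL)
  }
  recurse(utree_start(tips[1:3], n_tips_total + 1L), 4L, n_tips_total + 2L)
}

# Tip set on the `child` side of each edge, as a list of integer vectors.
edge_tip_sides <- function(edge, n_tips) {
  n_nodes <- max(edge)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  collect <- function(start, blocked) {
    seen <- integer(0)
    stack <- start
    prev <- c(blocked)
    visited <- logical(n_nodes)
    visited[blocked] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (visited[v]) next
      visited[v] <- TRUE
      if (v <= n_tips) seen <- c(seen, v)
      stack <- c(stack, adj[[v]])
    }
    sort(seen)
  }
  lapply(seq_len(nrow(edge)), function(i) {
    collect(edge[i, 2L], edge[i, 1L])
  })
}

# Canonical key of one bipartition: the tip-label set on the side not
# containing the reference label, sorted and joined by "|".
split_key <- function(side_labels, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side_labels) {
    side_labels <- setdiff(all_labels, side_labels)
  }
  paste(sort(side_labels), collapse = "|")
}

# Non-trivial bipartition keys of an unrooted tree given tip labels indexed by
# tip id. Returns a character vector (one per internal edge), with the source
# edge row recorded in the "edge_row" attribute.
utree_bipartitions <- function(edge, n_tips, labels) {
  sides <- edge_tip_sides(edge, n_tips)
  keep <- vapply(sides, function(s) {
    length(s) >= 2L && length(s) <= n_tips - 2L
  }, logical(1))
  keys <- vapply(which(keep), function(i) {
    split_key(labels[sides[[i]]], labels)
  }, character(1))
  attr(keys, "edge_row") <- which(keep)
  keys
}

# Canonical topology identifier (label-based, rooting-independent).
utree_key <- function(edge, n_tips, labels) {
  paste(sort(utree_bipartitions(edge, n_tips, labels)), collapse = ";")
}

# All NNI neighbours: for every internal edge (u,v), exchange one subtree of u
# with one subtree of v (two exchanges per internal edge).
nni_neighbors <- function(edge, n_tips) {
  out <- list()
  internal <- edge[, 1L] > n_tips & edge[, 2L] > n_tips
  for (i in which(internal)) {
    u <- edge[i, 1L]; v <- edge[i, 2L]
    u_rows <- setdiff(which(edge[, 1L] == u | edge[, 2L] == u), i)
    v_rows <- setdiff(which(edge[, 1L] == v | edge[, 2L] == v), i)
    ur <- u_rows[1L]
    for (vr in v_rows) {
      e2 <- edge
      # swap the far endpoints of rows ur and vr
      a <- if (e2[ur, 1L] == u) 2L else 1L
      b <- if (e2[vr, 1L] == v) 2L else 1L
      tmp <- e2[ur, a]
      e2[ur, a] <- e2[vr, b]
      e2[vr, b] <- tmp
      out[[length(out) + 1L]] <- e2
    }
    ur <- u_rows[2L]
    for (vr in v_rows) {
      e2 <- edge
      a <- if (e2[ur, 1L] == u) 2L else 1L
      b <- if (e2[vr, 1L] == v) 2L else 1L
      tmp <- e2[ur, a]
      e2[ur, a] <- e2[vr, b]
      e2[vr, b] <- tmp
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

# All SPR neighbours: prune the subtree on the far side of each edge whose
# near endpoint is internal, suppress the near endpoint, and regraft on every
# edge of the remaining tree not incident to the suppressed node.
spr_neighbors <- function(edge, n_tips) {
  out <- list()
  n_edges <- nrow(edge)
  for (i in seq_len(n_edges)) {
    for (dir in 1:2) {
      u <- edge[i, dir]              # kept side; must be internal
      v <- edge[i, 3L - dir]         # pruned subtree root
      if (u <= n_tips) next
      u_rows <- setdiff(which(edge[, 1L] == u | edge[, 2L] == u), i)
      # endpoints of u's two other edges
      ends <- vapply(u_rows, function(r) {
        if (edge[r, 1L] == u) edge[r, 2L] else edge[r, 1L]
      }, integer(1))
      # prune: drop edge i and u's rows, add (ends[1], ends[2])
      base <- edge[-c(i, u_rows), , drop = FALSE]
      bridge <- c(ends[1L], ends[2L])
      pruned <- rbind(base, bridge)
      # nodes on the pruned-subtree side (reachable from v in `pruned`?
      # the subtree rows are inside `base`; identify via reachability from v)
      sub_nodes <- reachable_nodes(base, v)
      for (r in seq_len(nrow(pruned))) {
        a <- pruned[r, 1L]; b <- pruned[r, 2L]
        if (a %in% sub_nodes || b %in% sub_nodes) next
        # skip regrafting onto the bridge's own position when it recreates
        # the original tree: regrafting on the bridge re-makes the source.
        if (r == nrow(pruned)) next
        e2 <- pruned
        e2[r, ] <- c(a, u)
        e2 <- rbind(e2, c(u, b), c(u, v))
        out[[length(out) + 1L]] <- e2
      }
      # regrafting on the bridge edge itself is also a valid SPR target but
      # reproduces the original topology, so it is intentionally skipped.
    }
  }
  out
}

# Nodes reachable from `start` in an edge list.
reachable_nodes <- function(edge, start) {
  if (nrow(edge) == 0L) return(start)
  n_nodes <- max(c(edge, start))
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  visited <- logical(n_nodes)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    more <- adj[[v]]
    stack <- c(stack, more[!visited[more]])
  }
  which(visited)
}

# Convert an edge-matrix tree to an ape "phylo" (unrooted, basal trifurcation).
utree_to_phylo <- function(edge, n_tips, labels) {
  nodes <- sort(unique(as.integer(edge)))
  internal <- nodes[nodes > n_tips]
  remap <- integer(max(nodes))
  remap[seq_len(n_tips)] <- seq_len(n_tips)
  root <- internal[1L]
  # orient away from root
  adj <- vector("list", max(nodes))
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent_of <- integer(max(nodes))
  ordered <- integer(0)
  stack <- root
  parent_of[root] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ordered <- c(ordered, v)
    kids <- setdiff(adj[[v]], parent_of[v])
    parent_of[kids] <- v
    stack <- c(stack, kids)
  }
  int_pre <- ordered[ordered > n_tips]
  remap[int_pre] <- n_tips + seq_along(int_pre)
  children <- ordered[ordered != root]
  pe <- cbind(remap[parent_of[children]], remap[children])
  phy <- list(edge = pe, tip.label = labels[seq_len(n_tips)],
              Nnode = length(internal))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

# Convert an ape "phylo" to the edge-matrix representation, with tip ids
# matching positions of `labels` (defaults to the tree's own label order).
phylo_to_utree <- function(phy, labels = phy$tip.label) {
  if (length(phy$tip.label) > 2L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  idx <- match(phy$tip.label, labels)
  if (anyNA(idx)) stop("tree labels not found in the supplied label set")
  edge <- phy$edge
  out <- edge
  out[edge <= n] <- idx[edge[edge <= n]]
  storage.mode(out) <- "integer"
  out
}

# Double factorial over odd terms: (2n-5)!! topologies on n labelled leaves.
odd_double_factorial <- function(m) {
  if (m <= 0) return(1)
  prod(seq(1, m, by = 2))
}
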