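tree_split_keys <- function(tree, labels) {
  edge <- phylo_to_utree(tree, labels)
  utree_bipartitions(edge, length(labels), labels)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference of their split sets).
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  labels <- sort(t1$tip.label)
  k1 <- tree_split_keys(t1, labels)
  k2 <- tree_split_keys(t2, labels)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Congruence constraints
#'
#' A set of leaf groups required to be monophyletic in the unrooted sense
#' (some bipartition separates the group from its complement), plus sister
#' constraints between named groups (the union of a sister pair must also be
#' separated by a bipartition).
#'
#' @param groups named list of character vectors (disjoint leaf sets).
#' @param sisters list of length-2 character vectors naming sister groups.
#' @return a `congruence_constraints` object.
#' @export
congruence_constraints <- function(groups, sisters = list()) {
  if (length(groups) &&
      (is.null(names(groups)) || any(!nzchar(names(groups))))) {
    stop("groups must be named")
  }
  all_leaves <- unlist(groups)
  if (anyDuplicated(all_leaves)) stop("groups must be disjoint")
  for (s in sisters) {
    if (length(s) != 2L || !all(s %in% names(groups))) {
      stop("each sister constraint names two declared groups")
    }
  }
  structure(list(groups = groups, sisters = sisters),
            class = "congruence_constraints")
}

#' Read congruence constraints from a JSON file
#'
#' The file holds an object with `groups` (name -> array of leaf ids) and
#' optionally `sisters` (array of two-element group-name arrays).
#'
#' @param path JSON file path.
#' @return a [congruence_constraints()] object.
#' @export
read_constraints <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(x$groups, as.character)
  sisters <- if (is.null(x$sisters)) list() else {
    if (is.matrix(x$sisters)) apply(x$sisters, 1L, as.character,
                                    simplify = FALSE)
    else lapply(x$sisters, as.character)
  }
  congruence_constraints(groups, sisters)
}

#' The great-ape congruence constraint set
#'
#' Five conspecific pairs monophyletic, the two gorilla species sister, and
#' the chimpanzee/bonobo (Pan) pair sister — the constraint set whose chance
#' of arising in a random ten-taxon unrooted topology is below 1/2,000,000.
#'
#' @param species_map named character vector sample id -> species.
#' @param sisters list of species-name pairs required sister (default:
#'   the two gorillas; chimpanzee and bonobo).
#' @return a [congruence_constraints()] object.
#' @export
great_ape_constraints <- function(species_map,
                                  sisters = list(
                                    c("gorilla_western", "gorilla_eastern"),
                                    c("chimpanzee", "bonobo"))) {
  groups <- split(names(species_map), unname(species_map))
  congruence_constraints(groups, sisters)
}

separated <- function(set, keys, labels) {
  k <- length(set)
  n <- length(labels)
  if (k <= 1L || k >= n - 1L) return(TRUE) # trivial split, always present
  split_key(set, labels) %in% keys
}

#' Is a tree congruent with the constraints?
#'
#' TRUE iff every required group is separated by some bipartition of the tree
#' and, for each sister pair, the union of the two groups is separated too.
#'
#' @param tree an [ape::phylo].
#' @param constraints a [congruence_constraints()] object.
#' @return logical.
#' @export
is_congruent <- function(tree, constraints) {
  labels <- sort(tree$tip.label)
  if (!all(unlist(constraints$groups) %in% labels)) {
    stop("constrained leaves missing from the tree")
  }
  keys <- tree_split_keys(tree, labels)
  for (g in constraints$groups) {
    if (!separated(g, keys, labels)) return(FALSE)
  }
  for (s in constraints$sisters) {
    u <- c(constraints$groups[[s[1L]]], constraints$groups[[s[2L]]])
    if (!separated(u, keys, labels)) return(FALSE)
  }
  TRUE
}

#' Number of unrooted binary topologies
#'
#' `(2n-5)!!` distinct unrooted binary topologies on `n` labelled leaves
#' (2,027,025 for ten taxa — more than 2,000,000).
#'
#' @param n_leaves number of leaves (>= 3).
#' @return the topology count (numeric; exact for any realistic `n`).
#' @export
count_topologies <- function(n_leaves) {
  if (n_leaves < 3L) stop("need at least 3 leaves")
  odd_double_factorial(2L * n_leaves - 5L)
}

#' Probability that a random topology satisfies the constraints
#'
#' Computed exactly: each required group is collapsed to a supertaxon
#' (contributing `(2k-3)!!` internal rooted arrangements), each sister pair of
#' supertaxa is collapsed to a single unit (one way to join two rooted
#' subtrees), and the remaining units are free — giving the congruent-tree
#' count over [count_topologies()]. An explicit-enumeration cross-check path
#' is available for small trees.
#'
#' @param n_leaves total number of leaves.
#' @param constraints a [congruence_constraints()] object.
#' @param method `"collapse"` (exact combinatorial, default) or
#'   `"enumerate"` (explicit enumeration over all topologies; requires
#'   `labels` and small `n_leaves`).
#' @param labels leaf labels (needed for `method = "enumerate"`; unnamed
#'   leaves are filled in automatically for the collapse method).
#' @return list with `numerator` (congruent topologies), `denominator`
#'   (all topologies) and `probability`.
#' @export
congruence_probability <- function(n_leaves, constraints,
                                   method = c("collapse", "enumerate"),
                                   labels = NULL) {
  method <- match.arg(method)
  sizes <- lengths(constraints$groups)
  if (sum(sizes) > n_leaves) {
    return(list(numerator = 0, denominator = count_topologies(n_leaves),
                probability = 0))
  }
  denom <- count_topologies(n_leaves)
  if (method == "collapse") {
    n_free <- n_leaves - sum(sizes)
    n_units <- length(sizes) + n_free
    mult <- prod(vapply(sizes, function(k) odd_double_factorial(2L * k - 3L),
                        numeric(1)))
    n_units <- n_units - length(constraints$sisters)
    numer <- if (n_units < 3L) mult else
      mult * odd_double_factorial(2L * n_units - 5L)
  } else {
    if (is.null(labels)) stop("labels required for enumeration")
    if (n_leaves > 9L) stop("enumeration limited to 9 leaves")
    env <- new.env()
    env$count <- 0
    enumerate_utrees(seq_len(n_leaves), n_leaves, function(edge) {
      tr <- utree_to_phylo(edge, n_leaves, labels)
      if (is_congruent(tr, constraints)) env$count <- env$count + 1
    })
    numer <- env$count
  }
  list(numerator = numer, denominator = denom,
       probability = numer / denom)
}

#' Branch-length apportionment between internal and terminal branches
#'
#' `terminal_fraction` is the summed length of leaf-adjacent branches over the
#' total tree length. `internal_fraction` is the summed length of the
#' species-discriminating internal branches — internal branches whose
#' bipartition separates whole species groups — over the total. The two need
#' not sum to 1 when other internal branches exist.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param species_map named character vector sample id -> species.
#' @return list with `internal_fraction`, `terminal_fraction`,
#'   `n_discriminating`.
#' @export
branch_apportionment <- function(tree, species_map) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  total <- sum(tree$edge.length)
  if (total <= 0) stop("zero total branch length")
  n <- length(tree$tip.label)
  term <- tree$edge[, 2L] <= n
  sides <- prop_part_sides_edges(tree)
  disc <- vapply(seq_len(nrow(tree$edge)), function(i) {
    if (term[i]) return(FALSE)
    tips <- tree$tip.label[sides[[i]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) return(FALSE)
    sp_in <- unique(species_map[tips])
    sp_out <- unique(species_map[setdiff(tree$tip.label, tips)])
    length(intersect(sp_in, sp_out)) == 0L
  }, logical(1))
  list(internal_fraction = sum(tree$edge.length[disc]) / total,
       terminal_fraction = sum(tree$edge.length[term]) / total,
       n_discriminating = sum(disc))
}

#' Correlation of internal branch lengths between two congruent trees
#'
#' Internal branches are matched by bipartition; each tree's internal lengths
#' are normalized to sum 1 (relative branch lengths) unless `relative =
#' FALSE`; the Pearson correlation and its square are returned. The trees must
#' have identical topologies and at least three internal branches; zero
#' variance in either vector yields an `NA` result with a warning.
#'
#' @param t1,t2 [ape::phylo] trees with branch lengths, same topology.
#' @param relative normalize internal lengths to sum 1 (default TRUE).
#' @return list with `r`, `r_squared`, `n_branches`.
#' @export
internal_branch_correlation <- function(t1, t2, relative = TRUE) {
  if (rf_distance(t1, t2) != 0L) stop("tree topologies differ")
  labels <- sort(t1$tip.label)
  v <- lapply(list(t1, t2), function(tr) {
    edge <- phylo_to_utree(tr, labels)
    keys <- utree_bipartitions(edge, length(labels), labels)
    len <- tr$edge.length[attr(keys, "edge_row")]
    setNames(len, keys)
  })
  if (length(v[[1L]]) < 3L) stop("fewer than 3 internal branches")
  x <- v[[1L]]
  y <- v[[2L]][names(x)]
  if (relative) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance in internal branch lengths; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, n_branches = length(x)))
  }
  r <- cor(x, y)
  list(r = r, r_squared = r^2, n_branches = length(x))
}

#' Technical-replicate overlap
#'
#' Fraction of reads in set A with no acceptable match in set B: a read
#' matches if some read in B reaches pairwise identity >= (100 -
#' `max_divergence`) under the OTU-clustering identity rules (class-wise
#' reference-guided alignment, terminal gaps excluded, internal gaps counted).
#' With `max_divergence = 0` this is the no-identical-match fraction.
#'
#' @param reads_a,reads_b data.frames with `read_id`, `sequence` (e.g. the
#'   filtered reads of the original sample and its technical replicate).
#' @param references reference taxonomy for classification and class
#'   representatives.
#' @param max_divergence allowed percent divergence (default 0.5). May be a
#'   vector: the expensive classification and alignment work is shared and
#'   one unmatched fraction is returned per value.
#' @param k,n_bootstrap,seed classifier settings.
#' @return the unmatched fraction(s) of `reads_a` (read-weighted), named by
#'   divergence when several are requested.
#' @export
replicate_overlap <- function(reads_a, reads_b, references,
                              max_divergence = 0.5, k = 8L,
                              n_bootstrap = 20L, seed = 1L) {
  stopifnot(nrow(reads_a) > 0L, nrow(reads_b) > 0L)
  thresholds <- 100 - max_divergence
  loosest <- min(thresholds)
  clf <- build_classifier(references, k)
  reps <- class_representatives(references)
  reads_a$sample_id <- "A"
  reads_b$sample_id <- "B"
  both <- rbind(reads_a[, c("read_id", "sequence", "sample_id")],
                reads_b[, c("read_id", "sequence", "sample_id")])
  asn <- classify_reads(both, clf, n_bootstrap = n_bootstrap, seed = seed)
  both$class <- asn$class
  types <- dereplicate(both)
  unmatched <- setNames(numeric(length(thresholds)),
                        paste0(max_divergence, "%"))
  for (cl in unique(types$class)) {
    idx <- which(types$class == cl)
    a_cnt <- types$counts[idx, "A"]
    b_cnt <- types$counts[idx, "B"]
    if (is.na(cl) || is.na(reps[cl])) {
      unmatched <- unmatched + sum(a_cnt)
      next
    }
    al <- align_class(types$sequence[idx], reps[[cl]])
    pairs <- similar_pairs(al, loosest)
    has_b <- b_cnt > 0L
    for (t in seq_along(thresholds)) {
      matched <- has_b # a type present in B matches itself
      keep <- pairs$identity >= thresholds[t]
      if (any(keep)) {
        pi <- pairs$i[keep]
        pj <- pairs$j[keep]
        matched[pi[has_b[pj]]] <- TRUE
        matched[pj[has_b[pi]]] <- TRUE
      }
      unmatched[t] <- unmatched[t] + sum(a_cnt[!matched])
    }
  }
  res <- unmatched / sum(types$counts[, "A"])
  if (length(res) == 1L) unname(res) else res
}
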