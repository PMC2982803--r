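#' Host community design for the synthetic generator
#'
#' Describes the host sampling design that the simulator emulates: a set of
#' host species each contributing several individuals, a species-level tree,
#' and the parameters that control how microbial community profiles diverge
#' along it.
#'
#' @param species named integer vector: individuals sampled per species.
#' @param topology Newick string of the unrooted species tree with branch
#'   lengths in arbitrary time units; tip labels must equal `names(species)`.
#' @param divergence_scale non-negative real: log10-abundance divergence per
#'   unit of species-tree branch length. Controls how strongly community
#'   profiles track the host tree; 0 removes all between-species signal.
#' @param indiv_sigma within-species individual noise (sd, log10 units).
#' @param turnover presence/absence flip rate per unit branch length.
#' @param indiv_branch branch length (time units) of individual terminal
#'   branches in the expanded sample tree.
#' @param epsilon minimum emitted branch length.
#' @param detection_floor relative frequencies below this are set to absent.
#' @return an object of class `host_spec`.
#' @export
host_spec <- function(species = c(human = 2L, chimpanzee = 2L, bonobo = 2L,
                                  gorilla_western = 2L, gorilla_eastern = 2L),
                      topology = paste0(
                        "(human:0.6,(chimpanzee:0.5,bonobo:0.5):0.7,",
                        "(gorilla_western:0.5,gorilla_eastern:0.5):0.9);"),
                      divergence_scale = 1.5,
                      indiv_sigma = 0.15,
                      turnover = 0.05,
                      indiv_branch = 0.1,
                      epsilon = 1e-8,
                      detection_floor = 1e-5) {
  if (is.null(names(species)) || any(!nzchar(names(species)))) {
    stop("species must be a named vector")
  }
  if (any(species < 1L)) stop("each species needs at least one individual")
  if (divergence_scale < 0 || indiv_sigma < 0 || turnover < 0) {
    stop("divergence_scale, indiv_sigma and turnover must be non-negative")
  }
  sp_tree <- ape::read.tree(text = topology)
  if (!setequal(sp_tree$tip.label, names(species))) {
    stop("topology tip labels must equal the species names")
  }
  structure(list(species = species, topology = topology,
                 divergence_scale = divergence_scale,
                 indiv_sigma = indiv_sigma, turnover = turnover,
                 indiv_branch = indiv_branch, epsilon = epsilon,
                 detection_floor = detection_floor),
            class = "host_spec")
}

# Pectinate Newick of one species' individuals (stem length added by caller).
indiv_subtree <- function(sp, count, ib) {
  tips <- sprintf("%s_%d", sp, seq_len(count))
  if (count == 1L) return(tips)
  s <- sprintf("%s:%g", tips[count], ib)
  for (i in seq(count - 1L, 1L)) {
    s <- sprintf("(%s:%g,%s):%g", tips[i], ib, s, if (i == 1L) 0 else ib * 0.1)
  }
  # the outermost ":0" stem placeholder is stripped; caller's edge remains
  sub(":0$", "", s)
}

#' Simulate the planted host tree
#'
#' Expands the species-level topology of a [host_spec()] into an unrooted
#' binary tree over individual samples (conspecifics attached under their
#' species' subtree) and converts branch lengths into expected
#' log10-divergence units by multiplying time-unit lengths by
#' `divergence_scale` (with an epsilon floor so lengths stay positive).
#'
#' @param spec a [host_spec()].
#' @param seed integer seed (construction is deterministic; kept for API
#'   symmetry with the other generator stages).
#' @return an [ape::phylo] with attributes `species_map` (sample -> species)
#'   and `individual_edges` (logical per edge row: inside a within-species
#'   subtree).
#' @export
simulate_host_tree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "host_spec"))
  if (sum(spec$species) < 4L) {
    stop("need at least 4 individuals in total for an unrooted binary tree")
  }
  txt <- spec$topology
  for (sp in names(spec$species)) {
    rep_str <- indiv_subtree(sp, spec$species[[sp]], spec$indiv_branch)
    txt <- gsub(sprintf("(?<=[(,])%s(?=[:,)])", sp), rep_str, txt, perl = TRUE)
  }
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- pmax(tree$edge.length * spec$divergence_scale,
                           spec$epsilon)
  sample_ids <- tree$tip.label
  species_map <- setNames(sub("_[0-9]+$", "", sample_ids), sample_ids)
  # edges inside a within-species subtree: all tips below belong to one
  # species AND the edge is not that species' stem (stem = subtree holds all
  # of the species' individuals and the parent holds more)
  # an edge is "within-species" iff the tips below it are a proper subset of
  # one species' individuals (the species stem, holding all of them, is not)
  sides <- prop_part_sides_edges(tree)
  indiv <- vapply(seq_len(nrow(tree$edge)), function(i) {
    tips <- sides[[i]]
    sp <- unique(species_map[tree$tip.label[tips]])
    length(sp) == 1L && length(tips) < spec$species[[sp]]
  }, logical(1))
  attr(tree, "species_map") <- species_map
  attr(tree, "individual_edges") <- indiv
  tree
}

# Tip sets below each EDGE of a phylo tree (child side).
prop_part_sides_edges <- function(phy) {
  n <- length(phy$tip.label)
  post <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (r in seq_len(nrow(post$edge))) {
    p <- post$edge[r, 1L]; ch <- post$edge[r, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(seq_len(nrow(phy$edge)), function(r) sort(sets[[phy$edge[r, 2L]]]))
}

#' Evolve community profiles along the host tree
#'
#' Log10 relative abundances of `n_otus` microbial lineages evolve by Brownian
#' motion along the species-level branches of the planted tree (variance =
#' emitted branch length x `divergence_scale`, i.e. time x scale^2);
#' presence/absence toggles as a Poisson process at the turnover rate;
#' individual-level variation enters only as i.i.d. Gaussian noise
#' (`indiv_sigma`, log10 units) at the leaves, so with sigma 0 and turnover 0
#' conspecific individuals have identical profiles. Frequencies below the
#' detection floor are set to absent; each profile is renormalized to sum 1.
#'
#' @param tree planted host tree from [simulate_host_tree()].
#' @param n_otus number of true OTUs.
#' @param spec the [host_spec()] used to build the tree.
#' @param seed integer seed.
#' @param root_sd sd of root log10 abundances across OTUs.
#' @return numeric matrix samples x OTUs of relative frequencies (rows sum
#'   to 1), with OTU ids as colnames.
#' @export
evolve_profiles <- function(tree, n_otus, spec, seed = 1L, root_sd = 1) {
  stopifnot(n_otus >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(tree$tip.label)
  indiv <- attr(tree, "individual_edges")
  if (is.null(indiv)) indiv <- rep(FALSE, nrow(tree$edge))
  phy <- ape::reorder.phylo(tree, "cladewise") # parents precede children
  indiv <- indiv[match(paste(phy$edge[, 1], phy$edge[, 2]),
                       paste(tree$edge[, 1], tree$edge[, 2]))]
  n_nodes <- n + phy$Nnode
  x <- matrix(NA_real_, n_nodes, n_otus)
  pres <- matrix(TRUE, n_nodes, n_otus)
  root <- n + 1L
  x[root, ] <- rnorm(n_otus, 0, root_sd)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1L]; ch <- phy$edge[r, 2L]
    len <- phy$edge.length[r]
    if (indiv[r]) {
      x[ch, ] <- x[p, ]
      pres[ch, ] <- pres[p, ]
    } else {
      v <- len * spec$divergence_scale
      x[ch, ] <- x[p, ] + if (v > 0) rnorm(n_otus, 0, sqrt(v)) else 0
      flips <- rpois(n_otus, spec$turnover * len)
      pres[ch, ] <- xor(pres[p, ], flips %% 2L == 1L)
    }
  }
  leaves <- seq_len(n)
  xl <- x[leaves, , drop = FALSE] +
    matrix(rnorm(n * n_otus, 0, spec$indiv_sigma), n, n_otus)
  freq <- ifelse(pres[leaves, , drop = FALSE], 10^xl, 0)
  freq <- freq / rowSums(freq)
  freq[freq < spec$detection_floor] <- 0
  zero <- rowSums(freq) == 0
  if (any(zero)) { # pathological: restore the most abundant lineage
    for (i in which(zero)) freq[i, which.max(xl[i, ])] <- 1
  }
  freq <- freq / rowSums(freq)
  rownames(freq) <- phy$tip.label
  colnames(freq) <- sprintf("otu_%03d", seq_len(n_otus))
  freq
}
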