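test_that("Robinson-Foulds distance counts one-sided bipartitions", {
  t1 <- read_newick("((a,b),(c,d),e);")
  expect_equal(rf_distance(t1, t1), 0L)
  # one NNI apart (exchange b with the (c,d) clade): they share the cd split
  t2 <- read_newick("((c,d),a,(b,e));")
  expect_equal(rf_distance(t1, t2), 2L)
  # no shared internal splits on 5 taxa: maximum 2(n-3) = 4
  t3 <- read_newick("((a,e),(b,c),d);")
  expect_equal(rf_distance(t1, t3), 4L)
  expect_error(rf_distance(t1, read_newick("((a,b),(c,x),e);")),
               "leaf sets")
})

test_that("RF agrees with an independent implementation on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (i in 1:10) {
    a <- ape::rtree(12, br = NULL)
    b <- ape::rtree(12, br = NULL)
    expect_equal(rf_distance(a, b), unname(phangorn::RF.dist(a, b)))
  }
})

test_that("congruence checks species and sister placements", {
  smap <- setNames(rep(c("human", "chimpanzee", "bonobo",
                         "gorilla_western", "gorilla_eastern"), each = 2),
                   c("human_1", "human_2", "chimpanzee_1", "chimpanzee_2",
                     "bonobo_1", "bonobo_2", "gorilla_western_1",
                     "gorilla_western_2", "gorilla_eastern_1",
                     "gorilla_eastern_2"))
  cc <- great_ape_constraints(smap)
  good <- read_newick(paste0(
    "((human_1,human_2),((chimpanzee_1,chimpanzee_2),",
    "(bonobo_1,bonobo_2)),((gorilla_western_1,gorilla_western_2),",
    "(gorilla_eastern_1,gorilla_eastern_2)));"))
  expect_true(is_congruent(good, cc))
  # a human leaf inside the chimpanzee pair breaks congruence
  bad <- read_newick(paste0(
    "((human_1,(chimpanzee_1,human_2)),(chimpanzee_2,",
    "(bonobo_1,bonobo_2)),((gorilla_western_1,gorilla_western_2),",
    "(gorilla_eastern_1,gorilla_eastern_2)));"))
  expect_false(is_congruent(bad, cc))
  # conspecifics paired but gorillas not sister to each other: sisters fail
  nosis <- read_newick(paste0(
    "((human_1,human_2),((chimpanzee_1,chimpanzee_2),",
    "(gorilla_western_1,gorilla_western_2)),((bonobo_1,bonobo_2),",
    "(gorilla_eastern_1,gorilla_eastern_2)));"))
  expect_false(is_congruent(nosis, cc))
})

test_that("enumeration identifies exactly the topologies holding a cherry", {
  labels <- paste0("l", 1:5)
  cc <- congruence_constraints(list(pair = c("l1", "l2")))
  hits <- 0L
  total <- 0L
  enumerate <- phylosym:::enumerate_utrees
  enumerate(1:5, 5L, function(edge) {
    tr <- phylosym:::utree_to_phylo(edge, 5L, labels)
    total <<- total + 1L
    keys <- phylosym:::utree_bipartitions(edge, 5L, labels)
    has_cherry <- "l1|l2" %in% keys ||
      phylosym:::split_key(c("l1", "l2"), labels) %in% keys
    expect_equal(is_congruent(tr, cc), has_cherry)
    if (is_congruent(tr, cc)) hits <<- hits + 1L
  })
  expect_equal(total, 15L)
  expect_equal(hits, 3L) # collapsing the cherry leaves 4 units: (2*4-5)!! = 3
})

test_that("constraints round-trip through a JSON file", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(groups = list(p1 = c("a", "b"),
                                          p2 = c("c", "d")),
                            sisters = list(c("p1", "p2"))),
                       path, auto_unbox = FALSE)
  cc <- read_constraints(path)
  expect_true(is_congruent(read_newick("(((a,b),(c,d)),e,f);"), cc))
  expect_false(is_congruent(read_newick("(((a,c),(b,d)),e,f);"), cc))
})

test_that("topology counts match explicit enumeration", {
  expect_error(count_topologies(2), "at least 3")
  expect_equal(count_topologies(3), 1)
  expect_equal(count_topologies(5), 15)
  expect_equal(count_topologies(10), 2027025)
  expect_gt(count_topologies(10), 2e6)
  for (n in 5:7) {
    cnt <- 0L
    phylosym:::enumerate_utrees(seq_len(n), n, function(edge) cnt <<- cnt + 1L)
    expect_equal(count_topologies(n), cnt)
  }
})

test_that("congruence probability is exact and matches enumeration", {
  # no constraints: probability 1
  none <- congruence_constraints(list())
  expect_equal(congruence_probability(8, none)$probability, 1)
  # one cherry on a quartet: 1 of 3 topologies
  p4 <- congruence_probability(4, congruence_constraints(list(p = c("a", "b"))))
  expect_equal(p4$numerator, 1)
  expect_equal(p4$denominator, 3)
  # collapse vs explicit enumeration on 6 and 7 leaves
  for (n in 6:7) {
    labels <- paste0("l", seq_len(n))
    cc <- congruence_constraints(
      list(g1 = c("l1", "l2"), g2 = c("l3", "l4")),
      sisters = list(c("g1", "g2")))
    a <- congruence_probability(n, cc)
    b <- congruence_probability(n, cc, method = "enumerate", labels = labels)
    expect_equal(a$numerator, b$numerator)
    expect_equal(a$denominator, b$denominator)
  }
  # the congruent count is always a whole number of trees
  cc2 <- congruence_constraints(list(g = c("x", "y", "z")))
  p <- congruence_probability(9, cc2)
  expect_equal(p$probability * count_topologies(9), round(p$numerator))
})

test_that("branch apportionment separates terminal and species branches", {
  smap <- setNames(rep(c("A", "B", "C", "D", "E"), each = 2),
                   paste0(rep(c("A", "B", "C", "D", "E"), each = 2), "_",
                          rep(1:2, 5)))
  spec <- host_spec(species = setNames(rep(2L, 5), c("A", "B", "C", "D", "E")),
                    topology = "(A:1,(B:1,C:1):1,(D:1,E:1):1);")
  tr <- simulate_host_tree(spec)
  # star tree: no internal branches at all
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, 6)
  smap6 <- setNames(c("A", "A", "B", "B", "C", "C"), star$tip.label)
  expect_equal(branch_apportionment(star, smap6)$internal_fraction, 0)
  # all terminal lengths zero: terminal 0, species-internal 1
  n <- length(tr$tip.label)
  t0 <- tr
  t0$edge.length <- ifelse(tr$edge[, 2] <= n, 0, 2)
  ap0 <- branch_apportionment(t0, smap)
  expect_equal(ap0$terminal_fraction, 0)
  expect_equal(ap0$internal_fraction, 1)
  # terminals 1, internals 2 on 10 leaves: 10/24 and 14/24
  t1 <- tr
  t1$edge.length <- ifelse(tr$edge[, 2] <= n, 1, 2)
  ap1 <- branch_apportionment(t1, smap)
  expect_equal(ap1$terminal_fraction, 10 / 24)
  expect_equal(ap1$internal_fraction, 14 / 24)
  expect_equal(ap1$n_discriminating, 7L)
})

test_that("internal branch correlation uses relative lengths", {
  spec <- host_spec()
  tr <- simulate_host_tree(spec)
  n <- length(tr$tip.label)
  internal <- tr$edge[, 2] > n
  t1 <- tr
  t1$edge.length <- ifelse(internal, seq_len(nrow(tr$edge)), 1)
  t2 <- t1
  t2$edge.length <- 2 * t1$edge.length
  r <- internal_branch_correlation(t1, t2)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$n_branches, 7L)
  # hand-built length vectors, verified against the textbook formula
  v1 <- c(0.30, 0.20, 0.15, 0.12, 0.10, 0.08, 0.05)
  v2 <- rev(v1)
  ta <- tr; tb <- tr
  ta$edge.length <- rep(1, nrow(tr$edge))
  tb$edge.length <- rep(1, nrow(tr$edge))
  ta$edge.length[internal] <- v1
  tb$edge.length[internal] <- v2
  got <- internal_branch_correlation(ta, tb)
  # independent computation (the internal-edge match is order-preserving
  # between ta and tb because they share tree structure)
  num <- sum((v1 - mean(v1)) * (v2 - mean(v2)))
  den <- sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(got$r, num / den)
  # zero variance: undefined-result signal
  tc <- tr
  tc$edge.length <- rep(1, nrow(tr$edge))
  expect_warning(rz <- internal_branch_correlation(tc, ta), "zero variance")
  expect_true(is.na(rz$r))
  # different topologies: error
  other <- ape::rtree(n, br = NULL)
  other$tip.label <- tr$tip.label
  other$edge.length <- rep(1, nrow(other$edge))
  if (rf_distance(other, tr) != 0) {
    expect_error(internal_branch_correlation(tr, other), "differ")
  }
})

test_that("replicate overlap distinguishes exact and 0.5% matching", {
  set.seed(30)
  seq0 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  v <- strsplit(seq0, "")[[1]]
  v[100] <- setdiff(c("A", "C", "G", "T"), v[100])[1]
  seq1 <- paste(v, collapse = "")
  refs <- data.frame(taxon_id = "t1", phylum = "P", class = "C",
                     sequence = seq0)
  A <- data.frame(read_id = "a1", sequence = seq0)
  B1 <- data.frame(read_id = "b1", sequence = seq1)
  # one substitution: 199/200 = 99.5% identity
  expect_equal(replicate_overlap(A, B1, refs, max_divergence = 0), 1)
  expect_equal(replicate_overlap(A, B1, refs, max_divergence = 0.5), 0)
  # identical sets at zero divergence: nothing unmatched
  expect_equal(replicate_overlap(A, A, refs, max_divergence = 0), 0)
})
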