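test_that("ordered costs are the |i-j| Wagner matrix", {
  cm <- ordered_costs()
  expect_equal(dim(cm), c(6L, 6L))
  expect_equal(cm[1, 6], 5)
  expect_equal(diag(cm), rep(0, 6))
  expect_true(isSymmetric(cm))
})

test_that("Sankoff scoring matches hand and brute-force oracles", {
  # constant character: zero on any tree
  m <- matrix(3L, 5, 4, dimnames = list(paste0("t", 1:5), NULL))
  expect_equal(sankoff_score(read_newick("((t1,t2),(t3,t4),t5);"), m), 0)
  # two-leaf tree, one character 0 vs 5: cost 5
  m2 <- matrix(c(0L, 5L), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(sankoff_score(read_newick("(a,b);"), m2), 5)
  # quartet (a=0, b=1, c=4, d=5) on ((a,b),(c,d)): brute force says 5
  m3 <- matrix(c(0L, 1L, 4L, 5L), 4, 1,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(sankoff_score(tr, m3), 5)
  expect_equal(sankoff_score(tr, m3), quartet_oracle(m3, ordered_costs()))
  # 500 random quartets: exact agreement with internal-state enumeration
  tr_ab <- read_newick("((a,b),(c,d));")
  for (i in 1:500) {
    set.seed(i)
    mq <- matrix(sample(0:5, 4L * 3L, replace = TRUE), 4, 3,
                 dimnames = list(c("a", "b", "c", "d"), NULL))
    expect_equal(sankoff_score(tr_ab, mq), quartet_oracle(mq, ordered_costs()))
  }
})

test_that("the score is invariant to rooting and leaf order", {
  m <- random_matrix(6, 25, seed = 10)
  tr <- read_newick("((t1,t2),((t3,t4),(t5,t6)));")
  s0 <- sankoff_score(tr, m)
  for (og in c("t1", "t4", "t6")) {
    expect_equal(sankoff_score(ape::root(tr, og), m), s0)
  }
  expect_equal(sankoff_score(tr, m[sample(6), ]), s0)
})

test_that("Sankoff agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  costs <- ordered_costs()
  for (i in 1:5) {
    m <- random_matrix(7, 30, seed = 100 + i)
    tr <- ape::rtree(7, tip.label = rownames(m), br = NULL)
    pd <- phangorn::phyDat(m, type = "USER", levels = 0:5)
    ref <- phangorn::parsimony(tr, pd, method = "sankoff", cost = costs)
    expect_equal(sankoff_score(tr, m, costs), unname(as.numeric(ref)))
  }
})

test_that("exhaustive search enumerates (2n-5)!! topologies and finds optima", {
  m3 <- random_matrix(3, 5, seed = 1)
  ex3 <- exhaustive_search(m3)
  expect_equal(ex3$n_scored, 1L)
  m5 <- random_matrix(5, 10, seed = 2)
  ex5 <- exhaustive_search(m5)
  expect_equal(ex5$n_scored, 15L)
  expect_error(exhaustive_search(random_matrix(10, 5, seed = 3)),
               "heuristic_search")
  # additive characters on a known 6-taxon tree: unique optimum = planted
  planted <- read_newick("((t1,t2),(t3,t4),(t5,t6));")
  labels <- paste0("t", 1:6)
  splits <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"))
  m6 <- do.call(cbind, rep(lapply(splits, function(s) {
    ifelse(labels %in% s, 2L, 0L)
  }), 4L))
  rownames(m6) <- labels
  ex6 <- exhaustive_search(m6)
  expect_equal(length(ex6$trees), 1L)
  expect_equal(rf_distance(ex6$trees[[1L]], planted), 0L)
  expect_equal(ex6$score, 3 * 4 * 2) # one 0->2 change per split per copy
})

test_that("heuristic search matches the exhaustive oracle", {
  # 3-4 taxa: search space <= 3 trees, must match exactly
  m4 <- random_matrix(4, 12, seed = 4)
  expect_equal(heuristic_search(m4, seed = 1)$score,
               exhaustive_search(m4)$score)
  # 7-taxon random matrices (SPR, 10 starts)
  hits <- 0L
  for (i in 1:20) {
    m <- random_matrix(7, 50, seed = 200 + i)
    h <- heuristic_search(m, n_starts = 10, seed = i)
    e <- exhaustive_search(m)
    expect_gte(h$score, e$score) # the heuristic can never beat the oracle
    if (h$score == e$score) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # strong planted signal on 10 taxa: SPR recovers the planted topology
  spec <- host_spec()
  tr <- simulate_host_tree(spec)
  p <- evolve_profiles(tr, 120L, spec, seed = 6L)
  cm <- build_character_matrix(normalize_abundance(round(p * 1e6) + 0L))
  h <- heuristic_search(cm, seed = 2)
  expect_equal(rf_distance(h$trees[[1L]], tr), 0L)
})

test_that("unit (Fitch) costs never exceed ordered costs", {
  fitch <- 1 - diag(6)
  for (i in 1:10) {
    m <- random_matrix(6, 30, seed = 300 + i)
    tr <- ape::rtree(6, tip.label = rownames(m), br = NULL)
    expect_lte(sankoff_score(tr, m, fitch), sankoff_score(tr, m))
  }
})

test_that("bootstrap gives full support to clean signal, none to noise", {
  labels <- paste0("t", 1:6)
  splits <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"))
  m <- do.call(cbind, rep(lapply(splits, function(s) {
    ifelse(labels %in% s, 4L, 0L)
  }), 17L))
  rownames(m) <- labels
  b <- bootstrap_parsimony(m, n_reps = 60L, n_starts = 2L, seed = 3L)
  for (s in splits) {
    expect_equal(clade_support(b, s, labels), 100)
  }
  # all-constant matrix: no bipartition gets real support, consensus unresolved
  mc <- matrix(2L, 6, 20, dimnames = list(labels, NULL))
  bc <- bootstrap_parsimony(mc, n_reps = 60L, n_starts = 2L, seed = 4L)
  expect_true(all(bc$support < 70))
  expect_equal(bc$consensus$Nnode, 1L) # star consensus
})

test_that("conflicting quartet signals split bootstrap support evenly", {
  labels <- c("a", "b", "c", "d")
  col1 <- c(0L, 0L, 5L, 5L) # supports ab|cd
  col2 <- c(0L, 5L, 0L, 5L) # supports ac|bd
  n1 <- 20L; n2 <- 19L # odd total: replicates can never tie
  m <- cbind(matrix(col1, 4, n1), matrix(col2, 4, n2))
  rownames(m) <- labels
  n_reps <- 200L
  b <- bootstrap_parsimony(m, n_reps = n_reps, n_starts = 2L, seed = 7L)
  # expected win rate for ab|cd: more type-1 than type-2 columns resampled
  p1 <- stats::pbinom((n1 + n2 - 1) %/% 2, n1 + n2, n1 / (n1 + n2),
                      lower.tail = FALSE)
  ci <- stats::qbinom(c(0.005, 0.995), n_reps, p1) / n_reps * 100
  s1 <- clade_support(b, c("a", "b"), labels)
  expect_gte(s1, ci[1L])
  expect_lte(s1, ci[2L])
})

test_that("branch lengths are minimal-change assignments summing to the p-score", {
  labels <- c("a", "b", "c", "d")
  mc <- matrix(1L, 4, 7, dimnames = list(labels, NULL))
  tr <- read_newick("((a,b),(c,d));")
  bl0 <- assign_branch_lengths(tr, mc)
  expect_equal(sum(bl0$edge.length), 0)
  m2 <- matrix(c(0L, 5L), 2, 1, dimnames = list(c("a", "b"), NULL))
  bl2 <- assign_branch_lengths(read_newick("(a,b);"), m2)
  expect_equal(sum(bl2$edge.length), 5)
  m3 <- matrix(c(0L, 1L, 4L, 5L), 4, 1, dimnames = list(labels, NULL))
  bl3 <- assign_branch_lengths(tr, m3)
  expect_equal(sum(bl3$edge.length), sankoff_score(tr, m3))
  # conservation on random matrices
  for (i in 1:5) {
    m <- random_matrix(7, 25, seed = 400 + i)
    t7 <- ape::rtree(7, tip.label = rownames(m), br = NULL)
    bl <- assign_branch_lengths(t7, m)
    expect_equal(sum(bl$edge.length), sankoff_score(t7, m))
  }
})

test_that("Newick round-trips preserve topology and branch lengths", {
  t1 <- read_newick("(a,b,(c,d));")
  expect_equal(rf_distance(read_newick(write_newick(t1)), t1), 0L)
  set.seed(9)
  t2 <- ape::rtree(8)
  t2$edge.length <- round(t2$edge.length, 9)
  rt <- read_newick(write_newick(t2))
  expect_equal(rf_distance(rt, t2), 0L)
  expect_lt(max(abs(sort(rt$edge.length) - sort(t2$edge.length))), 1e-9)
  for (n in c(10, 25, 50)) {
    tr <- ape::rtree(n)
    expect_equal(rf_distance(read_newick(write_newick(tr)), tr), 0L)
  }
  expect_error(read_newick("((a,b,(c);"))
})
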