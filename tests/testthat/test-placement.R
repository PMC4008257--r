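test_that("grafting subdivides one edge and pruning restores the tree", {
  tr <- parse_newick("((A:0.1,B:0.2):0.05,(C:0.3,D:0.12):0.07,E:0.2);")
  expect_error(graft(tr, 1, "A"), "already in backbone")
  expect_error(graft(tr, 1, "Q", attach_fraction = 1.2), "attach_fraction")

  for (seed in 1:20) {
    tr <- random_bl_tree(8, seed)
    e <- sample(nrow(tr$edge), 1)
    g <- graft(tr, e, "Q", attach_fraction = runif(1, 0.1, 0.9),
               pendant_length = 0.17)
    old <- tree_splits(tr)
    new <- tree_splits(g)
    # split-set difference: every old split survives with Q added to the side
    # of the grafted edge's component, plus exactly one new split
    childset <- treeplacer:::edge_child_leaves(tr, e)
    expect_true(split_key_of(c(childset, "Q"), g$tip.label) %in% new ||
                  split_key_of(childset, g$tip.label) %in% new)
    # prune inverse: identical splits and patristic distances
    back <- ape::drop.tip(g, "Q")
    expect_identical(tree_splits(back), tree_splits(tr))
    D1 <- patristic_distances(tr)
    expect_equal(patristic_distances(back)[rownames(D1), colnames(D1)], D1,
                 tolerance = 1e-12)
    # the grafted tree has exactly one more internal split
    expect_identical(length(new), length(old) + 1L)
  }
})

test_that("grafting on the internal edge of a quartet adds the expected split", {
  tr <- parse_newick("((C:1,D:1):1,A:1,B:1);")
  e <- which(edge_keys_of(tr) == split_key_of(c("C", "D"), tr$tip.label))
  g <- graft(tr, e, "Q", 0.5, 0.1)
  expect_true(split_key_of(c("C", "D", "Q"), g$tip.label) %in% tree_splits(g))
})

test_that("a 2-leaf backbone forces the single placement", {
  bb <- parse_newick("(A:0.1,B:0.1);")
  m <- subst_model_jc()
  aln <- rand_aln(c("A", "B", "Q"), 100, seed = 3,
                  chars = c("A", "C", "G", "T"), prob = rep(0.25, 4))
  pl <- place_query(bb, aln, m, "Q")
  expect_identical(nrow(pl$table), 1L)
  expect_identical(pl$margin, Inf)
})

test_that("placement on a 3-leaf backbone matches the exhaustive quartet oracle", {
  m <- subst_model_hky(4, c(0.3, 0.2, 0.2, 0.3), alpha = 1, ncat = 4L)
  for (seed in 1:5) {
    set.seed(seed)
    bb <- parse_newick("(A:0.08,B:0.11,C:0.14);")
    full <- graft(bb, sample(3, 1), "Q", 0.5, 0.07)
    aln <- simulate_alignment(full, m, 1500, seed = seed + 100)
    pl <- place_query(bb, aln, m, "Q")
    # oracle: optimize all three quartet topologies from scratch
    quartets <- list(AB = "((A:0.1,Q:0.1):0.1,B:0.1,C:0.1);",
                     AC = "((B:0.1,Q:0.1):0.1,A:0.1,C:0.1);",
                     AD = "((C:0.1,Q:0.1):0.1,A:0.1,B:0.1);")
    ll <- vapply(quartets, function(s) {
      optimize_branch_lengths(parse_newick(s), aln, m, tol = 1e-8,
                              max_sweeps = 30)$loglik
    }, 0)
    best_sister <- c("A", "B", "C")[which.max(ll)]
    expect_identical(pl$best$split, split_key_of(best_sister, bb$tip.label))
    # the placement's constrained optimum cannot beat the free quartet optimum
    expect_lte(pl$best$loglik, max(ll) + 1e-4)
  }
})

test_that("the best edge attains the maximum over all edges", {
  st <- make_placement_study(single_marker_config(seed = 21, L = 2000))
  pl <- place_query(st$backbone, st$alignment, st$models$g1[[1]], "query")
  expect_true(all(pl$best$loglik >= pl$table$loglik))
  expect_identical(pl$best$split, st$truth$edge_split)
  expect_gt(pl$margin, 10)  # strong signal
  expect_error(place_query(st$backbone, st$alignment, st$models$g1[[1]],
                           "nosuch"), "subscript|missing|undefined")
})

test_that("multiple queries planted on distant edges are both recovered", {
  set.seed(31)
  bb <- ape::unroot(ape::rtree(10, br = NULL))
  bb$tip.label <- sprintf("t%02d", 1:10)
  bb$edge.length <- runif(nrow(bb$edge), 0.02, 0.08)
  e1 <- 3; e2 <- 12
  s1 <- treeplacer:::edge_child_leaves(bb, e1)
  s2 <- treeplacer:::edge_child_leaves(bb, e2)
  full <- graft(bb, e1, "qA", 0.5, 0.05)
  k2 <- which(vapply(seq_len(nrow(full$edge)), function(e) {
    cl <- treeplacer:::edge_child_leaves(full, e)
    setequal(setdiff(cl, "qA"), s2) && !("qA" %in% cl)
  }, TRUE))[1]
  full <- graft(full, k2, "qB", 0.5, 0.05)
  m <- subst_model_hky(4, c(A = .3, C = .2, G = .2, T = .3), alpha = 1)
  aln <- simulate_alignment(full, m, 4000, seed = 32)
  pm <- place_multiple(bb, aln, m, c("qA", "qB"))
  fin <- pm$tree
  for (q in c("qA", "qB")) {
    other <- setdiff(c("qA", "qB"), q)
    key <- treeplacer:::.query_sister_edge(
      tree_splits(ape::drop.tip(fin, other)),
      setdiff(fin$tip.label, other), q, bb$tip.label)
    expect_identical(key, split_key_of(if (q == "qA") s1 else s2,
                                       bb$tip.label))
  }
  # single query reduces to place_query
  one <- place_multiple(st <- bb, aln, m, "qA")
  pq <- place_query(bb, aln, m, "qA")
  expect_identical(one$placements$qA$split[1], pq$best$split)
})

test_that("bootstrap tallies conserve replicates and are seed-deterministic", {
  st <- make_placement_study(single_marker_config(seed = 22, L = 1200))
  m <- st$models$g1[[1]]
  t1 <- bootstrap_placements(st$backbone, st$alignment, m, "query", B = 12,
                             seed = 5)
  expect_identical(sum(tally_table(t1)$count), 12L)
  t2 <- bootstrap_placements(st$backbone, st$alignment, m, "query", B = 12,
                             seed = 5)
  expect_identical(tally_table(t1), tally_table(t2))
  t3 <- bootstrap_placements(st$backbone, st$alignment, m, "query", B = 12,
                             seed = 6)
  expect_identical(sum(tally_table(t3)$count), 12L)
})

test_that("effective support reduces to plain support without rogues and grows with them", {
  bb <- parse_newick(
    "(((p1:1,p2:1):1,(r:1,p3:1):1):1,((o1:1,o2:1):1,(o3:1,o4:1):1):1,(o5:1,o6:1):1);")
  focal <- c("p1", "p2", "p3", "r")
  e_clade <- which(edge_keys_of(bb) == split_key_of(focal, bb$tip.label))
  mk_wander <- function() {
    b2 <- ape::drop.tip(bb, "r")
    b2 <- graft(b2, which(edge_keys_of(b2) == split_key_of("o5", b2$tip.label)),
                "r", 0.5, 0.1)
    graft(b2, which(edge_keys_of(b2) ==
                      split_key_of(c("p1", "p2", "p3"), b2$tip.label)),
          "q", 0.5, 0.1)
  }
  trees <- c(replicate(7, graft(bb, e_clade, "q", 0.5, 0.1), simplify = FALSE),
             replicate(2, mk_wander(), simplify = FALSE),
             replicate(1, graft(bb, which(edge_keys_of(bb) ==
                                            split_key_of(c("o1", "o2"),
                                                         bb$tip.label)),
                                "q", 0.5, 0.1), simplify = FALSE))
  tal <- placement_tally(trees, "q", bb, rogues = "r")
  plain <- effective_support(tal, focal, rogues = character(0))
  eff <- effective_support(tal, focal, rogues = "r")
  expect_equal(plain, 70)
  expect_equal(eff, 90)
  expect_gte(eff, plain)  # monotone as rogues are added
  expect_error(effective_support(tal, c("p1", "o1"), rogues = character(0)),
               "not a clade")
})

test_that("all replicates on one in-clade edge give 100% support", {
  bb <- parse_newick("(((a:1,b:1):1,c:1):1,(d:1,e:1):1,f:1);")
  e_in <- which(edge_keys_of(bb) == split_key_of(c("a", "b"), bb$tip.label))
  trees <- replicate(10, graft(bb, e_in, "q", 0.5, 0.1), simplify = FALSE)
  tal <- placement_tally(trees, "q", bb)
  expect_equal(effective_support(tal, c("a", "b", "c")), 100)
  expect_equal(region_support(tal, bb$tip.label), 100)
  expect_error(region_support(tal, character(0)), "empty")
})

test_that("subset selection finds the supported clade and ranks outgroups by completeness", {
  bb <- parse_newick("(((a:1,b:1):1,c:1):1,(d:1,e:1):1,(f:1,g:1):1);")
  e_in <- which(edge_keys_of(bb) == split_key_of(c("a", "b"), bb$tip.label))
  trees <- replicate(10, graft(bb, e_in, "q", 0.5, 0.1), simplify = FALSE)
  tal <- placement_tally(trees, "q", bb)
  mat <- matrix("A", 7, 10, dimnames = list(bb$tip.label, NULL))
  mat["d", 1:5] <- "?"   # missing fractions: d = 0.5
  mat["e", 1:2] <- "?"   # e = 0.2
  mat["f", 1] <- "?"     # f = 0.1
  aln <- partitioned_alignment(mat)
  sel <- select_subset(bb, tal, aln, region_threshold = 95,
                       outgroup_clades = list(og = c("d", "e", "f")), k = 2)
  expect_true(all(c("a", "b") %in% sel$ingroup))
  expect_identical(sort(sel$outgroup), c("e", "f"))  # lowest missing first
  expect_gte(sel$support, 95)
  expect_error(select_subset(bb, tal, aln, region_threshold = 40), "50")
})

test_that("jplace export is valid version-3 JSON with consistent edge numbering", {
  st <- make_placement_study(single_marker_config(seed = 23, L = 800))
  pl <- place_query(st$backbone, st$alignment, st$models$g1[[1]], "query")
  f <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(pl, f)
  j <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_identical(j$version, 3L)
  expect_match(j$tree, "\\{\\d+\\}")
  p <- j$placements[[1]]$p
  expect_identical(j$placements[[1]]$n[[1]], "query")
  # best edge first, like-weight ratios in (0, 1]
  lw <- vapply(p, function(x) x[[3]], 0)
  expect_true(all(diff(vapply(p, function(x) x[[2]], 0)) <= 0))
  expect_true(all(lw > 0 & lw <= 1))
})
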