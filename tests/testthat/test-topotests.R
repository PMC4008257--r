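make_two_tree_fixture <- function(seed = 44, L = 600) {
  tr <- random_bl_tree(6, seed = seed, lo = 0.05, hi = 0.3)
  m <- subst_model_hky(4, c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  aln <- simulate_alignment(tr, m, L, seed = seed + 1)
  # rival topology: exchange two non-sister tip labels on the true tree
  alt <- tr
  k <- tree_splits(tr)[1]
  side <- strsplit(k, "|", fixed = TRUE)[[1]]
  a <- side[1]
  b <- setdiff(tr$tip.label, side)[1]
  i <- match(a, alt$tip.label); j <- match(b, alt$tip.label)
  alt$tip.label[c(i, j)] <- alt$tip.label[c(j, i)]
  if (identical(tree_splits(alt), tree_splits(tr))) {
    stop("fixture failure: label swap did not change the topology")
  }
  list(true = tr, alt = alt, aln = aln, model = m)
}

test_that("site-wise matrices are bookkept correctly", {
  fx <- make_two_tree_fixture()
  sw <- sitewise_matrix(list(a = fx$true, b = fx$true), fx$aln, fx$model)
  # duplicate tree: identical rows
  expect_equal(sw$matrix[1, ], sw$matrix[2, ], tolerance = 1e-9)
  # row sums equal independently recomputed totals on the optimized trees
  for (nm in c("a", "b")) {
    tot <- attr(site_loglik(sw$trees[[nm]], fx$aln, fx$model), "total")
    expect_equal(unname(sw$totals[nm]), tot, tolerance = 1e-8)
  }
  expect_error(sitewise_matrix(list(fx$true, restrict_to_taxa(
    fx$true, fx$true$tip.label[1:4])), fx$aln, fx$model), "mismatch")
})

test_that("per-site values match single-site recomputation", {
  fx <- make_two_tree_fixture(seed = 45, L = 40)
  sw <- sitewise_matrix(list(a = fx$true, b = fx$alt), fx$aln, fx$model)
  tr_opt <- sw$trees$a
  for (j in c(1, 7, 23)) {
    one <- partitioned_alignment(fx$aln$matrix[, j, drop = FALSE])
    expect_equal(unname(sw$matrix["a", j]),
                 as.numeric(site_loglik(tr_opt, one, fx$model)),
                 tolerance = 1e-9)
  }
})

test_that("RELL resampling: identity indices, determinism, CLT consistency", {
  set.seed(10)
  M <- matrix(rnorm(3 * 50, -2), 3, 50)
  # forced identity resample reproduces the row sums exactly
  tt <- rell_bootstrap(M, B = 1, .indices = list(1:50))
  expect_equal(as.numeric(tt), rowSums(M), tolerance = 1e-12)
  expect_identical(rell_bootstrap(M, B = 25, seed = 3),
                   rell_bootstrap(M, B = 25, seed = 3))
  # replicate totals are direct sums over the resampled columns
  ix <- c(5, 5, 1, 50, 17)
  t2 <- rell_bootstrap(M, B = 1, .indices = list(ix))
  expect_equal(as.numeric(t2), rowSums(M[, ix]), tolerance = 1e-12)
  # mean of replicate totals within 3 SE of the original totals
  B <- 4000
  tb <- rell_bootstrap(M, B = B, seed = 9)
  for (k in 1:3) {
    se <- stats::sd(tb[, k]) / sqrt(B)
    expect_lt(abs(mean(tb[, k]) - sum(M[k, ])), 3 * se + 1e-9)
  }
})

test_that("a site-wise dominant tree gets the degenerate-high AU p", {
  M <- rbind(best = rep(-1, 80), worse = rep(-1.4, 80), worst = rep(-2, 80))
  au <- au_test(M, B_per_scale = 500, seed = 2)
  expect_true(all(au$degenerate))
  expect_gte(au$au_p[1], 1 - 1 / (2 * 500))
  expect_lte(au$au_p[2], 1 / (2 * 500))
  expect_lte(au$au_p[3], 1 / (2 * 500))
})

test_that("AU p-values are invariant to per-site constant shifts", {
  set.seed(6)
  M <- matrix(rnorm(2 * 150, -3), 2, 150)
  shift <- rnorm(150, 0, 5)
  M2 <- M + rbind(shift, shift)
  a1 <- au_test(M, B_per_scale = 800, seed = 11)
  a2 <- au_test(M2, B_per_scale = 800, seed = 11)
  expect_equal(a1$au_p, a2$au_p, tolerance = 1e-10)
})

test_that("AU and KH agree on ordering for a decided comparison", {
  fx <- make_two_tree_fixture(seed = 46, L = 1500)
  sw <- sitewise_matrix(list(true = fx$true, alt = fx$alt), fx$aln, fx$model)
  expect_gt(sw$totals[["true"]], sw$totals[["alt"]])
  au <- au_test(sw, B_per_scale = 2000, seed = 12)
  expect_gt(au$au_p[au$tree == "true"], au$au_p[au$tree == "alt"])
  kh <- kh_test(sw$matrix[c("true", "alt"), ], B = 2000, seed = 13)
  expect_lt(kh, 0.5)
})

test_that("compare_restricted reports likelihoods, AU and the consensus", {
  fx <- make_two_tree_fixture(seed = 47, L = 1200)
  # identical trees: zero difference, consensus is the tree itself
  same <- compare_restricted(fx$true, fx$true, fx$aln, fx$model,
                             B_per_scale = 300, seed = 3)
  expect_equal(same$difference, 0, tolerance = 1e-6)
  expect_identical(tree_splits(same$consensus), tree_splits(fx$true))

  # true tree vs NNI rival on strong data: positive difference, AU rejects
  cmp <- compare_restricted(fx$true, fx$alt, fx$aln, fx$model,
                            B_per_scale = 2000, seed = 4)
  expect_gt(cmp$difference, 0)
  expect_lt(cmp$au$au_p[cmp$au$tree == "b"], 0.05)
  expect_gt(cmp$au$au_p[cmp$au$tree == "a"], 0.05)
})

test_that("the per-site table round-trips through the export format", {
  fx <- make_two_tree_fixture(seed = 48, L = 30)
  sw <- sitewise_matrix(list(x = fx$true, y = fx$alt), fx$aln, fx$model)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sitewise(sw, f)
  back <- read_sitewise(f)
  expect_equal(unname(back$matrix), unname(sw$matrix), tolerance = 1e-6)
})
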