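test_that("perfectly linear pairs are included with plateau ratio ~ 1", {
  x <- seq(0.05, 1.2, length.out = 40)
  pairs <- data.frame(x = x, y = 0.9 * x)
  as <- assess_saturation(pairs)
  expect_identical(as$decision, "include")
  expect_equal(as$plateau_ratio, 1, tolerance = 1e-9)
  expect_equal(as$slope, 0.9, tolerance = 1e-9)
  expect_equal(as$r_squared, 1, tolerance = 1e-9)
})

test_that("a saturating curve is excluded by the plateau rule", {
  x <- seq(0.05, 3, length.out = 60)
  pairs <- data.frame(x = x, y = 0.75 * (1 - exp(-2 * x)))
  as <- assess_saturation(pairs)
  # closed-form OLS on the analytic curve: upper-half slope collapses
  ols <- function(x, y) stats::cov(x, y) / stats::var(x)
  lo <- x <= stats::median(x)
  expect_equal(as$plateau_ratio, ols(x[!lo], pairs$y[!lo]) /
                 ols(x[lo], pairs$y[lo]), tolerance = 1e-9)
  expect_lt(as$plateau_ratio, 0.5)
  expect_identical(as$decision, "exclude")
})

test_that("the decision is invariant to uniform branch-length rescaling", {
  x <- seq(0.05, 1.5, length.out = 30)
  y <- 0.8 * x + 0.01
  for (s in c(0.2, 1, 7)) {
    as <- assess_saturation(data.frame(x = s * x, y = s * y))
    expect_identical(as$decision, "include")
    expect_equal(as$plateau_ratio, 1, tolerance = 1e-6)
  }
})

test_that("zero x-variance yields a degenerate include", {
  as <- assess_saturation(data.frame(x = rep(0.3, 10), y = runif(10)))
  expect_identical(as$decision, "include")
  expect_true(as$degenerate)
})

test_that("pairs generated from the same tree (x = y) are always included", {
  st <- make_placement_study(single_marker_config(seed = 12, L = 1500))
  pr <- saturation_pairs(st$alignment, "g1")
  as <- assess_saturation(data.frame(x = pr$y, y = pr$y))
  expect_identical(as$decision, "include")
  expect_equal(as$plateau_ratio, 1, tolerance = 1e-9)
})

test_that("saturation pairs equal hand-computed path sums on a 4-taxon fixture", {
  # two haploid sequences pairs with known additive structure: build an
  # alignment whose NJ trees are exact, then compare patristic sums
  st <- make_placement_study(single_marker_config(seed = 3, n_leaves = 6,
                                                  L = 2000))
  pr <- saturation_pairs(st$alignment, "g1", min_sites = 10)
  Dm <- attr(pr, "patristic_model")
  Dp <- attr(pr, "patristic_p")
  for (i in seq_len(nrow(pr))) {
    expect_equal(pr$x[i], Dm[pr$taxon_i[i], pr$taxon_j[i]])
    expect_equal(pr$y[i], Dp[pr$taxon_i[i], pr$taxon_j[i]])
  }
  expect_equal(nrow(pr), choose(length(attr(pr, "taxa")), 2))
})

test_that("taxa below min_sites are excluded from both trees symmetrically", {
  st <- make_placement_study(single_marker_config(seed = 13, L = 800))
  aln <- st$alignment
  aln$matrix["t03", seq_len(760)] <- "?"
  pr <- saturation_pairs(aln, "g1", min_sites = 50)
  expect_false("t03" %in% attr(pr, "taxa"))
  expect_false(any(pr$taxon_i == "t03" | pr$taxon_j == "t03"))
  expect_warning(saturation_pairs(rand_aln(c("a", "b", "c", "d"), 30,
                                           seed = 1), "all",
                                  min_sites = 50), "fewer than 4")
})

test_that("homogeneous partitions yield no outliers; injected ones are flagged", {
  st <- make_placement_study(single_marker_config(seed = 14, L = 1200))
  pr <- saturation_pairs(st$alignment, "g1")
  expect_identical(nrow(detect_outliers(pr)), 0L)

  bad <- inject_outlier(st$alignment, "t04", "g1", seed = 15)
  pr2 <- saturation_pairs(bad, "g1")
  fl <- detect_outliers(pr2)
  expect_identical(fl$taxon, "t04")
})

test_that("injected outliers have ~0.75 expected mismatch and local effect", {
  st <- make_placement_study(synthetic_study_config(seed = 16))
  bad <- inject_outlier(st$alignment, "t02", "rrna_like", seed = 17)
  p <- bad$partitions$rrna_like
  pd <- p_distance(bad$matrix["t02", p$sites], bad$matrix["t07", p$sites])
  expect_gt(pd, 0.68); expect_lt(pd, 0.82)
  other <- setdiff(seq_len(ncol(bad$matrix)), p$sites)
  expect_identical(bad$matrix[, other], st$alignment$matrix[, other])
})

test_that("screening one fixture excludes the planted units and masks them", {
  st <- make_placement_study(synthetic_study_config(seed = 18))
  sc <- screen_partitions(st$alignment)
  excluded <- sort(sc$report$unit[sc$report$decision == "exclude"])
  expect_identical(excluded, c("cytb_like_pos3", "nd2_like_pos3"))
  # masked in the filtered matrix, and dropped from retained partitions
  u <- split_codon_positions(st$alignment, "cytb_like")$cytb_like_pos3
  expect_true(all(sc$filtered$matrix[, u$sites] == "?"))
  expect_false("cytb_like_pos3" %in% names(sc$filtered$partitions))
  expect_true("cytb_like_pos1" %in% names(sc$filtered$partitions))
})

test_that("an outlier's exclusion is local to the flagged marker", {
  st <- make_placement_study(synthetic_study_config(
    seed = 19, outlier_taxon = "t06", outlier_partition = "rrna_like"))
  sc <- screen_partitions(st$alignment)
  expect_true(all(sc$outliers$unit == "rrna_like"))
  expect_identical(unique(sc$outliers$taxon), "t06")
  # rrna block masked for t06 only; its other markers retained
  p <- st$alignment$partitions$rrna_like
  expect_true(all(sc$filtered$matrix["t06", p$sites] == "?"))
  p2 <- st$alignment$partitions$rag1_like
  expect_false(all(sc$filtered$matrix["t06", p2$sites] == "?"))
  # the marker itself stays included once the outlier is removed
  expect_identical(
    sc$report$decision[sc$report$unit == "rrna_like"], "include")
})
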