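test_that("model construction scales the rate matrix to mean rate 1", {
  m <- subst_model_hky(4, c(0.3, 0.2, 0.2, 0.3), alpha = 0.5)
  expect_equal(sum(m$freqs * diag(m$Q)), -1)
  expect_equal(unname(rowSums(m$Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(mean(m$cat_rates), 1, tolerance = 1e-10)
  expect_error(subst_model(rep(1, 6), c(0.5, 0.5, 0.1, 0.1)), "sum to 1")

  # transition matrices agree with an independent matrix exponential
  for (t in c(0.01, 0.1, 1, 5)) {
    P <- prob_matrix(m, t)
    for (c in seq_len(m$ncat)) {
      expect_equal(P[, , c],
                   expm_oracle(unclass(m$Q) * t * m$cat_rates[c]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("discrete Gamma with one category equals no heterogeneity", {
  m1 <- subst_model_jc(alpha = 0.7, ncat = 1L)
  mInf <- subst_model_jc(alpha = Inf)
  expect_identical(m1$cat_rates, 1)
  tr <- parse_newick("(A:0.2,B:0.1);")
  aln <- rand_aln(c("A", "B"), 40, seed = 2)
  expect_equal(site_loglik(tr, aln, m1), site_loglik(tr, aln, mInf),
               tolerance = 1e-12)
})

test_that("pruning log-likelihood matches two-taxon closed forms", {
  m <- subst_model_jc()
  # identical determinate site at t = 0: log(1/4) by stationarity
  same <- partitioned_alignment(matrix("A", 2, 1,
                                       dimnames = list(c("A", "B"), NULL)))
  expect_equal(as.numeric(site_loglik(parse_newick("(A:0,B:0);"), same, m)),
               log(0.25), tolerance = 1e-12)
  # differing states at distance t: log(pi * (1/4 - exp(-4t/3)/4))
  diffc <- partitioned_alignment(matrix(c("A", "C"), 2, 1,
                                        dimnames = list(c("A", "B"), NULL)))
  t <- 0.37
  tr <- parse_newick(sprintf("(A:%f,B:%f);", t / 2, t / 2))
  expect_equal(as.numeric(site_loglik(tr, diffc, m)),
               log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3))), tolerance = 1e-10)
})

test_that("pruning equals the exhaustive-state oracle on 3-5 leaf trees", {
  models <- list(subst_model_jc(),
                 subst_model_hky(4, c(0.3, 0.2, 0.2, 0.3), alpha = 0.7),
                 subst_model(c(1.2, 3.5, 0.8, 1.1, 4.2, 1),
                             c(0.28, 0.22, 0.24, 0.26), alpha = 0.4))
  fixtures <- list(
    parse_newick("((A:0.1,B:0.3):0.05,C:0.2);"),
    parse_newick("((A:0.1,B:0.23):0.08,(C:0.3,D:0.12):0.05);"),
    parse_newick("(((A:0.1,B:0.2):0.05,C:0.3):0.07,(D:0.15,E:0.25):0.12);"))
  for (tr in fixtures) {
    aln <- rand_aln(tr$tip.label, 20, seed = ape::Ntip(tr))
    for (m in models) {
      ll <- site_loglik(tr, aln, m)
      oracle <- vapply(seq_len(20), function(j) {
        brute_site_loglik(tr, as.list(stats::setNames(aln$matrix[, j],
                                                      rownames(aln$matrix))),
                          m)
      }, 0)
      expect_lt(max(abs(ll - oracle)), 1e-8)
    }
  }
})

test_that("site likelihoods over all 4^n patterns sum to one", {
  m <- subst_model_hky(3, c(0.35, 0.15, 0.2, 0.3), alpha = 0.6)
  for (tr in list(parse_newick("((A:0.1,B:0.3):0.05,C:0.2);"),
                  parse_newick("((A:0.1,B:0.23):0.08,(C:0.3,D:0.12):0.05);"))) {
    aln <- all_patterns_alignment(tr$tip.label)
    expect_equal(sum(exp(site_loglik(tr, aln, m))), 1, tolerance = 1e-10)
  }
})

test_that("pruning matches phangorn's likelihood on a GTR+Gamma fixture", {
  tr <- random_bl_tree(6, seed = 8)
  m <- subst_model(c(1.5, 4, 0.7, 1.2, 5, 1), c(0.3, 0.2, 0.2, 0.3),
                   alpha = 0.5, ncat = 4L)
  aln <- simulate_alignment(tr, m, 300, seed = 9)
  ll <- attr(site_loglik(tr, aln, m), "total")
  pd <- phangorn::phyDat(aln$matrix)
  # phangorn's GTR rate order matches (AC, AG, AT, CG, CT, GT); Q normalised
  fit <- phangorn::pml(tr, pd, bf = m$freqs, Q = unname(m$rates),
                       shape = 0.5, k = 4)
  expect_equal(ll, as.numeric(fit$logLik), tolerance = 1e-4)
})

test_that("branch-length optimization reaches the pairwise ML fixed point", {
  mat <- rbind(A = c(rep("A", 3), "C"), B = rep("A", 4))
  aln <- partitioned_alignment(mat)
  ob <- optimize_branch_lengths(parse_newick("(A:0.1,B:0.1);"), aln,
                                subst_model_jc())
  expect_equal(sum(ob$tree$edge.length), -0.75 * log(1 - 1 / 3),
               tolerance = 1e-5)

  # identical sequences: all lengths at the lower bound
  same <- partitioned_alignment(matrix("A", 2, 5,
                                       dimnames = list(c("A", "B"), NULL)))
  os <- optimize_branch_lengths(parse_newick("(A:0.1,B:0.1);"), same,
                                subst_model_jc())
  expect_true(all(os$tree$edge.length <= 1e-7))

  # re-optimizing at the optimum is a fixed point
  ob2 <- optimize_branch_lengths(ob$tree, aln, subst_model_jc())
  expect_lt(abs(ob2$loglik - ob$loglik), 1e-5)
  expect_gte(ob2$loglik, ob$loglik - 1e-9)
})

test_that("fit_model recovers simulation parameters", {
  set.seed(3)
  tr <- ape::unroot(ape::rtree(6, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.25)
  m <- subst_model_hky(4, c(A = .3, C = .2, G = .2, T = .3), alpha = 0.5)
  aln <- simulate_alignment(tr, m, 20000, seed = 21)
  fit <- fit_model(aln, tr, family = "HKY")
  kappa_hat <- fit$rates[["AG"]] / fit$rates[["AC"]]
  expect_gt(kappa_hat, 3.2); expect_lt(kappa_hat, 4.8)
  expect_gt(fit$alpha, 0.35); expect_lt(fit$alpha, 0.7)

  # JC data: near-equal GTR exchangeabilities, large alpha
  aj <- simulate_alignment(tr, subst_model_jc(), 10000, seed = 22)
  fj <- fit_model(aj, tr, family = "GTR")
  rel <- fj$rates / fj$rates[["GT"]]
  expect_true(all(rel > 0.7 & rel < 1.4))
  expect_gt(fj$alpha, 10)

  # degenerate alignment falls back to a JC-like model with a warning
  const <- partitioned_alignment(matrix("A", 3, 30,
                                        dimnames = list(c("t1", "t2", "t3"),
                                                        NULL)))
  expect_warning(fc <- fit_model(const, parse_newick("((t1:1,t2:1):1,t3:1);")),
                 "JC-like")
  expect_true(all(fc$rates == fc$rates[1]))
})
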