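# Independent oracles and small fixture builders shared across tests.

# matrix exponential independent of the package's eigen route
expm_oracle <- function(Q) as.matrix(Matrix::expm(Matrix::Matrix(Q)))

# brute-force tree likelihood: explicit product of transition probabilities,
# summing over internal-node state assignments via the pruning recursion but
# with independently computed transition matrices
brute_site_loglik <- function(tree, col, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 15L, "?" = 15L, N = 15L)
  tipp <- function(ch) {
    b <- bits[[ch]]
    as.numeric(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)
  }
  tot <- 0
  for (cat in seq_len(model$ncat)) {
    r <- model$cat_rates[cat] * model$rate_mult
    part <- vector("list", nn)
    for (i in seq_len(ntip)) part[[i]] <- tipp(col[[tr$tip.label[i]]])
    for (i in (ntip + 1):nn) part[[i]] <- rep(1, 4)
    for (e in seq_len(nrow(tr$edge))) {
      pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      P <- expm_oracle(unclass(model$Q) * tr$edge.length[e] * r)
      part[[pa]] <- part[[pa]] * as.vector(P %*% part[[ch]])
    }
    tot <- tot + sum(model$freqs * part[[ntip + 1]]) / model$ncat
  }
  log(tot)
}

# all-pattern matrix over the DNA alphabet for n taxa (4^n columns)
all_patterns_alignment <- function(taxa) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), length(taxa)),
                   stringsAsFactors = FALSE)
  m <- t(as.matrix(g))
  rownames(m) <- taxa
  partitioned_alignment(m)
}

random_bl_tree <- function(n, seed, lo = 0.02, hi = 0.3) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), lo, hi)
  tr
}

rand_aln <- function(taxa, L, seed, chars = c("A", "C", "G", "T", "-", "N"),
                     prob = c(.2, .2, .2, .2, .1, .1)) {
  set.seed(seed)
  m <- matrix(sample(chars, length(taxa) * L, TRUE, prob), length(taxa), L,
              dimnames = list(taxa, NULL))
  partitioned_alignment(m)
}

# single-partition study used by placement tests: one marker, moderate rates
single_marker_config <- function(seed, n_leaves = 10L, L = 5000L) {
  synthetic_study_config(
    n_leaves = n_leaves, seed = seed,
    partitions = list(list(name = "g1", origin = "nuclear", coding = FALSE,
                           length = as.integer(L), kappa = 4,
                           freqs = c(A = .3, C = .2, G = .2, T = .3),
                           alpha = 1, ncat = 4L, pos_rates = 1.0)))
}

split_key_of <- function(set, leaves) treeplacer:::split_key(set, leaves)
edge_keys_of <- function(tree) treeplacer:::edge_split_keys(tree)

`%||%` <- function(a, b) if (is.null(a)) b else a
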