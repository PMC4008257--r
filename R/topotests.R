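#' Site-wise log-likelihood matrix for candidate trees
#'
#' Branch lengths are optimized independently per tree on the fixed alignment;
#' rows are trees, columns sites, all on the same site order, and each row sum
#' equals the tree's optimized total log-likelihood.
#'
#' @param trees list of `phylo` (or `multiPhylo`) on the alignment's taxa.
#' @param aln a [partitioned_alignment()].
#' @param models a [subst_model()] or named list per partition.
#' @param optimize_bl re-optimize branch lengths per tree first?
#' @return a `sitewise_loglik` object: list with `matrix` (trees x sites),
#'   `totals`, `trees` (optimized), and `partitions` (site index sets, for
#'   stratified resampling).
#' @export
sitewise_matrix <- function(trees, aln, models, optimize_bl = TRUE) {
  trees <- unclass(trees)
  stopifnot(length(trees) >= 2L)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- paste0("tree", seq_along(trees))
  }
  base <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), base)) stop("leaf-set mismatch")
  }
  L <- ncol(aln$matrix)
  M <- matrix(0, length(trees), L, dimnames = list(names(trees), NULL))
  fitted <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (optimize_bl || is.null(tr$edge.length)) {
      tr <- optimize_branch_lengths(tr, aln, models, tol = 1e-6,
                                    max_sweeps = 12L)$tree
    }
    M[i, ] <- site_loglik(tr, aln, models)
    fitted[[names(trees)[i]]] <- tr
  }
  structure(list(matrix = M, totals = rowSums(M), trees = fitted,
                 partitions = lapply(aln$partitions, `[[`, "sites")),
            class = "sitewise_loglik")
}

#' Write/read the per-site table format
#'
#' Tab-separated sites x trees table with a header row of tree labels.
#'
#' @param sw a `sitewise_loglik` (or bare matrix, trees x sites).
#' @param path file path.
#' @return `write_sitewise()` returns `path`; `read_sitewise()` a
#'   `sitewise_loglik`.
#' @export
write_sitewise <- function(sw, path) {
  M <- if (inherits(sw, "sitewise_loglik")) sw$matrix else sw
  utils::write.table(t(M), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sitewise
#' @export
read_sitewise <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  M <- t(as.matrix(df))
  structure(list(matrix = M, totals = rowSums(M), trees = NULL,
                 partitions = list(all = seq_len(ncol(M)))),
            class = "sitewise_loglik")
}

# resolve matrix + partition strata from the first argument
.sw_parts <- function(sw, partitions) {
  M <- if (inherits(sw, "sitewise_loglik")) sw$matrix else as.matrix(sw)
  if (is.null(partitions)) {
    partitions <- if (inherits(sw, "sitewise_loglik")) sw$partitions
    else list(seq_len(ncol(M)))
  }
  list(M = M, partitions = partitions)
}

#' RELL bootstrap of site-wise log-likelihoods
#'
#' Resamples site indices with replacement (within partitions when given) and
#' sums log-likelihood columns per tree — no re-optimization.
#'
#' @param sw a `sitewise_loglik` or a trees x sites matrix.
#' @param B replicate count.
#' @param seed integer seed.
#' @param partitions optional list of site index vectors for stratified
#'   resampling (defaults to the object's own partitions).
#' @param .indices list of fixed site-index vectors overriding the resampling
#'   (testing hook).
#' @return matrix `B` x trees of replicate total log-likelihoods.
#' @export
rell_bootstrap <- function(sw, B, seed = NULL, partitions = NULL,
                           .indices = NULL) {
  sp <- .sw_parts(sw, partitions)
  M <- sp$M
  if (!is.null(.indices)) {
    out <- t(vapply(.indices, function(ix) rowSums(M[, ix, drop = FALSE]),
                    numeric(nrow(M))))
    colnames(out) <- rownames(M)
    return(out)
  }
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, B, nrow(M), dimnames = list(NULL, rownames(M)))
  for (b in seq_len(B)) {
    ix <- unlist(lapply(sp$partitions, function(s) {
      s[sample.int(length(s), length(s), replace = TRUE)]
    }), use.names = FALSE)
    out[b, ] <- rowSums(M[, ix, drop = FALSE])
  }
  out
}

# bootstrap proportions of each tree being the replicate maximum at one scale
# (ties split equally); vectorised over replicates in blocks
.bp_at_scale <- function(M, m, B, block = 500L) {
  ntree <- nrow(M); n <- ncol(M)
  wins <- numeric(ntree)
  done <- 0L
  while (done < B) {
    nb <- min(block, B - done)
    ix <- sample.int(n, m * nb, replace = TRUE)
    tot <- matrix(0, nb, ntree)
    for (k in seq_len(ntree)) {
      tot[, k] <- colSums(matrix(M[k, ix], m, nb))
    }
    mx <- do.call(pmax, as.data.frame(tot))
    ismax <- tot >= mx - 1e-10
    wins <- wins + colSums(ismax / rowSums(ismax))
    done <- done + nb
  }
  wins / B
}

#' Approximately unbiased (AU) topology test
#'
#' Multiscale RELL bootstrap: at each scale `r`, `ceiling(r * n)` sites are
#' resampled and the proportion of replicates in which each tree attains the
#' maximum total is recorded (ties split equally). Per tree, the normal
#' quantiles `z(r) = qnorm(1 - BP(r))` are regressed on `(sqrt(r), 1/sqrt(r))`
#' by weighted least squares to estimate the signed distance `d` and curvature
#' `c`; the AU p-value is `1 - pnorm(d - c)`. Proportions of exactly 0 or 1
#' are continuity-corrected to `1/(2B)` and `1 - 1/(2B)`; trees with fewer
#' than 3 informative scales get a degenerate p of 0 or 1 with a flag.
#'
#' @param sw a `sitewise_loglik` or trees x sites matrix.
#' @param scales relative resampling scales.
#' @param B_per_scale replicates per scale.
#' @param seed integer seed.
#' @param partitions optional strata for resampling (currently pooled across
#'   partitions at scaled size, matching standard multiscale practice).
#' @return an `au_result`: data frame with per-tree `au_p`, `bp` (naive
#'   proportion at scale 1), `d`, `c`, `degenerate`; the per-scale proportions
#'   are attached as attribute `bp_matrix`.
#' @export
au_test <- function(sw, scales = seq(0.5, 1.4, by = 0.1), B_per_scale = 10000L,
                    seed = NULL, partitions = NULL) {
  sp <- .sw_parts(sw, partitions)
  M <- sp$M
  ntree <- nrow(M); n <- ncol(M)
  stopifnot(ntree >= 2L)
  if (!is.null(seed)) set.seed(seed)
  BP <- matrix(0, length(scales), ntree,
               dimnames = list(sprintf("r=%.2f", scales), rownames(M)))
  for (i in seq_along(scales)) {
    m <- max(1L, as.integer(ceiling(scales[i] * n)))
    BP[i, ] <- .bp_at_scale(M, m, B_per_scale)
  }
  eps <- 1 / (2 * B_per_scale)
  i1 <- which.min(abs(scales - 1))
  res <- data.frame(tree = rownames(M) %||% paste0("tree", seq_len(ntree)),
                    au_p = NA_real_, bp = BP[i1, ], d = NA_real_,
                    c = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_len(ntree)) {
    bp <- BP[, k]
    informative <- bp > 0 & bp < 1
    bpc <- pmin(pmax(bp, eps), 1 - eps)
    if (sum(informative) < 3L) {
      res$degenerate[k] <- TRUE
      res$au_p[k] <- if (mean(bpc) >= 0.5) 1 - eps else eps
      next
    }
    use <- informative
    z <- stats::qnorm(1 - bpc[use])
    r <- scales[use]
    X <- cbind(sqrt(r), 1 / sqrt(r))
    wls <- B_per_scale * stats::dnorm(z)^2 / (bpc[use] * (1 - bpc[use]))
    fit <- stats::lm.wfit(X, z, wls)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    res$d[k] <- d; res$c[k] <- cc
    res$au_p[k] <- 1 - stats::pnorm(d - cc)
  }
  attr(res, "bp_matrix") <- BP
  attr(res, "scales") <- scales
  attr(res, "B_per_scale") <- B_per_scale
  class(res) <- c("au_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.au_result <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[order(-df$au_p), ]
  df$rank <- seq_len(nrow(df))
  cat("AU test (multiscale RELL bootstrap)\n")
  print(df[, c("rank", "tree", "au_p", "bp", "degenerate")], row.names = FALSE)
  invisible(x)
}

#' Write a ranked AU report as tab-separated text
#'
#' @param au an `au_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_au_report <- function(au, path) {
  df <- as.data.frame(au)
  df <- df[order(-df$au_p), c("tree", "au_p", "bp", "degenerate")]
  df$rank <- seq_len(nrow(df))
  utils::write.table(df[, c("rank", "tree", "au_p", "bp", "degenerate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare two trees restricted to common taxa
#'
#' Optimizes both trees on the alignment, reports their total log-likelihoods
#' and difference, the two-tree AU p-values, and the strict consensus.
#'
#' @param tree_a,tree_b `phylo` objects on identical leaf sets (use
#'   [restrict_to_taxa()] first if needed).
#' @param aln a [partitioned_alignment()].
#' @param models a [subst_model()] or named list per partition.
#' @param B_per_scale,seed AU test controls.
#' @return list with `loglik_a`, `loglik_b`, `difference` (a minus b), `au`
#'   (an `au_result`) and `consensus`.
#' @export
compare_restricted <- function(tree_a, tree_b, aln, models,
                               B_per_scale = 10000L, seed = NULL) {
  if (!identical(sort(tree_a$tip.label), sort(tree_b$tip.label))) {
    stop("leaf-set mismatch: restrict both trees to the common taxa first")
  }
  sw <- sitewise_matrix(list(a = tree_a, b = tree_b), aln, models)
  au <- au_test(sw, B_per_scale = B_per_scale, seed = seed)
  list(loglik_a = sw$totals[["a"]], loglik_b = sw$totals[["b"]],
       difference = sw$totals[["a"]] - sw$totals[["b"]],
       au = au, consensus = strict_consensus(list(tree_a, tree_b)))
}

#' One-sided Kishino-Hasegawa style p-value for two trees
#'
#' Normal approximation on the RELL distribution of the per-site
#' log-likelihood difference; auxiliary to [au_test()].
#'
#' @param sw a `sitewise_loglik` or 2 x sites matrix.
#' @param B replicates.
#' @param seed integer seed.
#' @return p-value for the hypothesis that the first tree is not better.
#' @export
kh_test <- function(sw, B = 10000L, seed = NULL) {
  sp <- .sw_parts(sw, NULL)
  M <- sp$M
  stopifnot(nrow(M) == 2L)
  rep_tot <- rell_bootstrap(M, B, seed = seed,
                            partitions = list(seq_len(ncol(M))))
  delta <- rep_tot[, 1] - rep_tot[, 2]
  dc <- delta - mean(delta)          # centred null
  obs <- sum(M[1, ] - M[2, ])
  mean(dc >= obs)
}
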