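# ---- encoding and pattern compression --------------------------------------

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L,
                N = 15L, "-" = 15L, "?" = 15L)

# character matrix -> integer bitmask matrix (same shape); unknown chars are
# treated as fully missing
tp_encode <- function(mat) {
  codes <- IUPAC_BITS[mat]
  codes[is.na(codes)] <- 15L
  matrix(as.integer(codes), nrow(mat), ncol(mat), dimnames = dimnames(mat))
}

# site-pattern compression over the rows of a code matrix (taxa x sites).
# Returns tipcode (npat x ntaxa, the C++ layout), weights, and the site ->
# pattern map.
tp_patterns <- function(codes) {
  if (ncol(codes) == 0L) stop("no sites")
  key <- do.call(paste, c(as.data.frame(t(codes)), sep = ","))
  f <- factor(key, levels = unique(key))
  map <- as.integer(f)
  first <- match(levels(f), key)
  list(tipcode = t(codes[, first, drop = FALSE]),
       weights = as.numeric(tabulate(map, nbins = length(first))),
       map = map)
}

# ---- tree indexing for the C++ kernels --------------------------------------

# postorder edge table with 0-based ids (tips 0..ntip-1, root = ntip)
tp_index <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree,
       edges0 = tree$edge - 1L,
       lengths = tree$edge.length,
       nnode = ape::Ntip(tree) + tree$Nnode,
       ntip = ape::Ntip(tree))
}

# flat transition-probability stack for all edges of an indexed tree
tp_pstack <- function(model, lengths) {
  do.call(c, lapply(lengths, function(t) tp_pflat(model, t)))
}

# normalise the `models` argument: a single subst_model is recycled over all
# partitions; otherwise a named list keyed by partition name
tp_models <- function(aln, models) {
  pn <- names(aln$partitions)
  if (inherits(models, "subst_model")) {
    out <- stats::setNames(rep(list(models), length(pn)), pn)
    return(out)
  }
  if (!all(pn %in% names(models))) {
    stop("models must be named for every partition: ",
         paste(setdiff(pn, names(models)), collapse = ", "))
  }
  models[pn]
}

# per-partition likelihood engine data for a fixed taxon order
tp_engine <- function(aln, taxa, models) {
  if (!all(taxa %in% aln$taxa)) {
    stop("taxon in tree absent from alignment: ",
         setdiff(taxa, aln$taxa)[1])
  }
  models <- tp_models(aln, models)
  codes <- tp_encode(aln$matrix[taxa, , drop = FALSE])
  lapply(names(aln$partitions), function(nm) {
    p <- aln$partitions[[nm]]
    pat <- tp_patterns(codes[, p$sites, drop = FALSE])
    list(name = nm, sites = p$sites, model = models[[nm]],
         tipcode = pat$tipcode, weights = pat$weights, map = pat$map)
  })
}

# ---- site-wise log-likelihood -----------------------------------------------

#' Site-wise log-likelihood of a tree
#'
#' Per-site log-likelihoods by Felsenstein pruning under the model(s),
#' averaging over discrete-Gamma rate categories; missing and ambiguous
#' characters contribute the partial likelihood of their IUPAC state set.
#' Site patterns are compressed per partition and expanded on return.
#'
#' @param tree a `phylo` with branch lengths; leaves must be alignment taxa.
#' @param aln a [partitioned_alignment()].
#' @param models a [subst_model()] or named list, one per partition.
#' @return numeric vector of per-site log-likelihoods (alignment site order),
#'   with the total as attribute `total`.
#' @export
site_loglik <- function(tree, aln, models) {
  idx <- tp_index(tree)
  eng <- tp_engine(aln, idx$tree$tip.label, models)
  out <- numeric(ncol(aln$matrix))
  for (e in eng) {
    P <- tp_pstack(e$model, idx$lengths)
    ll <- cpp_site_loglik(idx$edges0, idx$nnode, e$tipcode, P,
                          e$model$freqs, e$model$ncat)
    out[e$sites] <- ll[e$map]
  }
  attr(out, "total") <- sum(out)
  out
}

# total log-likelihood from prebuilt engines (internal fast path)
tp_total_loglik <- function(idx, eng) {
  tot <- 0
  for (e in eng) {
    P <- tp_pstack(e$model, idx$lengths)
    ll <- cpp_site_loglik(idx$edges0, idx$nnode, e$tipcode, P,
                          e$model$freqs, e$model$ncat)
    tot <- tot + sum(ll * e$weights)
  }
  tot
}

# ---- branch-length optimization ---------------------------------------------

#' Optimize branch lengths on a fixed topology
#'
#' Round-robin Brent optimization of one branch at a time, using cached
#' conditional likelihoods for the rest of the tree, until the total
#' log-likelihood improves by less than `tol` in a sweep. The log-likelihood
#' is non-decreasing across sweeps by construction.
#'
#' @param tree a `phylo`; missing branch lengths are initialised to 0.1.
#' @param aln a [partitioned_alignment()].
#' @param models a [subst_model()] or named list per partition.
#' @param tol convergence tolerance in log-likelihood units.
#' @param max_sweeps maximum optimization sweeps.
#' @param bounds branch-length search interval.
#' @return list with elements `tree` (updated lengths), `loglik`, `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, models, tol = 1e-6,
                                    max_sweeps = 20L, bounds = c(1e-8, 10)) {
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tree$edge.length[tree$edge.length < bounds[1]] <- bounds[1]
  idx <- tp_index(tree)
  eng <- tp_engine(aln, idx$tree$tip.label, models)
  nedge <- nrow(idx$edges0)
  ll_old <- tp_total_loglik(idx, eng)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    for (ei in seq_len(nedge)) {
      v <- idx$edges0[ei, 2]
      parts <- lapply(eng, function(e) {
        P <- tp_pstack(e$model, idx$lengths)
        cpp_tree_partials(idx$edges0, idx$nnode, e$tipcode, P, e$model$ncat)
      })
      f <- function(t) {
        tot <- 0
        for (k in seq_along(eng)) {
          e <- eng[[k]]
          tot <- tot + cpp_edge_loglik(parts[[k]]$down, parts[[k]]$up, v,
                                       nrow(e$tipcode), e$model$ncat,
                                       tp_pflat(e$model, t), e$model$freqs,
                                       e$weights)
        }
        tot
      }
      opt <- stats::optimize(f, interval = bounds, maximum = TRUE,
                             tol = 1e-8)
      cur <- f(idx$lengths[ei])
      if (opt$objective > cur) idx$lengths[ei] <- opt$maximum
    }
    ll_new <- tp_total_loglik(idx, eng)
    if (ll_new < ll_old - 1e-6) {
      stop("internal error: log-likelihood decreased during branch optimization")
    }
    if (ll_new - ll_old < tol || sweeps >= max_sweeps) break
    ll_old <- ll_new
  }
  out <- idx$tree
  out$edge.length <- idx$lengths
  list(tree = out, loglik = ll_new, sweeps = sweeps)
}

# ---- model fitting ----------------------------------------------------------

#' Fit a substitution model on a fixed topology
#'
#' Base frequencies are set empirically (with a single pseudocount per state);
#' exchangeabilities and the Gamma shape are optimized by coordinate ascent,
#' interleaving branch-length re-optimization.
#'
#' @param aln a [partitioned_alignment()] (fitted on all sites).
#' @param tree a `phylo` over a subset of the alignment's taxa; branch lengths
#'   are (re)estimated.
#' @param family `"JC"`, `"HKY"` or `"GTR"` (the latter two with Gamma rates).
#' @param ncat discrete-Gamma categories.
#' @param rounds coordinate-ascent rounds.
#' @return a [subst_model()] with attributes `tree` (optimized branch
#'   lengths) and `loglik`.
#' @export
fit_model <- function(aln, tree, family = c("HKY", "GTR", "JC"), ncat = 4L,
                      rounds = 3L) {
  family <- match.arg(family)
  mat <- aln$matrix[tree$tip.label, , drop = FALSE]
  obs <- table(factor(mat[mat %in% c("A", "C", "G", "T")],
                      levels = c("A", "C", "G", "T")))
  freqs <- (as.numeric(obs) + 1) / (sum(obs) + 4)
  freqs <- freqs / sum(freqs)
  codes <- tp_encode(mat)
  variable <- any(apply(codes, 2, function(cl) {
    det <- cl[cl %in% c(1L, 2L, 4L, 8L)]
    length(unique(det)) > 1L
  }))
  if (!variable) {
    warning("no variable comparable sites; returning a JC-like model")
    return(subst_model_jc(alpha = Inf))
  }
  mono <- partitioned_alignment(mat)  # fit is on the pooled sites

  mk <- function(par) {
    if (family == "JC") {
      subst_model(rep(1, 6), rep(0.25, 4), alpha = exp(par[1]), ncat = ncat)
    } else if (family == "HKY") {
      subst_model_hky(exp(par[1]), freqs, alpha = exp(par[2]), ncat = ncat)
    } else {
      subst_model(c(exp(par[1:5]), 1), freqs, alpha = exp(par[6]), ncat = ncat)
    }
  }
  par <- switch(family, JC = log(1), HKY = c(log(2), log(1)),
                GTR = c(rep(0, 5), log(1)))
  lower <- rep(log(1e-3), length(par)); upper <- rep(log(100), length(par))

  cur_tree <- tree
  loglik <- -Inf
  for (r in seq_len(rounds)) {
    bl <- optimize_branch_lengths(cur_tree, mono, mk(par), tol = 1e-4,
                                  max_sweeps = 5L)
    cur_tree <- bl$tree
    idx <- tp_index(cur_tree)
    eng <- tp_engine(mono, idx$tree$tip.label, mk(par))
    obj <- function(p) {
      m <- mk(p)
      eng2 <- lapply(eng, function(e) { e$model <- m; e })
      -tp_total_loglik(idx, eng2)
    }
    opt <- stats::optim(par, obj, method = "L-BFGS-B", lower = lower,
                        upper = upper, control = list(maxit = 40))
    par <- opt$par
    loglik <- -opt$value
  }
  bl <- optimize_branch_lengths(cur_tree, mono, mk(par), tol = 1e-6,
                                max_sweeps = 10L)
  model <- mk(par)
  attr(model, "tree") <- bl$tree
  attr(model, "loglik") <- bl$loglik
  model
}
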