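# ---- tree surgery -----------------------------------------------------------

# leaf labels below each node (list indexed by node id)
node_leafsets <- function(tree) {
  idx <- tp_index(tree)
  tr <- idx$tree
  out <- vector("list", idx$nnode)
  for (i in seq_len(idx$ntip)) out[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    out[[par]] <- c(out[[par]], out[[ch]])
  }
  out
}

# leaves on the child side of one edge (edge = row index of tree$edge)
edge_child_leaves <- function(tree, edge) {
  sets <- node_leafsets(tree)
  sort(sets[[tree$edge[edge, 2]]])
}

# canonical split keys of every edge, in edge-row order
edge_split_keys <- function(tree) {
  sets <- node_leafsets(tree)
  leaves <- tree$tip.label
  vapply(seq_len(nrow(tree$edge)), function(e) {
    split_key(sets[[tree$edge[e, 2]]], leaves)
  }, "")
}

match_edge_by_split <- function(tree, key) {
  hit <- which(edge_split_keys(tree) == key)
  if (length(hit) == 0L) stop("no backbone edge induces the split: ", key)
  hit[1]  # a rooted binary representation duplicates the root edge
}

#' Graft a query tip onto a backbone edge
#'
#' A new internal node subdivides the edge; the fraction of the edge length
#' assigned to the child side is `attach_fraction`, and the query hangs from
#' the new node by `pendant_length`. All other splits are unchanged.
#'
#' @param backbone a `phylo` with branch lengths.
#' @param edge edge row index in `backbone$edge`, or the canonical split key
#'   of the edge (see [tree_splits()]).
#' @param query new tip label (must not already be a leaf).
#' @param attach_fraction position of the new node, in `(0, 1)`, measured as
#'   the child-side share of the edge length.
#' @param pendant_length length of the query's pendant branch.
#' @return the augmented `phylo`.
#' @export
graft <- function(backbone, edge, query, attach_fraction = 0.5,
                  pendant_length = 0.1) {
  if (!(attach_fraction > 0 && attach_fraction < 1)) {
    stop("attach_fraction must be in (0, 1)")
  }
  if (is.character(edge)) edge <- match_edge_by_split(backbone, edge)
  stopifnot(length(edge) == 1L)
  te <- backbone$edge.length[edge]
  graft_lengths(backbone, edge, query, t_child = attach_fraction * te,
                t_parent = (1 - attach_fraction) * te,
                pendant = pendant_length)
}

# graft with explicit child-side / parent-side / pendant lengths
graft_lengths <- function(backbone, edge, query, t_child, t_parent, pendant) {
  tr <- backbone
  if (query %in% tr$tip.label) {
    stop("query label already in backbone: ", query)
  }
  ntip <- ape::Ntip(tr)
  par <- tr$edge[edge, 1]; ch <- tr$edge[edge, 2]
  # renumber: internals shift by +1 (new tip takes id ntip+1),
  # the new internal node gets the last id
  bump <- function(x) ifelse(x > ntip, x + 1L, x)
  E <- cbind(bump(tr$edge[, 1]), bump(tr$edge[, 2]))
  len <- tr$edge.length
  newtip <- ntip + 1L
  newnode <- ntip + 1L + tr$Nnode + 1L
  pb <- bump(par); cb <- bump(ch)
  E[edge, ] <- c(pb, newnode); len[edge] <- t_parent
  E <- rbind(E, c(newnode, cb), c(newnode, newtip))
  len <- c(len, t_child, pendant)
  out <- list(edge = E, edge.length = len,
              tip.label = c(tr$tip.label, query),
              Nnode = tr$Nnode + 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

# ---- placement engines ------------------------------------------------------

# joint site-pattern data over backbone taxa plus query/rogue rows, one entry
# per partition; patterns are compressed over ALL rows so that any subtree's
# tip codes and any extra taxon's codes stay aligned
joint_patterns <- function(aln, base_taxa, extras, models) {
  taxa <- c(base_taxa, extras)
  if (!all(taxa %in% aln$taxa)) {
    stop("taxon absent from alignment: ", setdiff(taxa, aln$taxa)[1])
  }
  models <- tp_models(aln, models)
  codes <- tp_encode(aln$matrix[taxa, , drop = FALSE])
  lapply(names(aln$partitions), function(nm) {
    p <- aln$partitions[[nm]]
    pat <- tp_patterns(codes[, p$sites, drop = FALSE])
    cod <- t(pat$tipcode)            # taxa x npat
    rownames(cod) <- taxa
    list(name = nm, sites = p$sites, model = models[[nm]],
         codes = cod, weights = pat$weights, map = pat$map,
         n_sites = length(p$sites))
  })
}

# transition stacks + conditional likelihoods of one tree for every partition
tree_partials <- function(idx, pats) {
  lapply(pats, function(pp) {
    tipcode <- t(pp$codes[idx$tree$tip.label, , drop = FALSE])
    P <- tp_pstack(pp$model, idx$lengths)
    pr <- cpp_tree_partials(idx$edges0, idx$nnode, tipcode, P, pp$model$ncat)
    list(down = pr$down, up = pr$up, npat = nrow(tipcode))
  })
}

# optimize the three local branch lengths for a query grafted on one edge;
# returns list(loglik, t_child, t_parent, pendant)
optimize_graft <- function(idx, pats, parts, weights, qname, edge_i,
                           mode = c("full", "cheap"),
                           bounds = c(1e-9, 5), sweeps = 2L) {
  mode <- match.arg(mode)
  v <- idx$edges0[edge_i, 2]
  te <- max(idx$lengths[edge_i], 2e-9)
  np <- length(pats)
  qcodes <- lapply(pats, function(pp) as.integer(pp$codes[qname, ]))
  pstack <- function(t) lapply(pats, function(pp) tp_pflat(pp$model, t))
  # per-coordinate evaluation with the two fixed stacks cached
  eval_with <- function(P1s, P2s, Pqs) {
    tot <- 0
    for (k in seq_len(np)) {
      m <- pats[[k]]$model
      tot <- tot + cpp_graft_loglik(parts[[k]]$down, parts[[k]]$up, v,
                                    parts[[k]]$npat, m$ncat, qcodes[[k]],
                                    P1s[[k]], P2s[[k]], Pqs[[k]], m$freqs,
                                    weights[[k]])
    }
    tot
  }
  t1 <- te / 2; t2 <- te / 2; tp <- 0.1
  P1s <- pstack(t1); P2s <- pstack(t2)
  # pendant optimization against the precomputed fixed factor
  brent_tp <- function() {
    gs <- lapply(seq_len(np), function(k) {
      m <- pats[[k]]$model
      cpp_graft_fixed(parts[[k]]$down, parts[[k]]$up, v, parts[[k]]$npat,
                      m$ncat, P1s[[k]], P2s[[k]], m$freqs)
    })
    f <- function(x) {
      tot <- 0
      for (k in seq_len(np)) {
        m <- pats[[k]]$model
        tot <- tot + cpp_pendant_loglik(gs[[k]], qcodes[[k]], tp_pflat(m, x),
                                        weights[[k]], parts[[k]]$npat, m$ncat)
      }
      tot
    }
    stats::optimize(f, interval = bounds, maximum = TRUE,
                    tol = if (mode == "cheap") 1e-3 else 1e-6)
  }
  if (mode == "cheap") {
    o <- brent_tp()
    return(list(loglik = o$objective, t_child = t1, t_parent = t2,
                pendant = o$maximum))
  }
  # one sub-edge against the other's fixed factor
  brent_side <- function(which_var, Pfixs, Pqs) {
    hs <- lapply(seq_len(np), function(k) {
      m <- pats[[k]]$model
      fixed <- if (which_var == "child") parts[[k]]$up else parts[[k]]$down
      cpp_graft_fixed_q(fixed, v, parts[[k]]$npat, m$ncat, Pfixs[[k]],
                        qcodes[[k]], Pqs[[k]], m$freqs)
    })
    f <- function(x) {
      tot <- 0
      for (k in seq_len(np)) {
        m <- pats[[k]]$model
        varside <- if (which_var == "child") parts[[k]]$down else parts[[k]]$up
        tot <- tot + cpp_side_loglik(hs[[k]], varside, v, parts[[k]]$npat,
                                     m$ncat, tp_pflat(m, x), weights[[k]])
      }
      tot
    }
    stats::optimize(f, interval = bounds, maximum = TRUE, tol = 1e-6)$maximum
  }
  for (s in seq_len(sweeps)) {
    tp <- brent_tp()$maximum
    Pqs <- pstack(tp)
    t1 <- brent_side("child", P2s, Pqs)
    P1s <- pstack(t1)
    t2 <- brent_side("parent", P1s, Pqs)
    P2s <- pstack(t2)
  }
  list(loglik = eval_with(P1s, P2s, pstack(tp)), t_child = t1, t_parent = t2,
       pendant = tp)
}

# evaluate the query on every edge of `tree`; weights may override the
# original pattern weights (bootstrap); partials may be precomputed
place_on_tree <- function(tree, pats, qname, weights = NULL, partials = NULL,
                          mode = c("full", "screen"), top_m = 3L) {
  mode <- match.arg(mode)
  idx <- tp_index(tree)
  if (is.null(partials)) partials <- tree_partials(idx, pats)
  if (is.null(weights)) weights <- lapply(pats, `[[`, "weights")
  # a 2-leaf tree is stored rooted: its two edge rows are the same edge
  cand <- which(!duplicated(edge_split_keys(idx$tree)))
  ne <- nrow(idx$edges0)
  if (mode == "full") {
    fits <- lapply(cand, function(e) {
      optimize_graft(idx, pats, partials, weights, qname, e, "full")
    })
  } else {
    fits <- lapply(cand, function(e) {
      optimize_graft(idx, pats, partials, weights, qname, e, "cheap")
    })
    ll <- vapply(fits, `[[`, 0, "loglik")
    top <- order(ll, decreasing = TRUE)[seq_len(min(top_m, length(cand)))]
    for (i in top) {
      fits[[i]] <- optimize_graft(idx, pats, partials, weights, qname,
                                  cand[i], "full")
    }
  }
  tab <- data.frame(
    edge = cand,
    child_node = idx$edges0[cand, 2] + 1L,
    split = edge_split_keys(idx$tree)[cand],
    loglik = vapply(fits, `[[`, 0, "loglik"),
    t_child = vapply(fits, `[[`, 0, "t_child"),
    t_parent = vapply(fits, `[[`, 0, "t_parent"),
    pendant = vapply(fits, `[[`, 0, "pendant"),
    stringsAsFactors = FALSE)
  list(tree = idx$tree, table = tab[order(-tab$loglik), ])
}

#' Constrained ML placement of a query on a backbone
#'
#' For every backbone edge the query is grafted and the three local branch
#' lengths (pendant plus the two sub-edges) are optimized by Brent coordinate
#' sweeps, holding the rest of the tree fixed; edges are returned ranked by
#' log-likelihood.
#'
#' @param backbone a `phylo` with branch lengths (the topological constraint).
#' @param aln a [partitioned_alignment()] containing backbone taxa and query.
#' @param models a [subst_model()] or named list per partition.
#' @param query query taxon label.
#' @return a `placement_result`: list with `table` (one row per edge, ranked),
#'   `best` (top row), `margin` (log-likelihood gap to the runner-up),
#'   `tree` (the postorder backbone the edge indices refer to) and `query`.
#' @export
place_query <- function(backbone, aln, models, query) {
  if (is.null(backbone$edge.length)) stop("backbone needs branch lengths")
  qrow <- aln$matrix[query, ]
  if (!any(qrow %in% c("A", "C", "G", "T"))) {
    stop("query '", query, "' has no determinate site")
  }
  pats <- joint_patterns(aln, backbone$tip.label, query, models)
  res <- place_on_tree(backbone, pats, query, mode = "full")
  tab <- res$table
  margin <- if (nrow(tab) > 1L) tab$loglik[1] - tab$loglik[2] else Inf
  structure(list(table = tab, best = tab[1, ], margin = margin,
                 tree = res$tree, query = query),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("placement of '%s': best edge {%s}\n", x$query, x$best$split))
  cat(sprintf("log-likelihood %.3f, margin to runner-up %.3f\n",
              x$best$loglik, x$margin))
  print(utils::head(x$table[, c("split", "loglik", "pendant")], 5))
  invisible(x)
}

#' Place several queries jointly
#'
#' Queries are inserted sequentially in decreasing order of non-missing site
#' count (ties broken lexicographically); after the last insertion each query
#' is pruned and re-placed once against the augmented tree (one refinement
#' pass, which can only increase the joint likelihood).
#'
#' @inheritParams place_query
#' @param queries character vector of query labels.
#' @return list with `placements` (per-query `placement_result`-like tables on
#'   the tree current at insertion), `tree` (final augmented tree) and
#'   `order` (insertion order).
#' @export
place_multiple <- function(backbone, aln, models, queries) {
  stopifnot(length(queries) >= 1L)
  ndata <- vapply(queries, function(q) {
    sum(aln$matrix[q, ] %in% c("A", "C", "G", "T"))
  }, 0L)
  ord <- queries[order(-ndata, queries)]
  pats <- joint_patterns(aln, backbone$tip.label, ord, models)
  cur <- backbone
  placements <- list()
  for (q in ord) {
    res <- place_on_tree(cur, pats, q, mode = "full")
    best <- res$table[1, ]
    placements[[q]] <- res$table
    cur <- graft_lengths(res$tree, best$edge, q, best$t_child, best$t_parent,
                         best$pendant)
  }
  if (length(ord) > 1L) {
    for (q in ord) {
      pruned <- ape::drop.tip(cur, q)
      res <- place_on_tree(pruned, pats, q, mode = "full")
      best <- res$table[1, ]
      placements[[q]] <- res$table
      cur <- graft_lengths(res$tree, best$edge, q, best$t_child,
                           best$t_parent, best$pendant)
    }
  }
  list(placements = placements, tree = cur, order = ord)
}

# ---- bootstrap tallies ------------------------------------------------------

#' Bootstrap placement tally
#'
#' Sites are resampled with replacement within each retained partition
#' (partition sizes preserved) and the query — together with any designated
#' rogue taxa, which are detached from the backbone and re-placed jointly in
#' every replicate — is re-placed. Each replicate's placement descriptor is
#' the canonical split set of the resulting topology.
#'
#' @inheritParams place_query
#' @param B number of bootstrap replicates.
#' @param seed integer seed (all resampling derives from it).
#' @param rogues labels of rogue taxa to detach and re-place per replicate.
#' @param top_m number of screened edges refined with full three-branch
#'   optimization per insertion.
#' @return a `placement_tally` object; counts sum to `B`.
#' @export
bootstrap_placements <- function(backbone, aln, models, query, B = 100L,
                                 seed, rogues = character(0), top_m = 3L) {
  stopifnot(B >= 1L)
  if (missing(seed)) stop("seed is mandatory")
  rogues <- setdiff(rogues, query)
  base <- if (length(rogues)) ape::drop.tip(backbone, rogues) else backbone
  extras <- c(query, rogues)
  ndata <- vapply(extras, function(q) {
    sum(aln$matrix[q, ] %in% c("A", "C", "G", "T"))
  }, 0L)
  ord <- extras[order(-ndata, extras)]
  pats <- joint_patterns(aln, base$tip.label, ord, models)
  idx0 <- tp_index(base)
  base_partials <- tree_partials(idx0, pats)

  set.seed(seed)
  reps <- vector("list", B)
  best_edges <- character(B)
  for (b in seq_len(B)) {
    w <- lapply(pats, function(pp) {
      s <- sample.int(pp$n_sites, pp$n_sites, replace = TRUE)
      as.numeric(tabulate(pp$map[s], nbins = length(pp$weights)))
    })
    cur <- idx0$tree
    partials <- base_partials
    qsplit <- NA_character_
    for (q in ord) {
      res <- place_on_tree(cur, pats, q, weights = w, partials = partials,
                           mode = "screen", top_m = top_m)
      best <- res$table[1, ]
      if (q == query) qsplit <- best$split
      cur <- graft_lengths(res$tree, best$edge, q, best$t_child,
                           best$t_parent, best$pendant)
      partials <- NULL  # tree changed; recompute for the next insertion
    }
    reps[[b]] <- tree_splits(cur)
    best_edges[b] <- qsplit
  }
  structure(list(B = B, query = query, rogues = rogues,
                 backbone = backbone, base_tree = base,
                 leaves = sort(c(base$tip.label, ord)),
                 replicates = reps, query_edge_on_base = best_edges,
                 seed = seed),
            class = "placement_tally")
}

#' Construct a tally from explicit replicate topologies
#'
#' Useful for summarizing placements computed elsewhere: each replicate is a
#' full tree over the backbone leaves plus the query (and rogues).
#'
#' @param trees list of `phylo` replicate topologies.
#' @param query,rogues labels.
#' @param backbone the backbone `phylo` (with rogues, without the query).
#' @return a `placement_tally`.
#' @export
placement_tally <- function(trees, query, backbone, rogues = character(0)) {
  base <- if (length(rogues)) ape::drop.tip(backbone, rogues) else backbone
  reps <- lapply(trees, tree_splits)
  qedge <- vapply(trees, function(tr) {
    pruned <- if (length(rogues)) ape::drop.tip(tr, rogues) else tr
    .query_sister_edge(tree_splits(pruned), pruned$tip.label, query,
                       base$tip.label)
  }, "")
  structure(list(B = length(trees), query = query, rogues = rogues,
                 backbone = backbone, base_tree = base,
                 leaves = sort(unique(c(backbone$tip.label, query))),
                 replicates = reps, query_edge_on_base = qedge,
                 seed = NA_integer_),
            class = "placement_tally")
}

#' @export
print.placement_tally <- function(x, ...) {
  cat(sprintf("placement tally: %d replicates, query '%s'%s\n", x$B, x$query,
              if (length(x$rogues)) paste0(", rogues: ",
                                           paste(x$rogues, collapse = ", "))
              else ""))
  print(utils::head(tally_table(x), 10))
  invisible(x)
}

# decode a canonical split key into the two leaf sets
.key_sides <- function(key, leaves) {
  side <- strsplit(key, "|", fixed = TRUE)[[1]]
  list(side, setdiff(leaves, side))
}

# the attachment edge of `query` expressed as a canonical split key on the
# base (query-free) leaf set: the smallest split side containing the query,
# minus the query
.query_sister_edge <- function(splits, leaves, query, base_leaves) {
  best <- NULL
  for (k in splits) {
    for (side in .key_sides(k, leaves)) {
      if (query %in% side && (is.null(best) || length(side) < length(best))) {
        best <- side
      }
    }
  }
  if (is.null(best)) {  # <= 5-leaf replicate: fall back to the pendant sister
    return(split_key(setdiff(leaves, query), base_leaves))
  }
  split_key(setdiff(best, query), base_leaves)
}

#' Aggregate a tally by query attachment
#'
#' @param tally a `placement_tally`.
#' @return data frame with the query's sister split (on the rogue-free leaf
#'   set), replicate count and percentage, sorted by count.
#' @export
tally_table <- function(tally) {
  keys <- vapply(seq_len(tally$B), function(b) {
    .replicate_query_edge(tally, b)
  }, "")
  tt <- sort(table(keys), decreasing = TRUE)
  data.frame(placement = names(tt), count = as.integer(tt),
             percent = 100 * as.integer(tt) / tally$B,
             stringsAsFactors = FALSE, row.names = NULL)
}

.replicate_query_edge <- function(tally, b) {
  if (!is.na(tally$query_edge_on_base[b])) return(tally$query_edge_on_base[b])
  leaves <- setdiff(tally$leaves, tally$rogues)
  .query_sister_edge(.strip_rogues(tally$replicates[[b]], tally$leaves,
                                   tally$rogues),
                     leaves, tally$query, tally$base_tree$tip.label)
}

# remove rogues from every side of every split key; re-canonicalise
.strip_rogues <- function(splits, leaves, rogues) {
  if (!length(rogues)) return(splits)
  keep <- setdiff(leaves, rogues)
  out <- vapply(splits, function(k) {
    side <- setdiff(strsplit(k, "|", fixed = TRUE)[[1]], rogues)
    if (length(side) == 0L || length(side) >= length(keep) - 1L) return(NA_character_)
    split_key(side, keep)
  }, "")
  unique(out[!is.na(out)])
}

#' Effective (rogue-aware) bootstrap support for a relationship
#'
#' Percentage of replicates in which, after deleting the designated rogue
#' taxa from the replicate's topology, the query attaches inside or as sister
#' to the focal clade — i.e. the clade `(focal \\ rogues) + query` is present.
#' With an empty rogue set this is the plain bootstrap support for the
#' relationship.
#'
#' @param tally a `placement_tally`.
#' @param focal_clade taxon set; must be a clade of the backbone (after
#'   removing the rogues under consideration).
#' @param rogues rogue labels to delete from each replicate (defaults to the
#'   tally's own rogue set).
#' @return support percentage in `[0, 100]`.
#' @export
effective_support <- function(tally, focal_clade, rogues = tally$rogues) {
  rogues <- intersect(rogues, tally$leaves)
  focal_eff <- setdiff(focal_clade, rogues)
  check_tree <- if (length(rogues)) {
    ape::drop.tip(tally$backbone, intersect(rogues, tally$backbone$tip.label))
  } else tally$backbone
  if (!is_tree_clade(check_tree, focal_eff)) {
    stop("focal clade is not a clade of the backbone")
  }
  leaves_eff <- setdiff(tally$leaves, rogues)
  target <- sort(unique(c(focal_eff, tally$query)))
  target_key <- split_key(target, leaves_eff)
  hits <- vapply(tally$replicates, function(spl) {
    target_key %in% .strip_rogues(spl, tally$leaves, rogues)
  }, TRUE)
  100 * sum(hits) / tally$B
}

#' Cumulative region support
#'
#' Percentage of replicates whose query attachment edge lies on or within the
#' region spanned by `region_taxa`: the subtrees of the region's clades plus
#' the spine connecting them (an edge qualifies iff both of its sides contain
#' region taxa).
#'
#' @param tally a `placement_tally`.
#' @param region_taxa non-empty taxon set (a union of backbone clades).
#' @return support percentage in `[0, 100]`.
#' @export
region_support <- function(tally, region_taxa) {
  if (length(region_taxa) == 0L) stop("empty region")
  base_leaves <- tally$base_tree$tip.label
  region <- intersect(region_taxa, base_leaves)
  if (length(region) == 0L) stop("region contains no backbone taxa")
  hits <- vapply(seq_len(tally$B), function(b) {
    key <- .replicate_query_edge(tally, b)
    side <- strsplit(key, "|", fixed = TRUE)[[1]]
    other <- setdiff(base_leaves, side)
    length(intersect(side, region)) > 0L && length(intersect(other, region)) > 0L
  }, TRUE)
  100 * sum(hits) / tally$B
}

#' Select the focused-reanalysis taxon subset
#'
#' Greedily accumulates backbone clades until their union reaches the region
#' support threshold (ties broken by fewer added taxa, then lexicographically),
#' then prunes redundant clades; adds, from each named outgroup clade, the
#' `k` taxa with the least missing data (ties broken lexicographically).
#'
#' @param backbone the backbone `phylo`.
#' @param tally a `placement_tally` from the large-scale bootstrap.
#' @param aln the supermatrix, for completeness ranking.
#' @param region_threshold required cumulative region support, in `(50, 100]`.
#' @param outgroup_clades named list of taxon sets to draw outgroups from.
#' @param k outgroup representatives per clade.
#' @return list with `ingroup`, `outgroup`, `taxa` (their union), `clades`
#'   (chosen clade keys) and `support` (achieved region support).
#' @export
select_subset <- function(backbone, tally, aln, region_threshold = 95,
                          outgroup_clades = list(), k = 2L) {
  if (!(region_threshold > 50 && region_threshold <= 100)) {
    stop("region_threshold must be in (50, 100]")
  }
  clades <- tree_clades(tally$base_tree, include_tips = TRUE)
  max_support <- region_support(tally, tally$base_tree$tip.label)
  if (max_support < region_threshold) {
    stop(sprintf("region threshold %.1f unattainable; maximum achievable %.1f",
                 region_threshold, max_support))
  }
  chosen <- list()
  region <- character(0)
  support <- 0
  while (support < region_threshold) {
    gains <- vapply(clades, function(cl) {
      region_support(tally, union(region, cl))
    }, 0)
    sizes <- vapply(clades, function(cl) length(setdiff(cl, region)), 0L)
    keys <- vapply(clades, paste, "", collapse = "|")
    ordx <- order(-gains, sizes, keys)
    pick <- ordx[1]
    if (gains[pick] <= support && sizes[pick] == 0L) break
    chosen[[length(chosen) + 1L]] <- clades[[pick]]
    region <- union(region, clades[[pick]])
    support <- gains[pick]
    clades <- clades[-pick]
  }
  # prune redundant clades (kept order-stable)
  if (length(chosen) > 1L) {
    for (i in rev(seq_along(chosen))) {
      trial <- unique(unlist(chosen[-i]))
      if (length(trial) &&
          region_support(tally, trial) >= region_threshold) {
        chosen <- chosen[-i]
        region <- trial
      }
    }
  }
  miss <- apply(aln$matrix, 1, function(r) mean(r %in% MISSING_CHARS))
  outg <- character(0)
  for (cl in outgroup_clades) {
    cl <- intersect(cl, aln$taxa)
    ordc <- cl[order(miss[cl], cl)]
    outg <- c(outg, utils::head(ordc, k))
  }
  list(ingroup = sort(region), outgroup = outg,
       taxa = sort(unique(c(region, outg))),
       clades = vapply(chosen, paste, "", collapse = "|"),
       support = support)
}

# ---- jplace export ----------------------------------------------------------

# newick with {edge_number} tags after branch lengths (jplace convention);
# edge numbers are the rows of tree$edge
.newick_jplace <- function(tree) {
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  ntip <- ape::Ntip(tree)
  rec <- function(node, inedge) {
    lab <- if (node <= ntip) tree$tip.label[node] else ""
    body <- if (node > ntip) {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e) {
        rec(tree$edge[e, 2], e)
      }, ""), collapse = ","), ")")
    } else ""
    tail <- if (is.na(inedge)) "" else
      sprintf(":%.10g{%d}", tree$edge.length[inedge], inedge - 1L)
    paste0(body, lab, tail)
  }
  root <- ntip + 1L
  paste0(rec(root, NA), ";")
}

#' Write a placement result as jplace (version 3)
#'
#' @param placement a `placement_result` from [place_query()].
#' @param path output file.
#' @param top how many edges to report per query (ranked).
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placement, path, top = 7L) {
  tree <- placement$tree
  tab <- utils::head(placement$table, top)
  lwr <- exp(tab$loglik - max(tab$loglik))
  lwr <- lwr / sum(exp(placement$table$loglik - max(placement$table$loglik)))
  p <- lapply(seq_len(nrow(tab)), function(i) {
    list(tab$edge[i] - 1L, tab$loglik[i], lwr[i], tab$t_child[i],
         tab$pendant[i])
  })
  obj <- list(
    version = 3L,
    tree = .newick_jplace(tree),
    placements = list(list(p = p, n = list(placement$query))),
    fields = list("edge_num", "likelihood", "like_weight_ratio",
                  "distal_length", "pendant_length"),
    metadata = list(software = "treeplacer")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Write a tally table as tab-separated text
#'
#' @param tally a `placement_tally`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tally, path) {
  utils::write.table(tally_table(tally), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
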