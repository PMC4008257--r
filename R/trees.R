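#' Newick parsing and writing
#'
#' Thin validated wrappers around ape's newick reader/writer. Round trips
#' preserve topology, branch lengths (to printed precision) and labels.
#'
#' @param text newick string.
#' @return `parse_newick()` returns an ape `phylo`; `write_newick()` a string.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unbalanced or empty string")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' @rdname parse_newick
#' @param tree an ape `phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape), with negative estimated branch
#' lengths clamped to zero. Handles the degenerate 2- and 3-taxon cases by
#' their closed forms.
#'
#' @param D symmetric distance matrix (`dist` or matrix) with labels.
#' @return unrooted `phylo` over the labels.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix needs labels")
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1, ]
    stop("incomparable (non-finite) distance between '", labs[bad[1]],
         "' and '", labs[bad[2]], "'")
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    return(parse_newick(sprintf("(%s:%.10g,%s:%.10g);",
                                labs[1], D[1, 2] / 2, labs[2], D[1, 2] / 2)))
  }
  if (n == 3L) {
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    v <- pmax(c(a, b, c), 0)
    return(parse_newick(sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                labs[1], v[1], labs[2], v[2], labs[3], v[3])))
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Patristic (tip-to-tip) distances
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix of path-length distances between leaves.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Restrict a tree to a taxon subset
#'
#' Prunes all other leaves and suppresses the resulting degree-2 nodes,
#' summing branch lengths, so the split set equals the induced splits of the
#' original tree.
#'
#' @param tree a `phylo`.
#' @param taxa character vector, subset of the leaf labels, length >= 2.
#' @return the restricted `phylo`.
#' @export
restrict_to_taxa <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxon: ", unknown[1])
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  if (setequal(taxa, tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Strict consensus of trees on one leaf set
#'
#' Contains exactly the splits present in every input tree; conflicting or
#' unshared splits collapse to polytomies. Branch lengths are dropped.
#'
#' @param trees list of `phylo` (or `multiPhylo`) on identical leaf sets.
#' @return an unrooted `phylo` without branch lengths.
#' @export
strict_consensus <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) < 2L) stop("need at least 2 trees")
  base <- sort(trees[[1]]$tip.label)
  for (t in trees[-1]) {
    if (!identical(sort(t$tip.label), base)) {
      stop("leaf-set mismatch: restrict trees to common taxa first")
    }
  }
  trees <- lapply(trees, function(t) { t$edge.length <- NULL; t })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 1, rooted = FALSE)
  cons$edge.length <- NULL
  cons
}

# ---- split utilities -------------------------------------------------------

# Canonical key of one leaf subset: the side NOT containing the anchor
# (lexicographically smallest leaf), sorted and pipe-joined.
split_key <- function(side, leaves, anchor = min(leaves)) {
  side <- sort(side)
  if (anchor %in% side) side <- sort(setdiff(leaves, side))
  paste(side, collapse = "|")
}

#' Non-trivial splits of an unrooted tree
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split keys (each key lists the side
#'   not containing the alphabetically first leaf, sorted, `|`-joined).
#' @export
tree_splits <- function(tree) {
  leaves <- tree$tip.label
  if (length(leaves) < 4L) return(character(0))
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (i in seq_along(pp)) {
    cl <- leaves[pp[[i]]]
    if (length(cl) <= 1L || length(cl) >= length(leaves) - 1L) next
    out <- c(out, split_key(cl, leaves))
  }
  sort(unique(out))
}

# all clade leaf sets of a tree as rooted (list of character vectors),
# including trivial single-leaf clades, excluding the full set
tree_clades <- function(tree, include_tips = TRUE) {
  leaves <- tree$tip.label
  pp <- ape::prop.part(tree)
  out <- lapply(pp, function(ix) sort(leaves[ix]))
  out <- out[vapply(out, length, 1L) < length(leaves)]
  if (include_tips) out <- c(out, as.list(sort(leaves)))
  unique(out)
}

# is `set` one side of some edge of the unrooted tree (incl. pendant edges)?
is_tree_clade <- function(tree, set) {
  leaves <- tree$tip.label
  set <- sort(unique(set))
  if (!all(set %in% leaves)) return(FALSE)
  if (length(set) == 0L || length(set) == length(leaves)) return(FALSE)
  if (length(set) == 1L || length(set) == length(leaves) - 1L) return(TRUE)
  key <- split_key(set, leaves)
  key %in% tree_splits(tree)
}
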