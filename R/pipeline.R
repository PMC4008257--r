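# fast empirical per-partition models for screening/placement: empirical base
# frequencies, pooled moment estimate of kappa, fixed conventional alpha, and
# relative rate multipliers from mean pairwise ML distances (normalised to a
# site-weighted mean of 1)
#' Quick empirical models for every partition
#'
#' @param aln a [partitioned_alignment()].
#' @param alpha Gamma shape used for all partitions.
#' @param ncat discrete-Gamma categories.
#' @return named list of [subst_model()]s, one per partition.
#' @export
empirical_models <- function(aln, alpha = 0.5, ncat = 4L) {
  det <- c("A", "C", "G", "T")
  specs <- lapply(aln$partitions, function(p) {
    mat <- aln$matrix[, p$sites, drop = FALSE]
    use <- apply(mat, 1, function(r) sum(r %in% det) >= 20L)
    mat <- mat[use, , drop = FALSE]
    obs <- table(factor(mat[mat %in% det], levels = det))
    freqs <- (as.numeric(obs) + 1) / (sum(obs) + 4)
    kap <- if (nrow(mat) >= 2L) estimate_kappa(mat) else 2
    mdist <- if (nrow(mat) >= 2L) {
      D <- distance_matrix(mat, subst_model_hky(kap, freqs / sum(freqs),
                                                alpha = alpha))
      mean(D[upper.tri(D)], na.rm = TRUE)
    } else NA_real_
    list(freqs = freqs / sum(freqs), kappa = kap, mdist = mdist,
         n = length(p$sites))
  })
  md <- vapply(specs, function(s) s$mdist, 0)
  ns <- vapply(specs, function(s) s$n, 0)
  ok <- is.finite(md) & md > 0
  scale <- if (any(ok)) sum(md[ok] * ns[ok]) / sum(ns[ok]) else 1
  mult <- ifelse(ok, md / scale, 1)
  out <- lapply(seq_along(specs), function(i) {
    subst_model_hky(specs[[i]]$kappa, specs[[i]]$freqs, alpha = alpha,
                    ncat = ncat, rate_mult = mult[i])
  })
  names(out) <- names(aln$partitions)
  out
}

#' Single-gene quality-control trees
#'
#' For every gene in which the query has data, builds an NJ tree on HKY+Gamma
#' ML distances, records the query's nearest-neighbour taxa, and estimates
#' their frequency over distance-bootstrap replicates. A gene is flagged when
#' its modal neighbourhood is disjoint from every other gene's modal
#' neighbourhood at or above `conflict_threshold` percent support —
#' the signature of a sequencing error or contamination in that marker.
#'
#' @param aln a [partitioned_alignment()].
#' @param query query taxon label.
#' @param B distance-bootstrap replicates per gene.
#' @param seed integer seed.
#' @param min_sites minimum determinate sites for a taxon to enter a gene.
#' @param conflict_threshold percent support above which a conflicting
#'   neighbourhood is flagged.
#' @return data frame: gene, n_taxa, neighbours, neighbour bootstrap
#'   percentage, conflict flag.
#' @export
single_gene_qc <- function(aln, query, B = 100L, seed = 1L, min_sites = 30L,
                           conflict_threshold = 70) {
  set.seed(seed)
  det <- c("A", "C", "G", "T")
  rows <- list()
  modal <- list()
  for (p in aln$partitions) {
    mat <- aln$matrix[, p$sites, drop = FALSE]
    nsites <- apply(mat, 1, function(r) sum(r %in% det))
    keep <- names(nsites)[nsites >= min_sites]
    if (!(query %in% keep) || length(keep) < 4L) {
      if (query %in% rownames(mat) && nsites[query] >= min_sites) {
        message("gene '", p$name, "' skipped: fewer than 4 usable taxa")
      }
      next
    }
    mat <- mat[keep, , drop = FALSE]
    obs <- table(factor(mat[mat %in% det], levels = det))
    freqs <- (as.numeric(obs) + 1) / (sum(obs) + 4)
    model <- subst_model_hky(estimate_kappa(mat), freqs / sum(freqs),
                             alpha = 0.5)
    sisters <- function(m) {
      D <- distance_matrix(m, model)
      if (any(!is.finite(D))) return(NA_character_)
      tr <- neighbor_joining(D)
      spl <- tree_splits(tr)
      best <- NULL
      for (k in spl) {
        for (side in .key_sides(k, tr$tip.label)) {
          if (query %in% side && (is.null(best) || length(side) < length(best))) {
            best <- side
          }
        }
      }
      if (is.null(best)) best <- tr$tip.label
      paste(sort(setdiff(best, query)), collapse = "|")
    }
    point <- sisters(mat)
    boot <- vapply(seq_len(B), function(b) {
      ix <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      sisters(mat[, ix, drop = FALSE])
    }, "")
    boot <- boot[!is.na(boot)]
    tab <- sort(table(boot), decreasing = TRUE)
    modal_key <- names(tab)[1]
    freq <- 100 * as.integer(tab[1]) / max(1L, length(boot))
    modal[[p$name]] <- strsplit(modal_key, "|", fixed = TRUE)[[1]]
    rows[[p$name]] <- data.frame(
      gene = p$name, n_taxa = nrow(mat),
      neighbours = point, modal_neighbours = modal_key,
      modal_pct = freq, flagged = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("query has no usable gene")
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  if (nrow(rep) > 1L) {
    for (i in seq_len(nrow(rep))) {
      others <- unique(unlist(modal[rep$gene[-i]]))
      mine <- modal[[rep$gene[i]]]
      rep$flagged[i] <- length(intersect(mine, others)) == 0L &&
        rep$modal_pct[i] >= conflict_threshold
    }
  }
  rep
}

#' Configuration for the two-tier workflow
#'
#' @param alignment a [partitioned_alignment()] or path readable by
#'   [read_alignment()].
#' @param backbone a `phylo` or newick path.
#' @param query query taxon label.
#' @param partition_table optional partition table (path or data frame) when
#'   `alignment` is a path.
#' @param rogues rogue taxon labels re-placed per bootstrap replicate.
#' @param outgroup_clades named list of taxon sets for outgroup sampling.
#' @param hypotheses named list of taxon sets: each hypothesis regrafts the
#'   query as sister to that set on the best small-scale tree for AU testing.
#' @param B bootstrap replicates (both tiers).
#' @param seed integer master seed; every stage derives its own from it.
#' @param region_threshold cumulative region support required of the subset.
#' @param k outgroup representatives per clade.
#' @param alpha fixed Gamma shape of the empirical screening models.
#' @param qc_B distance-bootstrap replicates in single-gene QC.
#' @param au_B,au_scales AU test controls.
#' @param plateau_threshold,slope_threshold,min_sites saturation controls.
#' @param out_dir output directory (created).
#' @return a `run_config` list.
#' @export
run_config <- function(alignment, backbone, query,
                       partition_table = NULL,
                       rogues = character(0), outgroup_clades = list(),
                       hypotheses = NULL, B = 100L, seed,
                       region_threshold = 95, k = 2L, alpha = 0.5,
                       qc_B = 100L, au_B = 2000L,
                       au_scales = seq(0.5, 1.4, by = 0.1),
                       plateau_threshold = 0.5, slope_threshold = 0.3,
                       min_sites = 50L, out_dir = tempfile("run")) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(B >= 1L)
  structure(list(alignment = alignment, backbone = backbone, query = query,
                 partition_table = partition_table, rogues = rogues,
                 outgroup_clades = outgroup_clades, hypotheses = hypotheses,
                 B = as.integer(B), seed = as.integer(seed),
                 region_threshold = region_threshold, k = as.integer(k),
                 alpha = alpha, qc_B = as.integer(qc_B),
                 au_B = as.integer(au_B), au_scales = au_scales,
                 plateau_threshold = plateau_threshold,
                 slope_threshold = slope_threshold,
                 min_sites = as.integer(min_sites), out_dir = out_dir),
            class = "run_config")
}

#' Run the two-tier placement workflow end to end
#'
#' Stages: clean the supermatrix, single-gene QC, saturation screen,
#' large-scale constrained placement and bootstrap tally with effective and
#' region support, focused subset selection, small-scale re-placement and
#' bootstrap, hypothesis-tree construction by regrafting, AU testing, and a
#' full set of written artifacts (filtered alignment, jplace, tally tables,
#' subset list, AU report, consensus newick, log of seeds and thresholds).
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of in-memory results; artifacts are written to
#'   `config$out_dir`.
#' @export
run_two_tier <- function(config) {
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cf$out_dir, "run.log")
  logit <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                             append = TRUE)
  cat("", file = logf)
  logit("treeplacer %s", as.character(utils::packageVersion("treeplacer")))
  logit("seed=%d B=%d region_threshold=%.1f k=%d alpha=%.3f", cf$seed, cf$B,
        cf$region_threshold, cf$k, cf$alpha)
  logit("plateau_threshold=%.2f slope_threshold=%.2f min_sites=%d",
        cf$plateau_threshold, cf$slope_threshold, cf$min_sites)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  aln <- stage("load", {
    if (inherits(cf$alignment, "partitioned_alignment")) cf$alignment
    else read_alignment(cf$alignment, partition_table = cf$partition_table)
  })
  backbone <- stage("load", {
    if (inherits(cf$backbone, "phylo")) cf$backbone
    else ape::read.tree(cf$backbone)
  })

  aln <- stage("clean", clean_alignment(aln))
  rem <- attr(aln, "removal_report")
  logit("clean: removed %d taxa, %d columns", length(rem$removed_taxa),
        length(rem$removed_columns))

  qc <- stage("qc", single_gene_qc(aln, cf$query, B = cf$qc_B,
                                   seed = cf$seed + 1L))
  utils::write.table(qc, file.path(cf$out_dir, "single_gene_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in which(qc$flagged)) {
    logit("qc flag: gene %s modal neighbourhood %s at %.0f%%", qc$gene[i],
          qc$modal_neighbours[i], qc$modal_pct[i])
  }

  screen <- stage("screen", screen_partitions(
    aln, min_sites = cf$min_sites, alpha = cf$alpha,
    plateau_threshold = cf$plateau_threshold,
    slope_threshold = cf$slope_threshold))
  write_saturation_report(screen, file.path(cf$out_dir, "saturation.tsv"),
                          pairs_dir = file.path(cf$out_dir, "saturation_pairs"))
  for (i in seq_len(nrow(screen$report))) {
    if (screen$report$decision[i] == "exclude") {
      logit("screen: excluded unit %s (slope %.3f, plateau ratio %.3f)",
            screen$report$unit[i], screen$report$slope[i],
            screen$report$plateau_ratio[i])
    }
  }
  for (i in seq_len(nrow(screen$outliers))) {
    logit("screen: outlier %s in unit %s (score %.3f)",
          screen$outliers$taxon[i], screen$outliers$unit[i],
          screen$outliers$score[i])
  }
  fal <- screen$filtered
  write_alignment(fal, file.path(cf$out_dir, "filtered_alignment.fasta"))

  models <- stage("models", empirical_models(fal, alpha = cf$alpha))

  bb <- stage("tier1", {
    tr <- restrict_to_taxa(backbone,
                           intersect(backbone$tip.label, fal$taxa))
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.05, nrow(tr$edge))
    optimize_branch_lengths(tr, fal, models, tol = 1e-3, max_sweeps = 3L)$tree
  })
  pl1 <- stage("tier1", place_query(bb, fal, models, cf$query))
  write_jplace(pl1, file.path(cf$out_dir, "tier1_placement.jplace"))
  tally1 <- stage("tier1", bootstrap_placements(
    bb, fal, models, cf$query, B = cf$B, seed = cf$seed + 2L,
    rogues = cf$rogues))
  write_tally(tally1, file.path(cf$out_dir, "tier1_tally.tsv"))
  logit("tier1: best edge {%s}, margin %.3f", pl1$best$split, pl1$margin)

  subset <- stage("subset", select_subset(
    bb, tally1, fal, region_threshold = cf$region_threshold,
    outgroup_clades = cf$outgroup_clades, k = cf$k))
  writeLines(subset$taxa, file.path(cf$out_dir, "subset_taxa.txt"))
  logit("subset: %d ingroup + %d outgroup taxa, region support %.1f%%",
        length(subset$ingroup), length(subset$outgroup), subset$support)

  sub_taxa <- unique(c(subset$taxa, cf$query))
  sub_bb <- stage("tier2", restrict_to_taxa(bb, setdiff(sub_taxa, cf$query)))
  sal <- fal
  sal$matrix <- fal$matrix[intersect(sub_taxa, fal$taxa), , drop = FALSE]
  sal$taxa <- rownames(sal$matrix)
  sal <- stage("tier2", clean_alignment(sal))
  models2 <- stage("tier2", empirical_models(sal, alpha = cf$alpha))
  sub_bb <- stage("tier2", restrict_to_taxa(sub_bb,
                                            intersect(sub_bb$tip.label,
                                                      sal$taxa)))
  sub_bb <- optimize_branch_lengths(sub_bb, sal, models2, tol = 1e-3,
                                    max_sweeps = 3L)$tree
  pl2 <- stage("tier2", place_query(sub_bb, sal, models2, cf$query))
  write_jplace(pl2, file.path(cf$out_dir, "tier2_placement.jplace"))
  tally2 <- stage("tier2", bootstrap_placements(
    sub_bb, sal, models2, cf$query, B = cf$B, seed = cf$seed + 3L,
    rogues = intersect(cf$rogues, sub_bb$tip.label)))
  write_tally(tally2, file.path(cf$out_dir, "tier2_tally.tsv"))
  logit("tier2: best edge {%s}, margin %.3f", pl2$best$split, pl2$margin)
  logit("tier2 missing fraction %.3f (tier1 %.3f)", missing_fraction(sal),
        missing_fraction(fal))

  best2 <- pl2$best
  best_tree <- graft_lengths(pl2$tree, best2$edge, cf$query, best2$t_child,
                             best2$t_parent, best2$pendant)
  hyp <- cf$hypotheses
  if (is.null(hyp)) {
    runner <- pl2$table[2, ]
    hyp <- list(runner_up = strsplit(runner$split, "|", fixed = TRUE)[[1]])
  }
  trees <- list(best = best_tree)
  pruned <- ape::drop.tip(best_tree, cf$query)
  for (nm in names(hyp)) {
    trees[[nm]] <- stage("hypotheses",
                         regraft_at(pruned, cf$query, hyp[[nm]],
                                    pendant = best2$pendant))
  }
  au <- stage("autest", {
    sw <- sitewise_matrix(trees, sal, models2)
    au_test(sw, scales = cf$au_scales, B_per_scale = cf$au_B,
            seed = cf$seed + 4L)
  })
  write_au_report(au, file.path(cf$out_dir, "au_report.tsv"))

  ord <- order(-au$au_p)
  cons <- strict_consensus(trees[au$tree[ord[1:2]]])
  ape::write.tree(cons, file.path(cf$out_dir, "consensus.nwk"))
  ape::write.tree(best_tree, file.path(cf$out_dir, "tier2_best_tree.nwk"))
  logit("au: best tree %s (p=%.4g), worst %s (p=%.4g)",
        au$tree[ord[1]], au$au_p[ord[1]], au$tree[ord[length(ord)]],
        au$au_p[ord[length(ord)]])
  invisible(list(alignment = fal, screen = screen, qc = qc,
                 tier1 = list(placement = pl1, tally = tally1),
                 subset = subset,
                 tier2 = list(placement = pl2, tally = tally2,
                              best_tree = best_tree),
                 au = au, out_dir = cf$out_dir))
}

#' Regraft a query as sister to a taxon set
#'
#' Attaches the query on the edge above the most recent common ancestor of
#' `sister_taxa` in `tree` (the pendant edge when a single taxon is given):
#' the device used to build hypothesis trees on a fixed best backbone.
#'
#' @param tree a `phylo` without the query.
#' @param query tip label to add.
#' @param sister_taxa taxon set the query becomes sister to.
#' @param pendant pendant branch length.
#' @return the augmented `phylo`.
#' @export
regraft_at <- function(tree, query, sister_taxa, pendant = 0.05) {
  sister_taxa <- intersect(sister_taxa, tree$tip.label)
  if (length(sister_taxa) == 0L) stop("no sister taxa present in the tree")
  if (length(sister_taxa) == 1L) {
    node <- match(sister_taxa, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, sister_taxa)
  }
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) != 1L) stop("sister set has no subtending edge (root?)")
  graft(tree, edge, query, attach_fraction = 0.5, pendant_length = pendant)
}
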