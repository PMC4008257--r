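#' Simulate sequences along a tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' edge by edge with transition probabilities `expm(Q t r)`, where `r` is the
#' site's discrete-Gamma category rate. Reproducible under `seed`.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model a [subst_model()] (its `rate_mult` scales all branches).
#' @param length number of sites.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a [partitioned_alignment()] with one partition.
#' @export
simulate_alignment <- function(tree, model, length, seed) {
  set.seed(seed)
  partitioned_alignment(.sim_matrix(tree, model, length))
}

# simulation core; assumes the RNG state is already set
.sim_matrix <- function(tree, model, L) {
  idx <- tp_index(tree)
  nnode <- idx$nnode; ntip <- idx$ntip
  states <- matrix(0L, nnode, L)
  root <- ntip + 1L
  cats <- sample.int(model$ncat, L, replace = TRUE)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$freqs)
  edges <- idx$tree$edge
  for (e in rev(seq_len(nrow(edges)))) {     # preorder
    par <- edges[e, 1]; ch <- edges[e, 2]
    Parr <- prob_matrix(model, idx$lengths[e])
    for (cc in seq_len(model$ncat)) {
      sel_c <- which(cats == cc)
      ps <- states[par, sel_c]
      for (s in 1:4) {
        sel <- sel_c[ps == s]
        if (length(sel)) {
          states[ch, sel] <- sample.int(4L, length(sel), replace = TRUE,
                                        prob = Parr[s, , cc])
        }
      }
    }
  }
  chars <- c("A", "C", "G", "T")
  mat <- matrix(chars[states[seq_len(ntip), ]], ntip, L)
  rownames(mat) <- idx$tree$tip.label
  mat
}

#' Configuration for a synthetic placement study
#'
#' The default marker mix emulates a mixed mitochondrial/nuclear amphibian
#' supermatrix at desk scale: two mitochondrial protein-coding genes (AT-rich,
#' high kappa, third positions at relative rate x15 — the planted saturated
#' units), one mitochondrial rRNA fragment, and three nuclear protein-coding
#' genes in the linear (unsaturated) regime.
#'
#' @param n_leaves backbone leaf count.
#' @param bl_range uniform branch-length range for the backbone.
#' @param pendant true pendant length of the query.
#' @param partitions list of marker specs; each has `name`, `origin`,
#'   `coding`, `length` (sites; a multiple of 3 for coding), `kappa`, `freqs`,
#'   `alpha`, `ncat`, and `pos_rates` (relative rate per codon position, or a
#'   single rate for non-coding markers).
#' @param missingness target missing-data fraction (block-structured; 0 = none).
#' @param outlier_taxon,outlier_partition optionally replace one taxon's block
#'   in one marker by i.i.d. uniform bases (contamination emulation).
#' @param query_label label of the query taxon.
#' @param seed mandatory integer seed.
#' @return a `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(n_leaves = 12L,
                                   bl_range = c(0.01, 0.07),
                                   pendant = 0.05,
                                   partitions = default_marker_mix(),
                                   missingness = 0,
                                   outlier_taxon = NULL,
                                   outlier_partition = NULL,
                                   query_label = "query",
                                   seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_leaves >= 4L, missingness >= 0, missingness < 1)
  structure(list(n_leaves = as.integer(n_leaves), bl_range = bl_range,
                 pendant = pendant, partitions = partitions,
                 missingness = missingness, outlier_taxon = outlier_taxon,
                 outlier_partition = outlier_partition,
                 query_label = query_label, seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' @rdname synthetic_study_config
#' @export
default_marker_mix <- function() {
  mito_freqs <- c(A = 0.33, C = 0.27, G = 0.13, T = 0.27)
  nuc_freqs <- c(A = 0.27, C = 0.23, G = 0.24, T = 0.26)
  list(
    list(name = "cytb_like", origin = "mitochondrial", coding = TRUE,
         length = 450L, kappa = 8, freqs = mito_freqs, alpha = 1, ncat = 4L,
         pos_rates = c(0.7, 0.3, 15), genetic_code = "vertebrate-mitochondrial"),
    list(name = "nd2_like", origin = "mitochondrial", coding = TRUE,
         length = 450L, kappa = 8, freqs = mito_freqs, alpha = 1, ncat = 4L,
         pos_rates = c(0.7, 0.3, 15), genetic_code = "vertebrate-mitochondrial"),
    list(name = "rrna_like", origin = "mitochondrial", coding = FALSE,
         length = 700L, kappa = 4, freqs = mito_freqs, alpha = 1, ncat = 4L,
         pos_rates = 0.5),
    list(name = "rag1_like", origin = "nuclear", coding = TRUE,
         length = 900L, kappa = 3, freqs = nuc_freqs, alpha = 1, ncat = 4L,
         pos_rates = c(0.5, 0.25, 1.0), genetic_code = "standard"),
    list(name = "pomc_like", origin = "nuclear", coding = TRUE,
         length = 900L, kappa = 3, freqs = nuc_freqs, alpha = 1, ncat = 4L,
         pos_rates = c(0.5, 0.25, 1.0), genetic_code = "standard"),
    list(name = "tyr_like", origin = "nuclear", coding = TRUE,
         length = 900L, kappa = 3, freqs = nuc_freqs, alpha = 1, ncat = 4L,
         pos_rates = c(0.5, 0.25, 1.0), genetic_code = "standard")
  )
}

# true substitution models implied by a config, one per marker x position unit
config_models <- function(spec) {
  if (spec$coding) {
    lapply(spec$pos_rates, function(r) {
      subst_model_hky(spec$kappa, spec$freqs, alpha = spec$alpha,
                      ncat = spec$ncat, rate_mult = r)
    })
  } else {
    list(subst_model_hky(spec$kappa, spec$freqs, alpha = spec$alpha,
                         ncat = spec$ncat, rate_mult = spec$pos_rates[1]))
  }
}

#' Generate a synthetic placement study
#'
#' Simulates sequences on a full tree that includes the query attached at a
#' random backbone edge, then emits the backbone (query pruned), the
#' alignment (query included) and a truth record with the attachment edge.
#'
#' @param config a [synthetic_study_config()].
#' @return list with `backbone` (`phylo`), `alignment`
#'   ([partitioned_alignment()]), `truth` (list: `query`, `edge_split`
#'   canonical key on backbone leaves, `sister_leaves`, `pendant`), and
#'   `models` (true per-partition models, named by partition).
#' @export
make_placement_study <- function(config) {
  set.seed(config$seed)
  n <- config$n_leaves
  backbone <- ape::unroot(ape::rtree(n, br = NULL))
  backbone$tip.label <- sprintf("t%02d", seq_len(n))
  backbone$edge.length <- stats::runif(nrow(backbone$edge),
                                       config$bl_range[1], config$bl_range[2])
  true_edge <- sample.int(nrow(backbone$edge), 1L)
  full <- graft(backbone, true_edge, config$query_label,
                attach_fraction = 0.5, pendant_length = config$pendant)
  sister_leaves <- edge_child_leaves(backbone, true_edge)

  gene_mats <- list(); models <- list()
  gene_meta <- list()
  for (spec in config$partitions) {
    mods <- config_models(spec)
    if (spec$coding) {
      npos <- spec$length / 3L
      blocks <- lapply(1:3, function(k) .sim_matrix(full, mods[[k]], npos))
      m <- matrix("", nrow(blocks[[1]]), spec$length,
                  dimnames = list(rownames(blocks[[1]]), NULL))
      for (k in 1:3) m[, seq(k, spec$length, by = 3L)] <- blocks[[k]]
    } else {
      m <- .sim_matrix(full, mods[[1]], spec$length)
    }
    gene_mats[[spec$name]] <- m
    models[[spec$name]] <- mods
    gene_meta[[spec$name]] <- spec
  }
  aln <- concatenate_genes(gene_mats,
                           origins = vapply(gene_meta, `[[`, "", "origin"),
                           coding = vapply(gene_meta, `[[`, TRUE, "coding"),
                           frames = lapply(gene_meta, function(s)
                             if (s$coding) 0L else NA_integer_),
                           codes = lapply(gene_meta, function(s)
                             if (s$coding) s$genetic_code else NA_character_))
  if (config$missingness > 0) {
    aln <- apply_missingness(aln, config$missingness,
                             seed = config$seed + 1000003L)
  }
  if (!is.null(config$outlier_taxon)) {
    aln <- inject_outlier(aln, config$outlier_taxon, config$outlier_partition,
                          seed = config$seed + 2000003L)
  }
  list(backbone = backbone, alignment = aln,
       truth = list(query = config$query_label,
                    edge_split = split_key(sister_leaves, backbone$tip.label),
                    sister_leaves = sister_leaves,
                    pendant = config$pendant,
                    edge = true_edge),
       models = models)
}

#' Mask whole taxon-by-marker blocks to a target missing fraction
#'
#' Blocks (a taxon's sites in one partition) are masked in random order until
#' the global missing fraction is within two percentage points of the target;
#' a taxon's last remaining marker is never masked.
#'
#' @param aln a [partitioned_alignment()].
#' @param target_fraction target global missing fraction in `[0, 0.95]`.
#' @param seed integer seed.
#' @return the masked alignment.
#' @export
apply_missingness <- function(aln, target_fraction, seed) {
  stopifnot(target_fraction >= 0, target_fraction <= 0.95)
  if (target_fraction == 0) return(aln)
  set.seed(seed)
  mat <- aln$matrix
  parts <- aln$partitions
  frac <- function(m) mean(m %in% MISSING_CHARS)
  # marker presence per taxon
  present <- sapply(parts, function(p) {
    apply(mat[, p$sites, drop = FALSE], 1,
          function(r) any(!(r %in% MISSING_CHARS)))
  })  # taxa x markers
  cand <- which(present, arr.ind = TRUE)
  ord <- sample.int(nrow(cand))
  cur <- frac(mat)
  for (i in ord) {
    if (cur >= target_fraction - 0.02) break
    tx <- cand[i, 1]; mk <- cand[i, 2]
    if (sum(present[tx, ]) <= 1L) next       # last-marker guard
    mat[tx, parts[[mk]]$sites] <- "?"
    present[tx, mk] <- FALSE
    cur <- frac(mat)
  }
  if (cur < target_fraction - 0.02) {
    stop(sprintf(
      "missingness target %.2f unreachable under the last-marker guard; achieved %.3f",
      target_fraction, cur))
  }
  out <- aln
  out$matrix <- mat
  out
}

#' Replace one taxon's marker block with random sequence
#'
#' Emulates a contaminated or mis-curated sequence: the block is replaced by
#' i.i.d. draws from uniform base frequencies; everything else is untouched.
#'
#' @param aln a [partitioned_alignment()].
#' @param taxon taxon label.
#' @param part partition name.
#' @param seed integer seed.
#' @return the modified alignment.
#' @export
inject_outlier <- function(aln, taxon, part, seed) {
  if (!taxon %in% aln$taxa) stop("unknown taxon: ", taxon)
  p <- aln$partitions[[part]]
  if (is.null(p)) stop("unknown partition: ", part)
  set.seed(seed)
  out <- aln
  out$matrix[taxon, p$sites] <- sample(c("A", "C", "G", "T"),
                                       length(p$sites), replace = TRUE)
  out
}
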