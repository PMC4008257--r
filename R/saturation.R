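#' Paired patristic distances for a saturation plot
#'
#' Builds a p-distance matrix and an HKY85+Gamma ML distance matrix over the
#' partition's usable taxa, a neighbor-joining tree from each, and returns the
#' paired tip-to-tip (patristic) distances: `x` from the model-corrected tree,
#' `y` from the uncorrected tree.
#'
#' @param aln a [partitioned_alignment()].
#' @param part partition name or [partition()] object.
#' @param min_sites minimum determinate sites for a taxon to enter the
#'   matrices.
#' @param alpha Gamma shape for the corrected distances (the pairwise
#'   estimate is unstable, so a fixed conventional value is used).
#' @param kappa transition/transversion ratio; `NULL` estimates it once per
#'   partition by a pooled Kimura-style moment estimate.
#' @return data frame with columns `taxon_i`, `taxon_j`, `x`, `y`; the taxa
#'   used, the distance matrices and the NJ trees are attached as attributes.
#'   Returns `NULL` (with a warning) when fewer than 4 usable taxa remain.
#' @export
saturation_pairs <- function(aln, part, min_sites = 50L, alpha = 0.5,
                             kappa = NULL) {
  p <- if (inherits(part, "aln_partition")) part else aln$partitions[[part]]
  if (is.null(p)) stop("unknown partition: ", part)
  mat <- aln$matrix[, p$sites, drop = FALSE]
  det <- c("A", "C", "G", "T")
  nsites <- apply(mat, 1, function(r) sum(r %in% det))
  keep <- names(nsites)[nsites >= min_sites]
  if (length(keep) < 4L) {
    warning("partition '", p$name, "' skipped: fewer than 4 usable taxa")
    return(NULL)
  }
  mat <- mat[keep, , drop = FALSE]
  Dp <- distance_matrix(mat, model = NULL)
  if (any(is.na(Dp))) {
    # drop the most incomplete taxa until all pairs are comparable
    while (any(is.na(Dp)) && nrow(Dp) > 4L) {
      worst <- names(which.max(rowSums(is.na(Dp))))
      mat <- mat[setdiff(rownames(mat), worst), , drop = FALSE]
      Dp <- distance_matrix(mat, model = NULL)
    }
    if (any(is.na(Dp))) {
      warning("partition '", p$name, "' skipped: incomparable taxon pairs")
      return(NULL)
    }
  }
  obs <- table(factor(mat[mat %in% det], levels = det))
  freqs <- (as.numeric(obs) + 1) / (sum(obs) + 4)
  if (is.null(kappa)) kappa <- estimate_kappa(mat)
  model <- subst_model_hky(kappa, freqs / sum(freqs), alpha = alpha)
  Dm <- distance_matrix(mat, model = model)
  tr_p <- neighbor_joining(Dp)
  tr_m <- neighbor_joining(Dm)
  Pp <- patristic_distances(tr_p)
  Pm <- patristic_distances(tr_m)
  taxa <- rownames(mat)
  ij <- utils::combn(taxa, 2)
  out <- data.frame(taxon_i = ij[1, ], taxon_j = ij[2, ],
                    x = Pm[cbind(ij[1, ], ij[2, ])],
                    y = Pp[cbind(ij[1, ], ij[2, ])],
                    stringsAsFactors = FALSE)
  attr(out, "taxa") <- taxa
  attr(out, "partition") <- p$name
  attr(out, "kappa") <- kappa
  attr(out, "alpha") <- alpha
  attr(out, "patristic_model") <- Pm
  attr(out, "patristic_p") <- Pp
  out
}

.ols_slope <- function(x, y) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) return(NA_real_)
  stats::cov(x, y) / vx
}

#' Assess saturation from paired distances
#'
#' Fits `y = a + b x` by ordinary least squares and computes the plateau
#' ratio: the OLS slope over pairs with `x` above the median `x`, divided by
#' the slope over pairs at or below the median. Saturated partitions show a
#' plateau (upper slope collapsing), unsaturated ones stay near-linear. The
#' decision is exclude iff `plateau_ratio < plateau_threshold` or the global
#' slope `b < slope_threshold`.
#'
#' @param pairs data frame from [saturation_pairs()] (columns `x`, `y`).
#' @param plateau_threshold minimum acceptable upper/lower slope ratio.
#' @param slope_threshold minimum acceptable global OLS slope.
#' @return a `saturation_assessment`: list with the fitted statistics, the
#'   thresholds used, and `decision` (`"include"`/`"exclude"`).
#' @export
assess_saturation <- function(pairs, plateau_threshold = 0.5,
                              slope_threshold = 0.3) {
  stopifnot(nrow(pairs) >= 6L)
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  degenerate <- FALSE
  if (stats::var(x) <= 1e-12) {
    out <- list(partition = attr(pairs, "partition"), n_pairs = n,
                slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                plateau_ratio = NA_real_, decision = "include",
                degenerate = TRUE, plateau_threshold = plateau_threshold,
                slope_threshold = slope_threshold, pairs = pairs,
                outliers = character(0))
    class(out) <- "saturation_assessment"
    return(out)
  }
  b <- .ols_slope(x, y)
  a <- mean(y) - b * mean(x)
  r2 <- if (stats::var(y) > 0) stats::cor(x, y)^2 else 1
  medx <- stats::median(x)
  lo <- x <= medx
  s_lo <- .ols_slope(x[lo], y[lo])
  s_hi <- .ols_slope(x[!lo], y[!lo])
  plateau <- if (is.na(s_lo) || is.na(s_hi)) {
    NA_real_
  } else if (s_lo <= 1e-9) {
    if (s_hi <= 1e-9) 0 else Inf
  } else {
    max(0, s_hi) / s_lo
  }
  decision <- if (!is.na(plateau) && plateau < plateau_threshold) "exclude"
  else if (b < slope_threshold) "exclude" else "include"
  out <- list(partition = attr(pairs, "partition"), n_pairs = n,
              slope = b, intercept = a, r_squared = r2,
              slope_lower = s_lo, slope_upper = s_hi,
              plateau_ratio = plateau, decision = decision,
              degenerate = degenerate,
              plateau_threshold = plateau_threshold,
              slope_threshold = slope_threshold, pairs = pairs,
              outliers = character(0))
  class(out) <- "saturation_assessment"
  out
}

#' @export
print.saturation_assessment <- function(x, ...) {
  cat(sprintf("saturation assessment%s: %s\n",
              if (!is.null(x$partition)) paste0(" [", x$partition, "]") else "",
              toupper(x$decision)))
  cat(sprintf("  %d pairs; slope %.3f (R^2 %.3f); plateau ratio %.3f (thresholds: plateau %.2f, slope %.2f)\n",
              x$n_pairs, x$slope, x$r_squared, x$plateau_ratio,
              x$plateau_threshold, x$slope_threshold))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a saturation assessment
#'
#' Model-corrected patristic distance against uncorrected patristic distance,
#' with the global OLS fit and the two half-range fits.
#'
#' @param x a `saturation_assessment`.
#' @param ... passed to `plot()`.
#' @export
plot.saturation_assessment <- function(x, ...) {
  p <- x$pairs
  graphics::plot(p$x, p$y, xlab = "model-corrected patristic distance",
                 ylab = "uncorrected patristic distance",
                 main = sprintf("%s: %s", x$partition %||% "", x$decision),
                 pch = 19, col = "grey30", ...)
  if (!is.na(x$slope)) graphics::abline(x$intercept, x$slope, col = "red3")
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Detect outlier sequences from tip-to-tip distances
#'
#' Per-taxon score: the median model-corrected patristic distance to all
#' other taxa. A taxon is flagged iff its score exceeds the overall median
#' score by more than `k` median absolute deviations, where the MAD is floored
#' at `mad_floor` times the median score. The floor makes "extremely high"
#' mean a several-fold excess over typical distances: in tightly clustered
#' low-rate partitions the raw MAD is nearly zero and would otherwise flag
#' ordinary long-branch taxa, while true contaminant sequences sit near the
#' random-sequence distance scale, far above any such floor.
#'
#' @param x a `saturation_pairs()` data frame or a patristic distance matrix.
#' @param k MAD multiplier.
#' @param mad_floor lower bound on the MAD, as a fraction of the median score.
#' @return data frame of flagged taxa and scores (possibly empty), with all
#'   scores attached as attribute `scores`.
#' @export
detect_outliers <- function(x, k = 5, mad_floor = 0.5) {
  D <- if (is.matrix(x)) x else attr(x, "patristic_model")
  if (is.null(D)) stop("need saturation pairs or a distance matrix")
  if (nrow(D) < 5L) {
    out <- data.frame(taxon = character(0), score = numeric(0))
    attr(out, "scores") <- stats::setNames(numeric(0), character(0))
    return(out)
  }
  scores <- vapply(seq_len(nrow(D)), function(i) {
    stats::median(D[i, -i])
  }, 0)
  names(scores) <- rownames(D)
  med <- stats::median(scores)
  madv <- max(stats::mad(scores), mad_floor * med)
  flag <- scores > med + k * madv
  out <- data.frame(taxon = names(scores)[flag], score = unname(scores[flag]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}

#' Screen all partitions for saturation and outliers
#'
#' Every gene x codon-position unit (coding partitions are split first) is
#' assessed: outlier taxa are detected on the model-corrected patristic
#' distances and removed, the plateau regression is fitted on the cleaned
#' pairs, and an include/exclude decision is made. Excluded units and
#' outlier taxon-marker cells are masked with `?` in the filtered supermatrix.
#'
#' @param aln a [partitioned_alignment()].
#' @param min_sites,alpha,kappa passed to [saturation_pairs()].
#' @param plateau_threshold,slope_threshold passed to [assess_saturation()].
#' @param k,mad_floor passed to [detect_outliers()].
#' @param split_codons split coding partitions by codon position first?
#' @return a `saturation_screen`: list with `report` (one row per unit),
#'   `assessments`, `retained` (list of retained unit partitions),
#'   `outliers` (taxon/unit pairs), and `filtered` (masked alignment whose
#'   partitions are the retained units).
#' @export
screen_partitions <- function(aln, min_sites = 50L, alpha = 0.5, kappa = NULL,
                              plateau_threshold = 0.5, slope_threshold = 0.3,
                              k = 5, mad_floor = 0.5, split_codons = TRUE) {
  units <- list()
  for (p in aln$partitions) {
    if (p$coding && split_codons) {
      units <- c(units, split_codon_positions(aln, p))
    } else {
      units[[p$name]] <- p
    }
  }
  rows <- list(); assessments <- list(); outl <- list()
  mat <- aln$matrix
  retained <- list()
  for (u in units) {
    pr <- withCallingHandlers(
      saturation_pairs(aln, u, min_sites = min_sites, alpha = alpha,
                       kappa = kappa),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(pr)) {
      rows[[u$name]] <- data.frame(
        unit = u$name, n_taxa = NA_integer_, n_pairs = 0L, slope = NA_real_,
        r_squared = NA_real_, plateau_ratio = NA_real_, decision = "skipped",
        outliers = "", stringsAsFactors = FALSE)
      next
    }
    fl <- detect_outliers(pr, k = k, mad_floor = mad_floor)
    if (nrow(fl) > 0L) {
      taxa <- setdiff(attr(pr, "taxa"), fl$taxon)
      sub <- aln
      sub$matrix <- aln$matrix[taxa, , drop = FALSE]
      sub$taxa <- taxa
      pr2 <- withCallingHandlers(
        saturation_pairs(sub, u, min_sites = min_sites, alpha = alpha,
                         kappa = kappa),
        warning = function(w) invokeRestart("muffleWarning"))
      for (tx in fl$taxon) {
        outl[[length(outl) + 1L]] <- data.frame(
          taxon = tx, unit = u$name,
          score = fl$score[fl$taxon == tx], stringsAsFactors = FALSE)
        mat[tx, u$sites] <- "?"
      }
      if (!is.null(pr2)) pr <- pr2
    }
    if (nrow(pr) < 6L) {
      rows[[u$name]] <- data.frame(
        unit = u$name, n_taxa = length(attr(pr, "taxa")), n_pairs = nrow(pr),
        slope = NA_real_, r_squared = NA_real_, plateau_ratio = NA_real_,
        decision = "skipped", outliers = paste(fl$taxon, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    as <- assess_saturation(pr, plateau_threshold = plateau_threshold,
                            slope_threshold = slope_threshold)
    as$outliers <- fl$taxon
    assessments[[u$name]] <- as
    if (as$decision == "exclude") {
      mat[, u$sites] <- "?"
    } else {
      retained[[u$name]] <- u
    }
    rows[[u$name]] <- data.frame(
      unit = u$name, n_taxa = length(attr(pr, "taxa")), n_pairs = as$n_pairs,
      slope = as$slope, r_squared = as$r_squared,
      plateau_ratio = as$plateau_ratio, decision = as$decision,
      outliers = paste(fl$taxon, collapse = ","), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  filtered <- partitioned_alignment(mat, unname(retained))
  outliers <- if (length(outl)) do.call(rbind, outl) else
    data.frame(taxon = character(0), unit = character(0), score = numeric(0))
  structure(list(report = report, assessments = assessments,
                 retained = retained, outliers = outliers,
                 filtered = filtered,
                 thresholds = list(plateau = plateau_threshold,
                                   slope = slope_threshold, k = k,
                                   mad_floor = mad_floor,
                                   min_sites = min_sites, alpha = alpha)),
            class = "saturation_screen")
}

#' @export
print.saturation_screen <- function(x, ...) {
  cat("saturation screen\n")
  print(x$report, row.names = FALSE)
  if (nrow(x$outliers)) {
    cat("outlier exclusions:\n")
    print(x$outliers, row.names = FALSE)
  }
  invisible(x)
}

#' Write the per-partition saturation report
#'
#' Tab-separated: unit, n_taxa, n_pairs, slope, R^2, plateau ratio, decision,
#' outliers. Plot-data (x,y pair) files are written alongside when
#' `pairs_dir` is given.
#'
#' @param screen a `saturation_screen`.
#' @param path output file for the report.
#' @param pairs_dir optional directory for per-unit x,y pair files.
#' @return `path`, invisibly.
#' @export
write_saturation_report <- function(screen, path, pairs_dir = NULL) {
  utils::write.table(screen$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pairs_dir)) {
    dir.create(pairs_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(screen$assessments)) {
      pr <- screen$assessments[[nm]]$pairs
      utils::write.table(pr, file.path(pairs_dir, paste0(nm, "_pairs.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
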