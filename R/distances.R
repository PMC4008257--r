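#' Uncorrected pairwise distance (p-distance)
#'
#' Proportion of differing sites over sites with a determinate A/C/G/T in both
#' sequences. Returns `NA` (incomparable) when no site is comparable.
#'
#' @param seq_i,seq_j character vectors (or single strings) of equal length.
#' @return proportion in `[0, 1]`, or `NA_real_` if incomparable.
#' @export
p_distance <- function(seq_i, seq_j) {
  si <- .as_chars(seq_i); sj <- .as_chars(seq_j)
  if (length(si) != length(sj)) stop("sequence length mismatch")
  det <- c("A", "C", "G", "T")
  ok <- si %in% det & sj %in% det
  if (!any(ok)) return(NA_real_)
  mean(si[ok] != sj[ok])
}

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Maximum-likelihood pairwise distance
#'
#' One-dimensional optimization of the two-sequence likelihood under a
#' reversible model. Gamma rate heterogeneity is integrated exactly
#' (continuous mixture) via the eigenvalue transform, so for JC the Jin-Nei
#' closed form `(3*alpha/4) * ((1 - 4p/3)^(-1/alpha) - 1)` is recovered.
#'
#' @param seq_i,seq_j character vectors or strings of equal length.
#' @param model a [subst_model()].
#' @param bounds search interval for the branch length.
#' @return ML distance (expected substitutions per site), `0` for identical
#'   sequences, `NA` if no site is comparable.
#' @export
ml_pairwise_distance <- function(seq_i, seq_j, model, bounds = c(1e-9, 10)) {
  si <- .as_chars(seq_i); sj <- .as_chars(seq_j)
  if (length(si) != length(sj)) stop("sequence length mismatch")
  det <- c("A", "C", "G", "T")
  ok <- si %in% det & sj %in% det
  if (!any(ok)) return(NA_real_)
  N <- table(factor(si[ok], levels = det), factor(sj[ok], levels = det))
  N <- (N + t(N)) / 2  # reversibility: direction is irrelevant
  if (sum(N) - sum(diag(N)) == 0) return(0)
  pi4 <- model$freqs
  negll <- function(t) {
    M <- tp_pmix_continuous(model, t)
    lp <- log(pmax(pi4 * M, 1e-300))
    -sum(N * lp)
  }
  opt <- stats::optimize(negll, interval = bounds, tol = 1e-10)
  opt$minimum
}

#' Pairwise distance matrices for a set of sequences
#'
#' @param mat character matrix (taxa x sites).
#' @param model `NULL` for p-distances, else a [subst_model()] for ML
#'   distances.
#' @return symmetric labelled matrix; incomparable pairs are `NA`.
#' @export
distance_matrix <- function(mat, model = NULL) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- if (is.null(model)) p_distance(mat[i, ], mat[j, ])
      else ml_pairwise_distance(mat[i, ], mat[j, ], model)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Pooled Kimura-style kappa moment estimate for a partition block: median
# over pairs of the two-parameter transition/transversion solution. Falls
# back to `fallback` when saturation leaves no valid pair.
estimate_kappa <- function(mat, fallback = 2) {
  n <- nrow(mat)
  det <- c("A", "C", "G", "T")
  purines <- c("A", "G")
  ks <- numeric(0)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      si <- mat[i, ]; sj <- mat[j, ]
      ok <- si %in% det & sj %in% det
      if (sum(ok) < 20) next
      si <- si[ok]; sj <- sj[ok]
      diff <- si != sj
      ts <- mean(diff & ((si %in% purines) == (sj %in% purines)))
      tv <- mean(diff & ((si %in% purines) != (sj %in% purines)))
      w1 <- 1 - 2 * ts - tv; w2 <- 1 - 2 * tv
      if (w1 <= 0 || w2 <= 0) next
      A <- -0.5 * log(w1) + 0.25 * log(w2)
      B <- -0.5 * log(w2)
      if (B <= 1e-9) next
      ks <- c(ks, max(1, 2 * A / B))
    }
  }
  if (length(ks) == 0) fallback else stats::median(ks)
}
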