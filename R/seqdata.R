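#' Remove all-missing taxa and columns
#'
#' Taxa whose row consists entirely of missing symbols and columns that are
#' missing in every taxon are deleted; partition site sets are re-indexed to
#' the surviving columns.
#'
#' @param aln a [partitioned_alignment()].
#' @param missing_chars symbols counted as missing.
#' @return the cleaned alignment, with a `removal_report` attribute listing
#'   `removed_taxa` and `removed_columns` (original indices).
#' @export
clean_alignment <- function(aln, missing_chars = MISSING_CHARS) {
  mat <- aln$matrix
  miss <- matrix(mat %in% missing_chars, nrow(mat))
  drop_tax <- rowSums(!miss) == 0L
  drop_col <- colSums(!miss) == 0L
  if (all(drop_tax) || all(drop_col)) stop("alignment empty after cleaning")
  keep_col <- which(!drop_col)
  mat2 <- mat[!drop_tax, keep_col, drop = FALSE]
  remap <- integer(ncol(mat)); remap[keep_col] <- seq_along(keep_col)
  parts <- list()
  for (p in aln$partitions) {
    s <- remap[p$sites[p$sites %in% keep_col]]
    if (length(s) == 0L) next
    parts[[length(parts) + 1L]] <- partition(p$name, s, origin = p$origin,
                                             coding = p$coding, frame = p$frame,
                                             genetic_code = p$genetic_code)
  }
  out <- partitioned_alignment(mat2, parts)
  attr(out, "removal_report") <- list(removed_taxa = aln$taxa[drop_tax],
                                      removed_columns = which(drop_col))
  out
}

#' Split a coding partition by codon position
#'
#' Sites are assigned to codon positions 1/2/3 by their ordinal within the
#' partition relative to the frame offset (the first complete codon starts at
#' ordinal `frame`); trailing incomplete codons follow the same rule. The
#' three outputs partition the parent's site set.
#'
#' @param aln a [partitioned_alignment()].
#' @param part name or [partition()]; must be coding.
#' @return list of three partitions named `<name>_pos1..3` (empty positions
#'   are dropped for very short partitions).
#' @export
split_codon_positions <- function(aln, part) {
  p <- if (inherits(part, "aln_partition")) part else aln$partitions[[part]]
  if (is.null(p)) stop("unknown partition: ", part)
  if (!p$coding) stop("partition '", p$name, "' is not coding")
  ord <- seq_along(p$sites) - 1L           # 0-based ordinal within partition
  pos <- ((ord - p$frame) %% 3L) + 1L
  out <- list()
  for (k in 1:3) {
    s <- p$sites[pos == k]
    if (length(s) == 0L) next
    out[[paste0(p$name, "_pos", k)]] <-
      partition(paste0(p$name, "_pos", k), s, origin = p$origin,
                coding = FALSE)
  }
  out
}

STOP_CODONS <- list(
  "standard" = c("TAA", "TAG", "TGA"),
  "vertebrate-mitochondrial" = c("TAA", "TAG", "AGA", "AGG")
)

#' Count in-frame stop codons per taxon
#'
#' Scans complete codons of a coding partition (offset by its frame) and
#' counts those matching the stop triplets of the partition's genetic code.
#' Codons containing missing or ambiguous characters are skipped. A non-zero
#' count flags a probable reading-frame or contamination problem.
#'
#' @param aln a [partitioned_alignment()].
#' @param part name or [partition()]; must be coding with a genetic code.
#' @return named integer vector of stop-codon counts per taxon.
#' @export
check_reading_frame <- function(aln, part) {
  p <- if (inherits(part, "aln_partition")) part else aln$partitions[[part]]
  if (is.null(p)) stop("unknown partition: ", part)
  if (!p$coding) stop("partition '", p$name, "' is not coding")
  code <- STOP_CODONS[[p$genetic_code]]
  if (is.null(code)) stop("unknown genetic code: ", p$genetic_code)
  sites <- p$sites
  n <- length(sites)
  starts <- seq(p$frame + 1L, n - 2L, by = 3L)
  if (n < p$frame + 3L) starts <- integer(0)
  counts <- integer(length(aln$taxa))
  names(counts) <- aln$taxa
  for (i in seq_along(aln$taxa)) {
    row <- aln$matrix[i, sites]
    for (s in starts) {
      cdn <- row[s:(s + 2L)]
      if (all(cdn %in% c("A", "C", "G", "T"))) {
        if (paste(cdn, collapse = "") %in% code) counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

#' Missing-data fraction of a supermatrix
#'
#' Fraction of matrix cells in the missing symbol set. Gaps, `?` and `N` all
#' count as missing by default (the symbol set is configurable for
#' sensitivity checks).
#'
#' @param aln a [partitioned_alignment()] or character matrix.
#' @param missing_chars symbols counted as missing.
#' @return proportion in `[0, 1]`.
#' @export
missing_fraction <- function(aln, missing_chars = MISSING_CHARS) {
  mat <- if (inherits(aln, "partitioned_alignment")) aln$matrix else aln
  if (length(mat) == 0L) stop("empty alignment")
  mean(mat %in% missing_chars)
}

#' Concatenate single-gene alignments into a supermatrix
#'
#' Builds the union of taxa; a taxon absent from a gene gets a `?`-filled
#' block. One partition per input gene, with cumulative site offsets.
#'
#' @param gene_alignments named list of [partitioned_alignment()]s (names are
#'   gene names) or of character matrices.
#' @param origins,coding,frames,codes optional per-gene partition metadata,
#'   recycled from the inputs' own single partitions when available.
#' @return a [partitioned_alignment()].
#' @export
concatenate_genes <- function(gene_alignments, origins = NULL, coding = NULL,
                              frames = NULL, codes = NULL) {
  if (is.null(names(gene_alignments)) || any(!nzchar(names(gene_alignments)))) {
    names(gene_alignments) <- paste0("gene", seq_along(gene_alignments))
  }
  mats <- lapply(gene_alignments, function(g) {
    if (inherits(g, "partitioned_alignment")) g$matrix else g
  })
  for (nm in names(mats)) {
    if (anyDuplicated(rownames(mats[[nm]]))) {
      d <- rownames(mats[[nm]])[duplicated(rownames(mats[[nm]]))][1]
      stop("gene '", nm, "': conflicting duplicate sequences for taxon '", d, "'")
    }
  }
  taxa <- sort(unique(unlist(lapply(mats, rownames))))
  total <- sum(vapply(mats, ncol, 1L))
  big <- matrix("?", length(taxa), total, dimnames = list(taxa, NULL))
  parts <- list()
  off <- 0L
  for (k in seq_along(mats)) {
    m <- mats[[k]]; nm <- names(mats)[k]
    idx <- off + seq_len(ncol(m))
    big[rownames(m), idx] <- m
    src <- gene_alignments[[k]]
    srcp <- if (inherits(src, "partitioned_alignment") &&
                length(src$partitions) == 1L) src$partitions[[1]] else NULL
    parts[[nm]] <- partition(
      nm, idx,
      origin = if (!is.null(origins)) origins[[k]] else if (!is.null(srcp)) srcp$origin else NA_character_,
      coding = if (!is.null(coding)) isTRUE(coding[[k]]) else if (!is.null(srcp)) srcp$coding else FALSE,
      frame = if (!is.null(frames)) frames[[k]] else if (!is.null(srcp)) srcp$frame else NA_integer_,
      genetic_code = if (!is.null(codes)) codes[[k]] else if (!is.null(srcp)) srcp$genetic_code else NA_character_)
    off <- off + ncol(m)
  }
  partitioned_alignment(big, unname(parts))
}
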