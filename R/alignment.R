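#' Partitioned multiple sequence alignments
#'
#' A `partitioned_alignment` holds a taxa x sites character matrix over the
#' DNA alphabet (including IUPAC ambiguity codes, `-`, `?` and `N`) together
#' with a list of named partitions covering disjoint site sets. It is the
#' supermatrix container used throughout the package.
#'
#' @param mat character matrix, one row per taxon (rownames are taxon labels),
#'   uniform row length; characters are uppercased on construction.
#' @param partitions list of partitions created with [partition()]; when
#'   `NULL` a single implicit partition spanning the whole matrix is used.
#' @return an object of class `partitioned_alignment`.
#' @export
partitioned_alignment <- function(mat, partitions = NULL) {
  if (!is.matrix(mat) || !is.character(mat)) {
    stop("mat must be a character matrix")
  }
  if (is.null(rownames(mat))) stop("mat must have taxon labels as rownames")
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1]
    stop("duplicate taxon label: ", dup)
  }
  mat[] <- toupper(mat)
  L <- ncol(mat)
  if (is.null(partitions)) {
    partitions <- list(partition("all", seq_len(L)))
  }
  seen <- integer(0)
  for (p in partitions) {
    if (!inherits(p, "aln_partition")) stop("partitions must be partition() objects")
    if (any(p$sites < 1L | p$sites > L)) {
      stop("partition '", p$name, "': site index out of range 1..", L)
    }
    if (any(p$sites %in% seen)) {
      stop("partition '", p$name, "' overlaps another partition")
    }
    seen <- c(seen, p$sites)
  }
  names(partitions) <- vapply(partitions, `[[`, "", "name")
  structure(list(taxa = rownames(mat), matrix = mat, partitions = partitions),
            class = "partitioned_alignment")
}

#' @rdname partitioned_alignment
#' @param name partition name.
#' @param sites sorted 1-based site indices.
#' @param origin `"mitochondrial"`, `"nuclear"` or `NA`.
#' @param coding is the partition protein-coding?
#' @param frame 0/1/2 offset of the first complete codon (coding only).
#' @param genetic_code `"standard"` or `"vertebrate-mitochondrial"`.
#' @export
partition <- function(name, sites, origin = NA_character_, coding = FALSE,
                      frame = if (coding) 0L else NA_integer_,
                      genetic_code = if (coding) "standard" else NA_character_) {
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) < 1L) stop("partition '", name, "' has no sites")
  if (coding && (is.na(frame) || !frame %in% 0:2)) {
    stop("coding partition '", name, "' needs a frame in 0..2")
  }
  structure(list(name = as.character(name), sites = sites,
                 origin = origin, coding = isTRUE(coding),
                 frame = if (coding) as.integer(frame) else NA_integer_,
                 genetic_code = genetic_code),
            class = "aln_partition")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("partitioned alignment: %d taxa x %d sites, %d partition(s)\n",
              length(x$taxa), ncol(x$matrix), length(x$partitions)))
  cat(sprintf("missing fraction: %.3f\n", missing_fraction(x)))
  for (p in x$partitions) {
    cat(sprintf("  %-16s %5d sites  %s%s\n", p$name, length(p$sites),
                ifelse(is.na(p$origin), "", p$origin),
                if (p$coding) sprintf(" coding frame %d", p$frame) else ""))
  }
  invisible(x)
}

MISSING_CHARS <- c("?", "-", "N")

#' Read an alignment from FASTA, relaxed PHYLIP or NEXUS
#'
#' `?` and `N` are retained as written (uppercased); a partition table can be
#' given as a RAxML-style text file, a tabular file, or a data frame.
#' 1-based inclusive external coordinates (NEXUS charsets, RAxML ranges with
#' `\\3` strides) are converted at the boundary.
#'
#' @param path input file.
#' @param format `"auto"`, `"fasta"`, `"phylip"` or `"nexus"`.
#' @param partition_table optional path or data frame describing partitions;
#'   see [read_partition_table()]. For NEXUS input, `charset` lines in a SETS
#'   or ASSUMPTIONS block are honoured when no table is supplied.
#' @return a [partitioned_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus"),
                           partition_table = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) "nexus"
    else if (grepl("^\\s*>", first)) "fasta" else "phylip"
  }
  parts <- NULL
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                               as.string = FALSE)
    mat <- .seqs_to_matrix(lapply(seqs, as.character), names(seqs))
  } else if (format == "phylip") {
    mat <- .read_phylip_relaxed(path)
  } else {
    seqs <- ape::read.nexus.data(path)
    mat <- .seqs_to_matrix(seqs, names(seqs))
    if (is.null(partition_table)) {
      parts <- .parse_nexus_charsets(readLines(path), ncol(mat))
    }
  }
  if (!is.null(partition_table)) {
    parts <- read_partition_table(partition_table, n_sites = ncol(mat))
  }
  partitioned_alignment(mat, parts)
}

.seqs_to_matrix <- function(seqs, taxa) {
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1])
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    expected <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- taxa[which(lens != expected)[1]]
    stop("ragged alignment: taxon '", bad, "' has length ",
         lens[which(lens != expected)[1]], ", expected ", expected)
  }
  mat <- do.call(rbind, lapply(seqs, function(s) toupper(as.character(s))))
  rownames(mat) <- taxa
  mat
}

.read_phylip_relaxed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ntax <- as.integer(hdr[1]); nsite <- as.integer(hdr[2])
  if (is.na(ntax) || is.na(nsite)) stop("bad PHYLIP header")
  body <- lines[-1]
  nm <- character(0); sq <- list()
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(nm) < ntax) {  # sequential or first interleave block
      nm <- c(nm, f[1])
      sq[[f[1]]] <- paste(f[-1], collapse = "")
    } else {                  # continuation lines (interleaved)
      i <- (length(sq) %% ntax) + 1L  # unused branch for strictly sequential
      sq[[nm[i]]] <- paste0(sq[[nm[i]]], paste(f, collapse = ""))
    }
  }
  # sequential files may wrap sequences over several lines per taxon
  lens <- vapply(sq, nchar, 1L)
  if (any(lens != nsite)) {
    # re-parse as strictly sequential with wrapped lines
    nm <- character(0); sq <- list(); cur <- NULL
    for (ln in body) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (is.null(cur) || nchar(sq[[cur]]) >= nsite) {
        cur <- f[1]; nm <- c(nm, cur)
        sq[[cur]] <- paste(f[-1], collapse = "")
      } else {
        sq[[cur]] <- paste0(sq[[cur]], paste(f, collapse = ""))
      }
    }
    lens <- vapply(sq, nchar, 1L)
    if (any(lens != nsite)) {
      stop("ragged PHYLIP: taxon '", nm[which(lens != nsite)[1]], "'")
    }
  }
  mat <- do.call(rbind, lapply(sq, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- nm
  toupper(mat)
}

.parse_nexus_charsets <- function(lines, n_sites) {
  txt <- tolower(paste(lines, collapse = "\n"))
  m <- gregexpr("charset\\s+([^=;]+)=([^;]+);", txt)[[1]]
  if (m[1] == -1) return(NULL)
  orig <- paste(lines, collapse = "\n")
  mm <- regmatches(orig, gregexpr("(?i)charset\\s+[^=;]+=[^;]+;", orig))[[1]]
  parts <- lapply(mm, function(s) {
    s <- sub("(?i)charset\\s+", "", s, perl = TRUE)
    s <- sub(";\\s*$", "", s)
    kv <- strsplit(s, "=")[[1]]
    name <- trimws(kv[1])
    sites <- .parse_ranges(kv[2], n_sites)
    partition(name, sites)
  })
  parts
}

# "12-908\3, 1000-1200" style 1-based inclusive ranges with optional stride
.parse_ranges <- function(txt, n_sites) {
  out <- integer(0)
  for (tok in strsplit(trimws(txt), "[,[:space:]]+")[[1]]) {
    if (!nzchar(tok)) next
    stride <- 1L
    if (grepl("\\\\", tok)) {
      bits <- strsplit(tok, "\\\\")[[1]]
      stride <- as.integer(bits[2]); tok <- bits[1]
    }
    if (grepl("-", tok)) {
      se <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(se[1], se[2], by = stride))
    } else {
      out <- c(out, as.integer(tok))
    }
  }
  if (any(out < 1L | out > n_sites)) {
    stop("partition site index out of range 1..", n_sites)
  }
  sort(unique(out))
}

#' Read a partition table
#'
#' Two dialects: RAxML-style lines (`DNA, RAG1_pos1 = 12-908\\3`) and a
#' tabular file (TSV/CSV) with columns `name,start,end,stride` and optional
#' `origin,coding,frame,code`. A data frame with those columns is accepted
#' directly.
#'
#' @param x path or data frame.
#' @param n_sites total alignment length, for range validation.
#' @return list of [partition()] objects.
#' @export
read_partition_table <- function(x, n_sites) {
  if (is.data.frame(x)) {
    return(.parts_from_df(x, n_sites))
  }
  lines <- readLines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("=", lines[1])) {  # RAxML dialect
    parts <- lapply(lines, function(ln) {
      ln <- sub("^[A-Za-z]+\\s*,\\s*", "", ln)  # drop "DNA," prefix
      kv <- strsplit(ln, "=")[[1]]
      partition(trimws(kv[1]), .parse_ranges(kv[2], n_sites))
    })
    return(parts)
  }
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .parts_from_df(df, n_sites)
}

.parts_from_df <- function(df, n_sites) {
  need <- c("name", "start", "end")
  if (!all(need %in% names(df))) stop("partition table needs name,start,end")
  lapply(seq_len(nrow(df)), function(i) {
    stride <- if ("stride" %in% names(df) && !is.na(df$stride[i])) df$stride[i] else 1L
    sites <- seq(df$start[i], df$end[i], by = stride)
    if (any(sites < 1L | sites > n_sites)) {
      stop("partition '", df$name[i], "': site index out of range")
    }
    partition(df$name[i], sites,
              origin = if ("origin" %in% names(df)) df$origin[i] else NA_character_,
              coding = if ("coding" %in% names(df)) isTRUE(as.logical(df$coding[i])) else FALSE,
              frame = if ("frame" %in% names(df) && !is.na(df$frame[i])) as.integer(df$frame[i]) else if (isTRUE(as.logical(df$coding[i]))) 0L else NA_integer_,
              genetic_code = if ("code" %in% names(df) && !is.na(df$code[i])) df$code[i] else if (isTRUE(as.logical(df$coding[i]))) "standard" else NA_character_)
  })
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param aln a [partitioned_alignment()].
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  mat <- aln$matrix
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(mat))) {
      writeLines(c(paste0(">", rownames(mat)[i]),
                   paste(mat[i, ], collapse = "")), con)
    }
  } else {
    lines <- c(sprintf("%d %d", nrow(mat), ncol(mat)),
               vapply(seq_len(nrow(mat)), function(i) {
                 paste(rownames(mat)[i], paste(mat[i, ], collapse = ""))
               }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Extract the sub-alignment of one partition
#'
#' @param aln a [partitioned_alignment()].
#' @param part a partition name or [partition()] object.
#' @param drop_missing_taxa drop taxa with no determinate base in the block?
#' @return a [partitioned_alignment()] over the partition's sites.
#' @export
extract_partition <- function(aln, part, drop_missing_taxa = FALSE) {
  p <- if (inherits(part, "aln_partition")) part else aln$partitions[[part]]
  if (is.null(p)) stop("unknown partition: ", part)
  mat <- aln$matrix[, p$sites, drop = FALSE]
  if (drop_missing_taxa) {
    keep <- apply(mat, 1, function(r) any(r %in% c("A", "C", "G", "T")))
    mat <- mat[keep, , drop = FALSE]
  }
  np <- partition(p$name, seq_len(ncol(mat)), origin = p$origin,
                  coding = p$coding, frame = p$frame,
                  genetic_code = p$genetic_code)
  partitioned_alignment(mat, list(np))
}
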