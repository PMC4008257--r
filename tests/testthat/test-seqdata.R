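test_that("alignments round-trip through FASTA, PHYLIP and NEXUS", {
  mat <- rbind(tx1 = c("A", "C", "G", "T", "?", "-"),
               tx2 = c("a", "c", "g", "t", "N", "A"))
  a <- partitioned_alignment(mat)
  expect_true(all(a$matrix %in% c("A", "C", "G", "T", "?", "-", "N")))

  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(a, f)
  expect_identical(unname(read_alignment(f)$matrix), unname(a$matrix))

  f2 <- withr::local_tempfile(fileext = ".phy")
  write_alignment(a, f2, "phylip")
  expect_identical(unname(read_alignment(f2)$matrix), unname(a$matrix))

  # double round trip is idempotent
  write_alignment(read_alignment(f), f2, "phylip")
  expect_identical(unname(read_alignment(f2)$matrix), unname(a$matrix))
})

test_that("NEXUS charsets convert 1-based inclusive ranges", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=10;",
               "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX",
               "tx1 ACGTACGTAC", "tx2 ACGTAC??AC", ";", "END;",
               "BEGIN SETS;", "charset g12S = 1-4;",
               "charset RAG1 = 5-10;", "END;"), f)
  a <- read_alignment(f)
  expect_identical(a$partitions$g12S$sites, 1:4)
  expect_identical(a$partitions$RAG1$sites, 5:10)
})

test_that("RAxML-style partition tables handle strides and multiple ranges", {
  f <- withr::local_tempfile()
  writeLines(c("DNA, g_pos1 = 1-9\\3", "DNA, g_pos2 = 2-9\\3, 10-10"), f)
  p <- read_partition_table(f, 10)
  expect_identical(p[[1]]$sites, c(1L, 4L, 7L))
  expect_identical(p[[2]]$sites, c(2L, 5L, 8L, 10L))
  expect_error(read_partition_table(f, 8), "out of range")
})

test_that("malformed alignments are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment(f), "ragged")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_alignment(f), "duplicate taxon label")
})

test_that("clean_alignment removes all-missing rows/columns and re-indexes", {
  m <- rbind(a = c("A", "-", "C", "?", "G", "T"),
             b = rep("?", 6),
             c = c("A", "-", "C", "A", "G", "T"))
  parts <- list(partition("p1", 1:3), partition("p2", 4:6))
  cl <- clean_alignment(partitioned_alignment(m, parts))
  expect_identical(dim(cl$matrix), c(2L, 5L))
  rep <- attr(cl, "removal_report")
  expect_identical(rep$removed_taxa, "b")
  expect_identical(rep$removed_columns, 2L)
  expect_identical(cl$partitions$p1$sites, 1:2)
  expect_identical(cl$partitions$p2$sites, 3:5)

  # no-op on clean input; idempotent
  cl2 <- clean_alignment(cl)
  expect_identical(cl2$matrix, cl$matrix)

  # never removes a column with one determinate base
  expect_true(all(apply(cl$matrix, 2, function(col)
    any(col %in% c("A", "C", "G", "T")))))

  expect_error(clean_alignment(partitioned_alignment(
    matrix("?", 2, 2, dimnames = list(c("x", "y"), NULL)))), "empty")
})

test_that("codon-position split follows the frame and partitions the sites", {
  a6 <- partitioned_alignment(matrix("A", 1, 6, dimnames = list("x", NULL)),
                              list(partition("g", 1:6, coding = TRUE,
                                             frame = 0L)))
  sp <- split_codon_positions(a6, "g")
  expect_identical(sp$g_pos1$sites, c(1L, 4L))
  expect_identical(sp$g_pos2$sites, c(2L, 5L))
  expect_identical(sp$g_pos3$sites, c(3L, 6L))

  # 7 sites, frame 1: assignments 3,1,2,3,1,2,3
  a7 <- partitioned_alignment(matrix("A", 1, 7, dimnames = list("x", NULL)),
                              list(partition("g", 1:7, coding = TRUE,
                                             frame = 1L)))
  sp7 <- split_codon_positions(a7, "g")
  expect_identical(sp7$g_pos1$sites, c(2L, 5L))
  expect_identical(sp7$g_pos2$sites, c(3L, 6L))
  expect_identical(sp7$g_pos3$sites, c(1L, 4L, 7L))

  expect_error(split_codon_positions(
    partitioned_alignment(matrix("A", 1, 3, dimnames = list("x", NULL)),
                          list(partition("nc", 1:3))), "nc"), "not coding")
})

test_that("codon split partitions the parent site set for all frames and lengths", {
  for (frame in 0:2) {
    for (L in 1:30) {
      a <- partitioned_alignment(
        matrix("A", 1, L, dimnames = list("x", NULL)),
        list(partition("g", seq_len(L), coding = TRUE, frame = frame)))
      sp <- split_codon_positions(a, "g")
      all_sites <- sort(unname(unlist(lapply(sp, `[[`, "sites"))))
      expect_identical(all_sites, as.integer(seq_len(L)))
      expect_identical(sum(lengths(lapply(sp, `[[`, "sites"))), L)
    }
  }
})

test_that("stop-codon scan respects frame, code and ambiguity", {
  mk <- function(s, code = "standard", frame = 0L) {
    partitioned_alignment(
      matrix(strsplit(s, "")[[1]], 1, nchar(s), dimnames = list("z", NULL)),
      list(partition("g", seq_len(nchar(s)), coding = TRUE, frame = frame,
                     genetic_code = code)))
  }
  expect_identical(unname(check_reading_frame(mk("ATGAAACCC"), "g")), 0L)
  expect_identical(unname(check_reading_frame(mk("ATGTAAATG"), "g")), 1L)
  # ambiguous codon skipped, the TAA still counted
  expect_identical(unname(check_reading_frame(mk("AT?TAAATG"), "g")), 1L)
  # AGA is a stop only in the vertebrate-mitochondrial code
  expect_identical(unname(check_reading_frame(mk("ATGAGAATG"), "g")), 0L)
  expect_identical(unname(check_reading_frame(
    mk("ATGAGAATG", code = "vertebrate-mitochondrial"), "g")), 1L)
})

test_that("missing_fraction counts the configured symbol set", {
  expect_identical(missing_fraction(partitioned_alignment(
    matrix("?", 2, 3, dimnames = list(c("a", "b"), NULL)))), 1)
  m <- rbind(a = c("A", "C", "?", "G"), b = c("-", "T", "A", "C"))
  expect_identical(missing_fraction(partitioned_alignment(m)), 0.25)
  expect_identical(missing_fraction(partitioned_alignment(m),
                                    missing_chars = "?"), 0.125)
  expect_error(missing_fraction(matrix(character(0), 0, 0)), "empty")
})

test_that("concatenation fills absent gene blocks with ? and offsets partitions", {
  gA <- matrix("A", 2, 3, dimnames = list(c("t1", "t2"), NULL))
  gB <- matrix("C", 2, 2, dimnames = list(c("t2", "t3"), NULL))
  cc <- concatenate_genes(list(A = gA, B = gB))
  expect_identical(ncol(cc$matrix), 5L)
  expect_identical(sort(cc$taxa), c("t1", "t2", "t3"))
  expect_true(all(cc$matrix["t1", 4:5] == "?"))
  expect_true(all(cc$matrix["t3", 1:3] == "?"))
  expect_identical(cc$partitions$A$sites, 1:3)
  expect_identical(cc$partitions$B$sites, 4:5)

  # identical taxon sets: no fill
  cc2 <- concatenate_genes(list(A = gA, B = gA))
  expect_identical(missing_fraction(cc2), 0)

  # fill only adds missing data
  expect_gte(missing_fraction(cc), missing_fraction(partitioned_alignment(gA)))

  expect_error(concatenate_genes(list(A = rbind(gA, gA))), "duplicate")
})

test_that("concatenation followed by extraction recovers each gene on shared taxa", {
  set.seed(5)
  genes <- lapply(1:3, function(i) {
    taxa <- sample(sprintf("t%d", 1:6), sample(3:6, 1))
    matrix(sample(c("A", "C", "G", "T"), length(taxa) * 10, TRUE),
           length(taxa), 10, dimnames = list(taxa, NULL))
  })
  names(genes) <- paste0("g", 1:3)
  cc <- concatenate_genes(genes)
  for (nm in names(genes)) {
    ext <- extract_partition(cc, nm)
    shared <- rownames(genes[[nm]])
    expect_identical(ext$matrix[shared, , drop = FALSE], genes[[nm]][shared, ])
  }
})
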