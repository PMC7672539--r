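test_that("core extraction returns exactly the designed ungapped columns", {
  # gap-free alignment: every column is core
  full <- alignmentBlock(c(s1 = "ABCDEFGHIJ", s2 = "ABCDEFGHIJ"))
  cm <- extractCore(full)
  expect_equal(cm@coreColumns, 1:10)
  expect_equal(cm@map$s2$resno, 1:10)

  # designed layout: columns 2, 5, 7 are the only all-ungapped ones
  blk <- alignmentBlock(c(
    a = "-AB-CD-E",
    b = "XA-YCDZE",
    c = "QABRC-SE"))
  # ungapped in all: col2 (A/A/A), col5 (C/C/C), col8 (E/E/E)
  cm2 <- extractCore(blk)
  expect_equal(cm2@coreColumns, c(2L, 5L, 8L))
  expect_equal(cm2@map$a$resno, c(1L, 3L, 5L))   # a's 1st, 3rd, 5th residues
  expect_equal(cm2@map$b$resno, c(2L, 4L, 7L))
  expect_equal(cm2@map$c$resno, c(2L, 5L, 7L))
  expect_equal(cm2@map$a$core, 1:3)

  # a column gapped in a single sequence is excluded
  blk3 <- alignmentBlock(c(x = "AB", y = "A-"))
  expect_equal(extractCore(blk3)@coreColumns, 1L)

  allGap <- alignmentBlock(c(x = "A-", y = "-B"))
  expect_error(extractCore(allGap), "no common core")
  expect_error(extractCore(alignmentBlock(c(only = "ABC"))), "at least 2")
})

test_that("pivot concatenation reproduces a hand-merged alignment", {
  # two blocks sharing pivot P (ungapped sequence "ABCDE" in both)
  b1 <- alignmentBlock(c(P = "AB-CDE", A = "ABXC-E"))
  b2 <- alignmentBlock(c(P = "A-BCDE", B = "AYBC-E"))
  merged <- concatenateAlignments(list(b1, b2), pivot = "P")

  # pivot columns survive; block-private insertion columns are dropped
  expect_equal(merged@sequences[["P"]], "ABCDE")
  expect_equal(merged@sequences[["A"]], "ABC-E")
  expect_equal(merged@sequences[["B"]], "ABC-E")
  # A keeps its 1st, 2nd, 4th and 5th residues (X sat in a dropped column)
  expect_equal(merged@track$A$resno, c(1L, 2L, 4L, 5L))
  expect_equal(merged@track$B$resno, c(1L, 3L, 4L, 5L))

  core <- extractCore(merged)
  expect_equal(core@coreColumns, c(1L, 2L, 3L, 5L))

  # identical blocks concatenate to themselves
  same <- concatenateAlignments(list(b1, b1), pivot = "P")
  expect_identical(same@sequences, b1@sequences)
  expect_identical(same@track, b1@track)
})

test_that("pivot problems are reported precisely", {
  b1 <- alignmentBlock(c(P = "ABC", A = "ABC"))
  b2 <- alignmentBlock(c(Q = "ABC", B = "ABC"))
  expect_error(concatenateAlignments(list(b1, b2), pivot = "P"),
               "missing from block 2")
  b3 <- alignmentBlock(c(P = "ABD", B = "ABC"))
  expect_error(concatenateAlignments(list(b1, b3), pivot = "P"),
               "pivot residue 3")
})

test_that("adding structures can only shrink the core", {
  b1 <- alignmentBlock(c(P = "ABCDE", A = "AB-DE"))
  b2 <- alignmentBlock(c(P = "ABCDE", B = "A-CDE"))
  merged <- concatenateAlignments(list(b1, b2), pivot = "P")
  coreMerged <- extractCore(merged)@coreColumns
  core1 <- extractCore(b1)@coreColumns
  core2 <- extractCore(b2)@coreColumns
  expect_true(all(coreMerged %in% core1))
  expect_true(all(coreMerged %in% core2))
})

test_that("applyCore rewrites ensembles to consensus-numbered Calpha traces", {
  fix <- generateAlignmentFixture(c(d1 = "ABCDEFGHIJ", d2 = "AB-DEFGH-J",
                                    d3 = "ABCDEF-HIJ"), nModels = 3,
                                  seed = 4)
  cm <- extractCore(fix$block)
  expect_equal(cm@coreColumns, c(1L, 2L, 4L, 5L, 6L, 8L, 10L))
  mapped <- lapply(names(fix$ensembles), function(id)
    applyCore(fix$ensembles[[id]], cm, id))
  for (m in mapped) {
    expect_equal(nAtoms(m), 7)
    expect_equal(atomTable(m)$resno, 1:7)
    expect_equal(unique(atomTable(m)$name), "CA")
    expect_equal(nModels(m), 3)
  }

  # identity mapping over a full-length structure keeps every residue
  full <- extractCore(alignmentBlock(c(d1 = "ABCDE", d2 = "ABCDE")))
  e <- toyEnsemble(randomCloud(5), nCopies = 2, names = rep("CA", 5))
  out <- applyCore(e, full, "d1")
  expect_equal(nAtoms(out), 5)

  # referencing a residue the structure does not have is an error
  short <- toyEnsemble(randomCloud(3), nCopies = 2, names = rep("CA", 3))
  expect_error(applyCore(short, full, "d1"), "missing Calpha")
  expect_error(applyCore(e, full, "zz"), "not present")
})

test_that("core-mapped ensembles from different domains pool into one PCA", {
  fix <- generateAlignmentFixture(c(d1 = "ABCDEFGH--", d2 = "--CDEFGHIJ"),
                                  nModels = 5, jitter = 0.3, seed = 9)
  cm <- extractCore(fix$block)
  pooled <- lapply(names(fix$ensembles), function(id)
    applyCore(fix$ensembles[[id]], cm, id))
  ms <- combinedPCA(pooled)
  expect_equal(nrow(ms@atoms), length(cm@coreColumns))
  expect_equal(nrow(modeProjections(ms)), 10)
  expect_setequal(unique(modeProjections(ms)$ensemble), c("d1", "d2"))
})

test_that("aligned FASTA files load with ids, chains and residue tracks", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1|A", "AB-CD", ">s2|B", "ABXCD"), f)
  blk <- readAlignedFasta(f)
  expect_equal(names(blk@sequences), c("s1", "s2"))
  expect_equal(blk@track$s2$chain[1], "B")
  expect_equal(blk@track$s1$resno, 1:4)

  tr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#structure\tposition\tchain\tresno",
               paste("s1", 1:4, "A", c(301L, 302L, 310L, 311L),
                     sep = "\t")), tr)
  blk2 <- readAlignedFasta(f, tr)
  expect_equal(blk2@track$s1$resno, c(301L, 302L, 310L, 311L))
  expect_equal(extractCore(blk2)@map$s1$resno, c(301L, 302L, 310L, 311L))
})
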