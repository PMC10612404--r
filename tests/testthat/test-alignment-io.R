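test_that("cs strings decode to reference-anchored events", {
  ed <- extractEdits(":5*ac:3+g:2-tt:4", "c1", 100)
  expect_equal(canonEdits(ed), canonEdits(data.frame(
    contig = "c1", pos = c(105L, 108L, 111L), kind = c("SUB", "INS", "DEL"),
    ref = c("A", "", "TT"), alt = c("C", "G", ""))))

  expect_equal(nrow(extractEdits(":150", "c1", 0)), 0L)

  ed2 <- extractEdits("*at*cg", "c1", 10)
  expect_equal(ed2$pos, c(10L, 11L))
  expect_equal(ed2$kind, c("SUB", "SUB"))
  expect_equal(ed2$ref, c("A", "C"))
  expect_equal(ed2$alt, c("T", "G"))

  # maximal runs become single events; N is flagged
  ed3 <- extractEdits(":2+acg:1-tg:1", "c1", 0)
  expect_equal(ed3$kind, c("INS", "DEL"))
  expect_equal(ed3$alt[1], "ACG")
  expect_equal(ed3$ref[2], "TG")
  expect_true(extractEdits(":1*an:1", "c1", 0)$has_n)

  expect_error(extractEdits(":5*a:3", "c1", 0), "malformed cs")
  expect_error(extractEdits(":5~gt10ac:3", "c1", 0), "malformed cs")
})

test_that("PAF parsing keeps one primary record per read and requires cs", {
  p <- writePaf(c(
    pafLine("r1", "c1", 0, 100, ":100"),
    pafLine("r2", "c1", 200, 300, ":50*ac:49", tp = "P"),
    pafLine("r2", "c2", 0, 100, ":100", tp = "S")))
  a <- readAlignments(p)
  expect_s4_class(a, "ReadAlignments")
  expect_equal(nReads(a), 2L)
  expect_equal(a@nSecondary, 1L)
  al <- alignments(a)
  expect_equal(al$ref_start[al$read_id == "r2"], 200L)
  expect_equal(al$ref_end[al$read_id == "r2"], 300L)
  ed <- edits(a)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$pos, 250L)

  # perfect-match alignment yields no events
  expect_equal(nrow(ed[ed$read_id == "r1", ]), 0L)

  # without tp tags: first record per read wins, with a warning
  p2 <- writePaf(c(pafLine("r1", "c1", 0, 100, ":100", tp = NA),
                   pafLine("r1", "c2", 0, 100, ":100", tp = NA)))
  expect_warning(a2 <- readAlignments(p2), "tp tags")
  expect_equal(alignments(a2)$contig, "c1")

  # missing cs is a hard error naming the line
  p3 <- writePaf(c(pafLine("r1", "c1", 0, 100, cs = NA)))
  expect_error(readAlignments(p3), "line 1")

  expect_error(readAlignments(writePaf("not\ta\tpaf")), "fewer than 12")

  empty <- tempfile(fileext = ".paf")
  file.create(empty)
  expect_warning(ae <- readAlignments(empty), "empty")
  expect_equal(nReads(ae), 0L)
})

test_that("gzipped PAF and read-name truncation at whitespace work", {
  gz <- tempfile(fileext = ".paf.gz")
  con <- gzfile(gz, "wt")
  writeLines(pafLine("r9 extra comment", "c1", 5, 25, ":10*ga:9"), con)
  close(con)
  a <- readAlignments(gz)
  expect_equal(alignments(a)$read_id, "r9")
  expect_equal(edits(a)$pos, 15L)
})

test_that("SAM records decode via cs or CIGAR+MD and skip secondary records", {
  # reference window ACGTACGTAC; s1 carries an insertion of T after ref
  # pos 3 and a substitution A>G at ref pos 4
  sam <- writeSam(c(
    samRecord("s1", 0, "c1", 1, "4M1I6M", "ACGTTGCGTAC", md = "4A5"),
    samRecord("s2", 256, "c1", 1, "10M", "ACGTACGTAC", md = "10"),
    samRecord("s3", 0, "c1", 3, "5M", "GTACG", cs = ":2*at:2")))
  a <- readAlignments(sam)
  expect_equal(nReads(a), 2L)
  expect_equal(a@nSecondary, 1L)
  ed <- edits(a)
  e1 <- ed[ed$read_id == "s1", ]
  expect_equal(canonEdits(e1), canonEdits(data.frame(
    contig = "c1", pos = c(3L, 4L), kind = c("INS", "SUB"),
    ref = c("", "A"), alt = c("T", "G"))))
  e3 <- ed[ed$read_id == "s3", ]
  expect_equal(e3$pos, 4L)   # POS 3 is 1-based -> 2 + :2
  expect_equal(e3$ref, "A")

  # deletion: MD supplies the deleted reference bases
  sam2 <- writeSam(samRecord("d1", 0, "c1", 1, "3M2D3M", "ACGCGT",
                             md = "3^TA3"))
  ed2 <- edits(readAlignments(sam2))
  expect_equal(ed2$kind, "DEL")
  expect_equal(ed2$pos, 3L)
  expect_equal(ed2$ref, "TA")
  al2 <- alignments(readAlignments(sam2))
  expect_equal(al2$ref_end, 8L)  # 6M + 2D of reference span

  # neither cs nor MD is a hard error
  sam3 <- writeSam(samRecord("x1", 0, "c1", 1, "5M", "ACGTA"))
  expect_error(readAlignments(sam3), "neither cs nor MD")

  # reverse-strand flag is recorded but coordinates stay reference-based
  sam4 <- writeSam(samRecord("v1", 16, "c1", 11, "5M", "ACGTA", md = "5"))
  expect_equal(alignments(readAlignments(sam4))$strand, "-")
  expect_equal(alignments(readAlignments(sam4))$ref_start, 10L)
})

test_that("replaying parsed edits onto the reference reconstructs the read", {
  set.seed(7)
  for (i in 1:25) {
    fx <- randomEditFixture(len = 300, maxEdits = 8)
    paf <- writePaf(pafLine("r1", "c1", 0, 300, fx$cs))
    a <- readAlignments(paf)
    rebuilt <- eceval:::applyEdits(
      as.data.frame(edits(a)), fx$ref, 0L, 300L)
    expect_equal(rebuilt, fx$read)
  }
})

test_that("cs extraction agrees with a Needleman-Wunsch oracle", {
  set.seed(11)
  ok <- 0L
  for (i in 1:60) {
    fx <- randomEditFixture(len = 400, maxEdits = 10)
    mine <- normalizeIndels(extractEdits(fx$cs, "c1", 0L),
                            c(c1 = fx$ref))
    oracle <- normalizeIndels(nwOracleEdits(fx$ref, fx$read), c(c1 = fx$ref))
    expect_equal(canonEdits(mine), canonEdits(oracle))
    ok <- ok + 1L
  }
  expect_equal(ok, 60L)
})
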