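# Small in-memory alignment fixtures built through the PAF parser so the
# evaluation tests exercise the same code path as real data.
alnFixture <- function(...) {
  readAlignments(writePaf(c(...)))
}

test_that("raw-only, shared and corrected-only events split into CC/UC/OC", {
  # identity corrector: same single error in both -> 1 UC
  raw <- alnFixture(pafLine("r1", "c1", 100, 200, ":5*ac:94"))
  corr <- alnFixture(pafLine("r1", "c1", 100, 200, ":5*ac:94"))
  ev <- perRead(evaluateReads(raw, corr))
  expect_equal(unlist(ev[, c("cc", "uc", "oc")], use.names = FALSE),
               c(0L, 1L, 0L))

  # perfect corrector: both raw errors gone -> CC=2
  raw <- alnFixture(pafLine("r1", "c1", 100, 300, ":5*ac:94-gg:99"))
  corr <- alnFixture(pafLine("r1", "c1", 100, 300, ":200"))
  ev <- perRead(evaluateReads(raw, corr))
  expect_equal(unlist(ev[, c("cc", "uc", "oc")], use.names = FALSE),
               c(2L, 0L, 0L))

  # mixed case from set definitions: one fixed, one kept, one new
  raw <- alnFixture(pafLine("r1", "c1", 0, 500, ":105*ac:194*ga:199"))
  corr <- alnFixture(pafLine("r1", "c1", 0, 500, ":300*ga:99+t:100"))
  ev <- perRead(evaluateReads(raw, corr))
  expect_equal(unlist(ev[, c("cc", "uc", "oc")], use.names = FALSE),
               c(1L, 1L, 1L))
  cls <- events(evaluateReads(raw, corr))
  expect_equal(cls$class[cls$pos == 105], "CC")
  expect_equal(cls$class[cls$pos == 300], "UC")
  expect_equal(cls$class[cls$pos == 399], "OC")
})

test_that("event identity includes the alt allele unless relaxed", {
  raw <- alnFixture(pafLine("r1", "c1", 0, 100, ":50*ac:49"))
  corr <- alnFixture(pafLine("r1", "c1", 0, 100, ":50*ag:49"))
  strict <- perRead(evaluateReads(raw, corr))
  expect_equal(unlist(strict[, c("cc", "uc", "oc")], use.names = FALSE),
               c(1L, 0L, 1L))
  relaxed <- perRead(evaluateReads(raw, corr, matchAlt = FALSE))
  expect_equal(unlist(relaxed[, c("cc", "uc", "oc")], use.names = FALSE),
               c(0L, 1L, 0L))
})

test_that("comparison is restricted to the interval overlap", {
  # corrected read trimmed: raw error at pos 10 falls outside the overlap
  raw <- alnFixture(pafLine("r1", "c1", 0, 200, ":10*ac:150*ga:38"))
  corr <- alnFixture(pafLine("r1", "c1", 100, 200, ":100"))
  pr <- perRead(evaluateReads(raw, corr))
  expect_equal(unlist(pr[, c("cc", "uc", "oc")], use.names = FALSE),
               c(1L, 0L, 0L))   # only the in-overlap raw error counts as CC
  expect_equal(pr$trimmed_raw_events, 1L)
  expect_equal(pr$ovl_start, 100L)
  expect_equal(pr$ovl_end, 200L)
})

test_that("mapping-inconsistent reads are flagged and excluded from totals", {
  raw <- alnFixture(pafLine("r1", "c1", 0, 100, ":50*ac:49"),
                    pafLine("r2", "c1", 0, 100, ":100"))
  corr <- alnFixture(pafLine("r1", "c2", 0, 100, ":20*ac:79"),
                     pafLine("r2", "c1", 0, 100, ":100"))
  ev <- evaluateReads(raw, corr)
  pr <- perRead(ev)
  expect_false(pr$mapping_consistent[pr$read_id == "r1"])
  expect_true(pr$mapping_consistent[pr$read_id == "r2"])
  s <- summarizeEvaluation(ev)
  expect_equal(s@nExcluded, 1L)
  expect_equal(s@nReads, 1L)
  # same contig but disjoint intervals is also inconsistent
  corr2 <- alnFixture(pafLine("r1", "c1", 5000, 5100, ":100"),
                      pafLine("r2", "c1", 0, 100, ":100"))
  expect_false(perRead(evaluateReads(raw, corr2))$mapping_consistent[1])
})

test_that("pairing reports dropped and orphan reads and applies suffix rules", {
  raw <- alnFixture(pafLine("r1", "c1", 0, 100, ":100"),
                    pafLine("r2", "c1", 0, 100, ":100"),
                    pafLine("r3", "c1", 0, 100, ":100"))
  corr <- alnFixture(pafLine("r1", "c1", 0, 100, ":100"),
                     pafLine("r3", "c1", 0, 100, ":100"),
                     pafLine("r9", "c1", 0, 100, ":100"))
  pr <- pairReads(raw, corr)
  expect_setequal(pr$paired, c("r1", "r3"))
  expect_equal(pr$dropped, "r2")
  expect_equal(pr$orphans, "r9")

  corr_sfx <- alnFixture(pafLine("r1_corrected", "c1", 0, 100, ":100"))
  pr2 <- pairReads(raw, corr_sfx, stripSuffix = "_corrected")
  expect_equal(pr2$paired, "r1")

  disjoint <- alnFixture(pafLine("z1", "c1", 0, 100, ":100"))
  expect_warning(pr3 <- pairReads(raw, disjoint), "no read ids in common")
  expect_length(pr3$paired, 0L)
})

test_that("summary implements FDR and FNR with NA on empty denominators", {
  s <- summarizeEvaluation(list(cc = 90, uc = 10, oc = 10))
  expect_equal(s@fnr, 0.10)
  expect_equal(s@fdr, 0.10)
  s0 <- summarizeEvaluation(list(cc = 0, uc = 0, oc = 0))
  expect_true(is.na(s0@fdr))
  expect_true(is.na(s0@fnr))
  # exclusion contract: inconsistent reads only counted on request
  df <- data.frame(cc = c(1, 5), uc = 0, oc = 0,
                   mapping_consistent = c(TRUE, FALSE))
  expect_equal(summarizeEvaluation(df)@cc, 1)
  expect_equal(summarizeEvaluation(df, includeInconsistent = TRUE)@cc, 6)
  tab <- summaryTable(s)
  expect_equal(tab$FNR, 0.10)
  expect_equal(tab$CC, 90)
})

test_that("duplicate event keys collapse with a warning", {
  raw <- alnFixture(pafLine("r1", "c1", 0, 100, ":50*ac:49"))
  dup <- raw
  dup@edits <- rbind(dup@edits, dup@edits)
  corr <- alnFixture(pafLine("r1", "c1", 0, 100, ":100"))
  expect_warning(ev <- evaluateReads(dup, corr), "duplicate")
  expect_equal(perRead(ev)$cc, 1L)
})

test_that("symmetry and conservation hold on random synthetic evaluations", {
  sim <- simulateECData(simParams(genomeLength = 3e4, readLength = 1500,
                                  coverage = 6, pCorrect = 0.5,
                                  qOvercorrect = 1, seed = 91))
  raw <- readAlignments(emitTruthAlignments(sim, "raw"))
  corr <- readAlignments(emitTruthAlignments(sim, "corrected"))
  fwd <- perRead(evaluateReads(raw, corr))
  rev <- perRead(evaluateReads(corr, raw))
  m <- match(fwd$read_id, rev$read_id)
  expect_equal(fwd$cc, rev$oc[m])
  expect_equal(fwd$oc, rev$cc[m])
  expect_equal(fwd$uc, rev$uc[m])

  # conservation: CC + UC equals the raw in-overlap event count per read
  red <- edits(raw)
  rawCount <- table(factor(red$read_id, levels = fwd$read_id))
  cons <- fwd$mapping_consistent & fwd$trimmed_raw_events == 0
  expect_equal((fwd$cc + fwd$uc)[cons],
               as.integer(rawCount)[cons])

  s <- summarizeEvaluation(evaluateReads(raw, corr))
  expect_gte(s@fdr, 0); expect_lte(s@fdr, 1)
  expect_gte(s@fnr, 0); expect_lte(s@fnr, 1)
})
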