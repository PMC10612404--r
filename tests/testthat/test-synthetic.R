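test_that("parameter validation rejects impossible settings", {
  expect_error(simParams(errorRate = 2), "rates")
  expect_error(simParams(genomeLength = 0), "positive")
  expect_error(simulateECData(simParams(genomeLength = 1000,
                                        readLength = 5000)),
               "readLength exceeds")
})

test_that("the simulation is deterministic given the seed", {
  p <- simParams(genomeLength = 2e4, readLength = 1000, coverage = 4,
                 qOvercorrect = 1, seed = 123)
  s1 <- simulateECData(p)
  s2 <- simulateECData(p)
  expect_identical(s1$assembly, s2$assembly)
  expect_identical(s1$rawReads, s2$rawReads)
  expect_identical(s1$corrReads, s2$corrReads)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$errors, s2$errors)
  s3 <- simulateECData(simParams(genomeLength = 2e4, readLength = 1000,
                                 coverage = 4, qOvercorrect = 1, seed = 124))
  expect_false(identical(s1$assembly, s3$assembly))
})

test_that("the two haplotypes differ by heterozygous variants", {
  sim <- simulateECData(simParams(genomeLength = 5e4, readLength = 1000,
                                  coverage = 1, seed = 2))
  expect_setequal(names(sim$assembly), c("chr1_MAT", "chr1_PAT"))
  h1 <- sim$assembly[["chr1_MAT"]]
  h2 <- sim$assembly[["chr1_PAT"]]
  expect_false(h1 == h2)
  # indel rate shifts total length a little, SNP rate keeps it close
  expect_lt(abs(nchar(h1) - nchar(h2)) / nchar(h1), 0.01)
})

test_that("corrector extremes produce clean ledgers and clean reads", {
  base <- function(pc, q) simParams(genomeLength = 2e4, readLength = 1000,
                                    coverage = 4, pCorrect = pc,
                                    qOvercorrect = q, seed = 31)
  perfect <- simulateECData(base(1, 0))
  expect_true(all(perfect$reads$n_missed == 0))
  expect_true(all(perfect$reads$n_introduced == 0))
  # every corrected read is the exact error-free haplotype substring
  for (i in seq_len(nrow(perfect$reads))) {
    rd <- perfect$reads[i, ]
    expect_identical(perfect$corrReads[[rd$read_id]],
                     substr(perfect$assembly[[rd$contig]],
                            rd$start + 1, rd$end))
  }

  identity <- simulateECData(base(0, 0))
  expect_true(all(identity$reads$n_fixed == 0))
  expect_identical(identity$corrReads, identity$rawReads)
})

test_that("the truth ledger is internally consistent", {
  sim <- simulateECData(simParams(genomeLength = 4e4, readLength = 1500,
                                  coverage = 6, pCorrect = 0.7,
                                  qOvercorrect = 1, sHapswitch = 0.1,
                                  seed = 77))
  rd <- sim$reads
  er <- sim$errors
  expect_equal(rd$n_injected, rd$n_fixed + rd$n_missed)
  agg <- as.data.frame(table(er$read_id, er$status))
  for (i in seq_len(nrow(rd))) {
    mine <- er[er$read_id == rd$read_id[i], ]
    expect_equal(sum(mine$status == "introduced"), rd$n_introduced[i])
    expect_equal(sum(mine$status == "injected_missed"), rd$n_missed[i])
  }
  # raw reads really contain the injected errors: length accounting
  for (i in which(!rd$switched)[1:5]) {
    mine <- er[er$read_id == rd$read_id[i] & er$status != "introduced", ]
    expLen <- (rd$end[i] - rd$start[i]) +
      sum(nchar(mine$alt[mine$kind == "INS"])) -
      sum(nchar(mine$ref[mine$kind == "DEL"]))
    expect_equal(nchar(sim$rawReads[[rd$read_id[i]]]), expLen)
  }
})

test_that("emitted truth alignments round-trip through the PAF parser", {
  sim <- simulateECData(simParams(genomeLength = 2e4, readLength = 1000,
                                  coverage = 4, pCorrect = 0.5,
                                  qOvercorrect = 1, sHapswitch = 0.2,
                                  seed = 41))
  paf <- emitTruthAlignments(sim, "raw")
  a <- readAlignments(paf)
  expect_equal(nReads(a), nrow(sim$reads))
  # parsed events equal the ledgered injected errors
  ed <- as.data.frame(edits(a))[, c("read_id", "contig", "pos", "kind",
                                    "ref", "alt")]
  truth <- as.data.frame(sim$errors[sim$errors$status != "introduced",
                                    c("read_id", "contig", "pos", "kind",
                                      "ref", "alt")])
  o <- function(d) d[order(d$read_id, d$pos, d$kind), ]
  rownames(ed) <- rownames(truth) <- NULL
  expect_equal(o(ed), o(truth), ignore_attr = TRUE)
  # replaying the cs-derived edits reconstructs every raw read
  al <- alignments(a)
  for (i in seq_len(min(20, nrow(al)))) {
    id <- al$read_id[i]
    mine <- ed[ed$read_id == id, ]
    rebuilt <- eceval:::applyEdits(mine, sim$assembly[[al$contig[i]]],
                                   al$ref_start[i], al$ref_end[i])
    expect_identical(rebuilt, sim$rawReads[[id]])
  }
  # switched corrected reads land on the opposite haplotype, error-free
  ca <- alignments(readAlignments(emitTruthAlignments(sim, "corrected")))
  sw <- sim$reads[sim$reads$switched, ]
  m <- match(sw$read_id, ca$read_id)
  expect_true(all(ca$contig[m] == sw$corr_contig))
  expect_true(all(ca$contig[m] != sw$contig))
})

test_that("simulation files are written in standard formats", {
  dir <- file.path(tempdir(), "simout")
  sim <- simulateECData(simParams(genomeLength = 1e4, readLength = 800,
                                  coverage = 2, seed = 6), dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("assembly.fasta", "raw.fastq", "corrected.fasta",
      "truth_reads.tsv", "truth_errors.tsv")))))
  asm <- Biostrings::readDNAStringSet(file.path(dir, "assembly.fasta"))
  expect_equal(as.character(asm), sim$assembly)
  fq <- readLines(file.path(dir, "raw.fastq"))
  expect_equal(length(fq), 4 * nrow(sim$reads))
  expect_match(readLines(file.path(dir, "truth_reads.tsv"), n = 1), "seed=6")
})
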