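BASES <- c("A", "C", "G", "T")

#' Parameters for the ground-truthed diploid read simulator
#'
#' Builds the parameter list consumed by [simulateECData()].  Defaults
#' emulate a small diploid HiFi experiment: ~15 kb reads at 30-fold
#' coverage with a uniform 0.2% base error rate (70% substitutions, 15%
#' insertions, 15% deletions, all single-base), a diploid genome whose
#' two haplotypes differ by heterozygous SNPs (1e-3/bp) and short
#' indels (2e-4/bp), and a pseudo-corrector that fixes each injected
#' error with probability `pCorrect`, introduces `qOvercorrect` new
#' errors per read in expectation, and rewrites a read onto the opposite
#' haplotype with probability `sHapswitch`.
#'
#' @param genomeLength total haploid genome length in bp.
#' @param nChromosomes number of chromosomes (each contributes a `_MAT`
#'   and a `_PAT` contig to the truth assembly).
#' @param hetSnpRate,hetIndelRate per-bp heterozygous SNP / indel rates
#'   between the two haplotypes.
#' @param readLength read length in bp (reference span of each read).
#' @param coverage fold coverage of the haploid genome.
#' @param errorRate per-bp probability of an injected sequencing error.
#' @param errorMix length-3 probability vector over
#'   substitution/insertion/deletion.
#' @param pCorrect probability the pseudo-corrector fixes an injected
#'   error.
#' @param qOvercorrect expected number of newly introduced errors per
#'   corrected read (Poisson).
#' @param sHapswitch probability a corrected read is rewritten as the
#'   clean opposite-haplotype sequence.
#' @param unambiguous place errors >= 5 bp apart, away from read ends
#'   and outside homopolymer context, so that every injected event has a
#'   unique alignment representation and exact per-read accounting is
#'   possible.  Default `FALSE` (unrestricted placement).
#' @param seed integer seed; the whole simulation is deterministic given
#'   the seed.
#' @return A validated named list of class `SimParams`.
#' @export
simParams <- function(genomeLength = 1e6, nChromosomes = 1L,
                      hetSnpRate = 1e-3, hetIndelRate = 2e-4,
                      readLength = 15000L, coverage = 30,
                      errorRate = 0.002, errorMix = c(0.70, 0.15, 0.15),
                      pCorrect = 0.9, qOvercorrect = 0.5, sHapswitch = 0,
                      unambiguous = FALSE, seed = 1L) {
  p <- list(genomeLength = as.integer(genomeLength),
            nChromosomes = as.integer(nChromosomes),
            hetSnpRate = hetSnpRate, hetIndelRate = hetIndelRate,
            readLength = as.integer(readLength), coverage = coverage,
            errorRate = errorRate, errorMix = errorMix / sum(errorMix),
            pCorrect = pCorrect, qOvercorrect = qOvercorrect,
            sHapswitch = sHapswitch, unambiguous = isTRUE(unambiguous),
            seed = as.integer(seed))
  rates <- c(p$hetSnpRate, p$hetIndelRate, p$errorRate, p$pCorrect,
             p$sHapswitch)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0,1]")
  if (p$qOvercorrect < 0) stop("qOvercorrect must be non-negative")
  if (p$genomeLength <= 0 || p$readLength <= 0 || p$nChromosomes <= 0)
    stop("lengths must be positive")
  if (length(p$errorMix) != 3L) stop("errorMix must have 3 components")
  class(p) <- "SimParams"
  p
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

otherBase <- function(b, exclude = character(0)) {
  sample(setdiff(BASES, c(b, exclude)), 1L)
}

# Apply heterozygous SNPs/indels to a haplotype-1 char vector to produce
# haplotype 2.
mutateHaplotype <- function(v, snpRate, indelRate) {
  L <- length(v)
  snpPos <- which(stats::runif(L) < snpRate)
  for (p in snpPos) v[p] <- otherBase(v[p])
  indPos <- which(stats::runif(L) < indelRate)
  if (!length(indPos)) return(paste(v, collapse = ""))
  isIns <- stats::runif(length(indPos)) < 0.5
  lens <- sample(1:3, length(indPos), replace = TRUE)
  pieces <- character(0)
  cur <- 1L
  for (k in seq_along(indPos)) {
    p <- indPos[k]
    if (p < cur) next                       # swallowed by a previous deletion
    pieces <- c(pieces, paste(v[cur:p], collapse = ""))
    if (isIns[k]) {
      pieces <- c(pieces, randSeq(lens[k]))
      cur <- p + 1L
    } else {
      cur <- min(p + lens[k], L) + 1L
    }
  }
  if (cur <= L) pieces <- c(pieces, paste(v[cur:L], collapse = ""))
  paste(pieces, collapse = "")
}

# Draw error events inside a read window.  `win` is the window char
# vector, positions are 0-based relative to the window start.  Existing
# positions are avoided with the mode's minimum spacing.
drawErrors <- function(n, win, mix, unambiguous, existing = integer(0)) {
  wlen <- length(win)
  minGap <- if (unambiguous) 5L else 2L
  lo <- if (unambiguous) 5L else 1L
  hi <- wlen - 1L - lo
  taken <- existing
  out <- vector("list", n)
  got <- 0L
  for (k in seq_len(n)) {
    for (try in 1:200) {
      p <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      if (length(taken) && min(abs(taken - p)) < minGap) next
      kind <- sample(c("SUB", "INS", "DEL"), 1L, prob = mix)
      b <- win[p + 1L]
      if (kind == "SUB") {
        ev <- list(pos = p, kind = kind, ref = b, alt = otherBase(b))
      } else if (kind == "DEL") {
        if (unambiguous && (win[p] == b || win[p + 2L] == b)) next
        ev <- list(pos = p, kind = kind, ref = b, alt = "")
      } else {
        excl <- if (unambiguous) c(b, win[p + 2L]) else character(0)
        if (length(setdiff(BASES, excl)) == 0L) next
        ev <- list(pos = p, kind = kind, ref = "", alt = otherBase("", excl))
      }
      taken <- c(taken, p)
      got <- got + 1L
      out[[got]] <- ev
      break
    }
  }
  if (!got) return(NULL)
  data.table(pos = vapply(out[1:got], `[[`, numeric(1), "pos"),
             kind = vapply(out[1:got], `[[`, character(1), "kind"),
             ref = vapply(out[1:got], `[[`, character(1), "ref"),
             alt = vapply(out[1:got], `[[`, character(1), "alt"))
}

#' Simulate a ground-truthed error-correction experiment
#'
#' Generates a two-haplotype genome, samples reads uniformly from both
#' haplotypes, injects sequencing errors at the configured rate, and
#' builds "corrected" reads by a pseudo-corrector that operates directly
#' on the truth ledger: each injected error is fixed with probability
#' `pCorrect`, new errors are introduced at rate `qOvercorrect` per
#' read, and with probability `sHapswitch` the read is rewritten as the
#' clean sequence of the opposite haplotype.  Because corrections are
#' bookkept rather than inferred, the per-read numbers of correct
#' corrections, under-corrections and over-corrections are known
#' exactly, which is what makes hermetic end-to-end testing of the
#' evaluation pipeline possible.
#'
#' @param params a `SimParams` list from [simParams()].
#' @param dir optional directory; when given, writes `assembly.fasta`,
#'   `raw.fastq`, `corrected.fasta`, `truth_reads.tsv` and
#'   `truth_errors.tsv` there.
#' @return A list of class `ECSimulation`: `assembly` (named character
#'   vector of contig sequences), `rawReads`/`corrReads` (named
#'   character vectors), `reads` (per-read ledger, incl. switch flag and
#'   the CC/UC/OC truth `n_fixed`/`n_missed`/`n_introduced`), `errors`
#'   (per-error ledger with `status` in
#'   `injected_fixed`/`injected_missed`/`introduced`), and `params`.
#' @export
simulateECData <- function(params = simParams(), dir = NULL) {
  stopifnot(inherits(params, "SimParams"))
  withSeed(params$seed, {
    chrLen <- as.integer(round(params$genomeLength / params$nChromosomes))
    if (params$readLength > chrLen)
      stop("readLength exceeds chromosome length (", chrLen, " bp)")
    assembly <- character(0)
    for (c in seq_len(params$nChromosomes)) {
      h1 <- randSeq(chrLen)
      h2 <- mutateHaplotype(strsplit(h1, "", fixed = TRUE)[[1L]],
                            params$hetSnpRate, params$hetIndelRate)
      assembly[[paste0("chr", c, "_MAT")]] <- h1
      assembly[[paste0("chr", c, "_PAT")]] <- h2
    }
    contigs <- names(assembly)
    clen <- nchar(assembly)
    chromOf <- sub("_(MAT|PAT)$", "", contigs)
    mateOf <- ifelse(grepl("_MAT$", contigs),
                     sub("_MAT$", "_PAT", contigs),
                     sub("_PAT$", "_MAT", contigs))

    nReads <- as.integer(ceiling(params$coverage * params$genomeLength /
                                 params$readLength))
    splitAssembly <- lapply(assembly, function(s) strsplit(s, "", fixed = TRUE)[[1L]])

    reads <- vector("list", nReads)
    errs <- vector("list", nReads)
    raw <- character(nReads)
    corr <- character(nReads)
    ids <- sprintf("read%05d", seq_len(nReads))
    for (i in seq_len(nReads)) {
      ctg_i <- sample(seq_along(contigs), 1L, prob = clen)
      ctg <- contigs[ctg_i]
      L <- clen[ctg_i]
      start <- sample.int(L - params$readLength + 1L, 1L) - 1L
      end <- start + params$readLength
      win <- splitAssembly[[ctg]][(start + 1L):end]

      nInj <- stats::rbinom(1L, params$readLength, params$errorRate)
      inj <- drawErrors(nInj, win, params$errorMix, params$unambiguous)
      injPos <- if (is.null(inj)) integer(0) else inj$pos
      injTab <- if (is.null(inj)) NULL else
        data.table(read_id = ids[i], contig = ctg, pos = as.integer(start + inj$pos),
                   kind = inj$kind, ref = inj$ref, alt = inj$alt)
      rawEd <- if (is.null(injTab)) emptySimEdits() else injTab
      raw[i] <- applyEdits(rawEd, assembly[[ctg]], start, end)

      switched <- stats::runif(1L) < params$sHapswitch
      if (switched) {
        mate <- mateOf[ctg_i]
        mlen <- nchar(assembly[[mate]])
        cstart <- min(start, mlen - params$readLength)
        cend <- cstart + params$readLength
        corr[i] <- substr(assembly[[mate]], cstart + 1L, cend)
        status <- if (is.null(injTab)) character(0) else rep("injected_fixed", nrow(injTab))
        missIntro <- NULL
        corrLocus <- list(contig = mate, start = cstart, end = cend)
      } else {
        fixed <- if (length(injPos)) stats::runif(length(injPos)) < params$pCorrect
                 else logical(0)
        nIntro <- stats::rpois(1L, params$qOvercorrect)
        intro <- drawErrors(nIntro, win, params$errorMix, params$unambiguous,
                            existing = injPos)
        status <- c(ifelse(fixed, "injected_fixed", "injected_missed"),
                    if (!is.null(intro)) rep("introduced", nrow(intro)))
        introTab <- if (is.null(intro)) NULL else
          data.table(read_id = ids[i], contig = ctg,
                     pos = as.integer(start + intro$pos),
                     kind = intro$kind, ref = intro$ref, alt = intro$alt)
        missIntro <- rbindlist(c(
          if (!is.null(injTab) && any(!fixed)) list(injTab[!fixed]),
          if (!is.null(introTab)) list(introTab)))
        corrEd <- if (is.null(missIntro) || !nrow(missIntro)) emptySimEdits()
                  else missIntro
        corr[i] <- applyEdits(corrEd, assembly[[ctg]], start, end)
        corrLocus <- list(contig = ctg, start = start, end = end)
      }
      allTab <- rbindlist(c(if (!is.null(injTab)) list(injTab),
                            if (!switched && exists("introTab") &&
                                !is.null(introTab)) list(introTab)))
      if (!is.null(allTab) && nrow(allTab)) {
        data.table::set(allTab, j = "status", value = status)
        errs[[i]] <- allTab
      }
      nFixed <- sum(status == "injected_fixed")
      nMissed <- sum(status == "injected_missed")
      nIntrod <- sum(status == "introduced")
      reads[[i]] <- data.table(
        read_id = ids[i], hap = sub("^.*_", "", ctg), contig = ctg,
        start = start, end = end, switched = switched,
        corr_contig = corrLocus$contig, corr_start = corrLocus$start,
        corr_end = corrLocus$end,
        n_injected = nFixed + nMissed, n_fixed = nFixed,
        n_missed = nMissed, n_introduced = nIntrod)
      rm(list = intersect("introTab", ls()))
    }
    names(raw) <- ids
    names(corr) <- ids
    sim <- list(assembly = assembly, rawReads = raw, corrReads = corr,
                reads = rbindlist(reads),
                errors = if (length(e <- Filter(Negate(is.null), errs)))
                           rbindlist(e) else emptySimErrors(),
                params = params)
    class(sim) <- "ECSimulation"
    if (!is.null(dir)) writeSimulation(sim, dir)
    sim
  })
}

emptySimEdits <- function() data.table(
  read_id = character(), contig = character(), pos = integer(),
  kind = character(), ref = character(), alt = character())

emptySimErrors <- function() data.table(
  read_id = character(), contig = character(), pos = integer(),
  kind = character(), ref = character(), alt = character(),
  status = character())

#' @export
print.ECSimulation <- function(x, ...) {
  cat("ECSimulation: ", length(x$assembly), " contig(s), ",
      nrow(x$reads), " reads, ", nrow(x$errors), " ledgered errors ",
      "(seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(sim$assembly, file.path(dir, "assembly.fasta"))
  writeFastq(sim$rawReads, file.path(dir, "raw.fastq"))
  writeFasta(sim$corrReads, file.path(dir, "corrected.fasta"))
  hdr <- paste0("# eceval simulation seed=", sim$params$seed)
  rt <- file.path(dir, "truth_reads.tsv")
  writeLines(hdr, rt)
  suppressWarnings(data.table::fwrite(sim$reads, rt, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  et <- file.path(dir, "truth_errors.tsv")
  writeLines(hdr, et)
  suppressWarnings(data.table::fwrite(sim$errors, et, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(dir)
}

writeFasta <- function(seqs, path) {
  out <- Biostrings::DNAStringSet(unname(seqs))
  names(out) <- names(seqs)
  Biostrings::writeXStringSet(out, path, format = "fasta")
  invisible(path)
}

writeFastq <- function(seqs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("I", nchar(seqs[[i]]))), con)
  invisible(path)
}

#' Emit truth alignments as PAF with cs tags
#'
#' Writes one primary PAF record per read, placed at the read's true
#' locus with a cs tag reconstructed from the ledgered error list (raw
#' reads carry all injected errors; corrected reads carry missed plus
#' introduced errors, or a perfect match on the opposite haplotype's
#' contig for switched reads).  This bypasses the aligner entirely, so
#' the evaluation pipeline can be exercised hermetically: the parsed
#' events are exactly the ledgered ones.
#'
#' @param sim an `ECSimulation` from [simulateECData()].
#' @param which `"raw"` or `"corrected"`.
#' @param path output PAF path; a temporary file by default.
#' @param mapq mapping quality written on every record (default 60).
#' @return The PAF path, invisibly.
#' @export
emitTruthAlignments <- function(sim, which = c("raw", "corrected"),
                                path = tempfile(fileext = ".paf"), mapq = 60L) {
  which <- match.arg(which)
  stopifnot(inherits(sim, "ECSimulation"))
  rd <- sim$reads
  er <- as.data.table(sim$errors)
  lines <- character(nrow(rd))
  for (i in seq_len(nrow(rd))) {
    id <- rd$read_id[i]
    if (which == "raw") {
      ctg <- rd$contig[i]; s <- rd$start[i]; e <- rd$end[i]
      ed <- er[er$read_id == id & er$status != "introduced"]
    } else {
      ctg <- rd$corr_contig[i]; s <- rd$corr_start[i]; e <- rd$corr_end[i]
      ed <- if (rd$switched[i]) er[0L]
            else er[er$read_id == id & er$status %in%
                    c("injected_missed", "introduced")]
    }
    cs <- buildCs(ed, sim$assembly[[ctg]], s, e)
    nIns <- sum(nchar(ed$alt[ed$kind == "INS"]))
    nDel <- sum(nchar(ed$ref[ed$kind == "DEL"]))
    nSub <- sum(ed$kind == "SUB")
    qlen <- (e - s) + nIns - nDel
    nmatch <- (e - s) - nDel - nSub
    lines[i] <- paste(id, qlen, 0L, qlen, "+", ctg, nchar(sim$assembly[[ctg]]),
                      s, e, nmatch, (e - s) + nIns, mapq,
                      "tp:A:P", paste0("cs:Z:", cs), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
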