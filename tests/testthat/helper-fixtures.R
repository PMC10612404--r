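# Shared fixture builders: hand-made PAF/SAM text and a Needleman-Wunsch
# oracle (Biostrings::pairwiseAlignment) independent of the cs parser.

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

pafLine <- function(id, contig, start, end, cs, mapq = 60, tp = "P",
                    tlen = 100000, strand = "+") {
  qlen <- end - start  # close enough for fixtures; parser ignores it
  tags <- c(if (!is.na(tp)) paste0("tp:A:", tp),
            if (!is.na(cs)) paste0("cs:Z:", cs))
  paste(c(id, qlen, 0, qlen, strand, contig, tlen, start, end,
          qlen, qlen, mapq, tags), collapse = "\t")
}

writePaf <- function(lines, path = tempfile(fileext = ".paf")) {
  writeLines(lines, path)
  path
}

samRecord <- function(id, flag, contig, pos1, cigar, seq, mapq = 60,
                      md = NA, cs = NA) {
  tags <- c(if (!is.na(md)) paste0("MD:Z:", md),
            if (!is.na(cs)) paste0("cs:Z:", cs))
  paste(c(id, flag, contig, pos1, mapq, cigar, "*", 0, 0, seq, "*", tags),
        collapse = "\t")
}

writeSam <- function(records, path = tempfile(fileext = ".sam"),
                     header = "@HD\tVN:1.6") {
  writeLines(c(header, records), path)
  path
}

# Canonical form of an edit event table for set comparison.
canonEdits <- function(df) {
  df <- as.data.frame(df)[, c("contig", "pos", "kind", "ref", "alt")]
  df <- df[order(df$contig, df$pos, df$kind, df$ref, df$alt), ]
  rownames(df) <- NULL
  df
}

# Independent oracle: global Needleman-Wunsch alignment of the read
# against the reference window, events read off the aligned strings.
nwOracleEdits <- function(refWin, read, contig = "c1", refStart = 0L) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(read, refWin, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 4, gapExtension = 2)
  pv <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sv <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  out <- list()
  cur <- refStart
  i <- 1L
  while (i <= length(pv)) {
    if (sv[i] == "-") {
      j <- i
      while (j <= length(pv) && sv[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, pos = cur - 1L, kind = "INS", ref = "",
        alt = paste(pv[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (pv[i] == "-") {
      j <- i
      while (j <= length(pv) && pv[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, pos = cur, kind = "DEL",
        ref = paste(sv[i:(j - 1L)], collapse = ""), alt = "")
      cur <- cur + (j - i)
      i <- j
    } else {
      if (pv[i] != sv[i])
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, pos = cur, kind = "SUB", ref = sv[i], alt = pv[i])
      cur <- cur + 1L
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), pos = integer(),
                      kind = character(), ref = character(),
                      alt = character()))
  do.call(rbind, out)
}

# Random reference window with unambiguously placed edits, plus the read
# implied by them and the cs string encoding them.  Two nearby gaps of
# opposite sign can cancel into a cheaper run of substitutions under
# optimal alignment, in which case the encoded edits are not the
# parsimonious ones, so indels are kept well separated.
randomEditFixture <- function(len = 500, maxEdits = 10, contig = "c1") {
  ref <- randomDna(len)
  win <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n <- sample(0:maxEdits, 1L)
  ed <- eceval:::drawErrors(n, win, c(0.5, 0.25, 0.25), unambiguous = TRUE)
  if (!is.null(ed) && sum(ed$kind != "SUB") > 1L) {
    o <- order(ed$pos)
    ed <- ed[o]
    keep <- rep(TRUE, nrow(ed))
    lastIndel <- -Inf
    for (i in seq_len(nrow(ed))) {
      if (ed$kind[i] == "SUB") next
      if (ed$pos[i] - lastIndel < 30) keep[i] <- FALSE
      else lastIndel <- ed$pos[i]
    }
    ed <- ed[keep]
  }
  edTab <- if (is.null(ed)) {
    data.frame(contig = character(), pos = integer(), kind = character(),
               ref = character(), alt = character())
  } else {
    data.frame(contig = contig, pos = as.integer(ed$pos), kind = ed$kind,
               ref = ed$ref, alt = ed$alt)
  }
  list(ref = ref,
       read = eceval:::applyEdits(edTab, ref, 0L, len),
       cs = eceval:::buildCs(edTab, ref, 0L, len),
       edits = edTab)
}
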