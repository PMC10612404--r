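#' Read primary alignments and their edit events from PAF or SAM
#'
#' Parses an alignment file into a [ReadAlignments-class] object holding
#' exactly one primary alignment per read and the reference-anchored
#' edit events (substitutions and gaps) of each alignment.  PAF records
#' must carry a short-form `cs` tag (align with `minimap2 --cs`); SAM
#' records may carry either a `cs` tag or CIGAR plus `MD`, from which
#' equivalent events are derived.  Files may be gzip-compressed.
#'
#' Primary selection: PAF records tagged `tp:A:S`/`tp:A:I` and SAM
#' records with the secondary (0x100) or supplementary (0x800) flag are
#' skipped and counted.  When a PAF file carries no `tp` tags at all, the
#' first record per read name is taken as primary, with a warning.
#'
#' @param path PAF or SAM file, optionally `.gz`.
#' @param format `"auto"` (by extension, default), `"paf"` or `"sam"`.
#' @return A [ReadAlignments-class] object.
#' @seealso [extractEdits()] for the cs-tag event semantics,
#'   [normalizeIndels()] for indel left-alignment.
#' @export
readAlignments <- function(path, format = c("auto", "paf", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext, paf = "paf", sam = "sam",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=\"paf\" or \"sam\""))
  }
  lines <- readLines(gzfile(path))
  if (format == "paf") parsePafLines(lines, path) else parseSamLines(lines, path)
}

firstWord <- function(x) sub("\\s.*$", "", x)

pafTag <- function(fields, prefix) {
  hit <- fields[startsWith(fields, prefix)]
  if (length(hit)) substring(hit[1L], nchar(prefix) + 1L) else NA_character_
}

parsePafLines <- function(lines, src) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty alignment file: ", src)
    return(new("ReadAlignments", alignments = emptyAlignments(),
               edits = emptyEdits(), nSecondary = 0L, source = src))
  }
  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf < 12L))
    stop("unparseable PAF line ", which(nf < 12L)[1L], " in ", src,
         ": fewer than 12 fields")
  qname <- firstWord(vapply(fl, `[[`, character(1), 1L))
  strand <- vapply(fl, `[[`, character(1), 5L)
  tname <- vapply(fl, `[[`, character(1), 6L)
  tstart <- as.integer(vapply(fl, `[[`, character(1), 8L))
  tend <- as.integer(vapply(fl, `[[`, character(1), 9L))
  mapq <- as.integer(vapply(fl, `[[`, character(1), 12L))
  tagpart <- lapply(fl, function(f) if (length(f) > 12L) f[13:length(f)] else character(0))
  tp <- vapply(tagpart, pafTag, character(1), prefix = "tp:A:")
  cs <- vapply(tagpart, pafTag, character(1), prefix = "cs:Z:")

  if (all(is.na(tp))) {
    warning("PAF has no tp tags; taking the first record per read as primary")
    primary <- rep(TRUE, length(qname))
  } else {
    primary <- !is.na(tp) & tp == "P"
    # tag-less records in a tagged file: candidate primaries for reads
    # that have no tagged primary record
    untagged <- is.na(tp)
    primary[untagged] <- !qname[untagged] %in% qname[primary]
  }
  # keep the first primary candidate per read
  prim_idx <- which(primary)
  prim_idx <- prim_idx[!duplicated(qname[prim_idx])]
  nSecondary <- length(lines) - length(prim_idx)

  missing_cs <- prim_idx[is.na(cs[prim_idx])]
  if (length(missing_cs))
    stop("PAF record without cs tag at line ", missing_cs[1L], " in ", src,
         "; re-run minimap2 with --cs")
  if (anyNA(tstart[prim_idx]) || anyNA(tend[prim_idx]))
    stop("unparseable PAF coordinates in ", src)

  aln <- data.table(read_id = qname[prim_idx], contig = tname[prim_idx],
                    ref_start = tstart[prim_idx], ref_end = tend[prim_idx],
                    strand = strand[prim_idx], mapq = mapq[prim_idx])
  ed <- parseCsMany(cs[prim_idx], tname[prim_idx], tstart[prim_idx],
                    qname[prim_idx], line = prim_idx)
  setorderv(ed, c("read_id", "pos"))
  new("ReadAlignments", alignments = aln, edits = ed,
      nSecondary = as.integer(nSecondary), source = src)
}

parseSamLines <- function(lines, src) {
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (!length(body_idx)) {
    warning("empty alignment file: ", src)
    return(new("ReadAlignments", alignments = emptyAlignments(),
               edits = emptyEdits(), nSecondary = 0L, source = src))
  }
  fl <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf < 11L))
    stop("unparseable SAM line ", body_idx[which(nf < 11L)[1L]], " in ", src)
  flag <- as.integer(vapply(fl, `[[`, character(1), 2L))
  qname <- firstWord(vapply(fl, `[[`, character(1), 1L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  keep <- !unmapped & !secondary
  keep[keep] <- !duplicated(qname[keep])
  nSecondary <- sum(secondary)

  aln_list <- vector("list", sum(keep))
  ed_list <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- fl[[i]]
    line_no <- body_idx[i]
    rname <- f[3L]
    pos0 <- as.integer(f[4L]) - 1L
    cigar <- f[6L]
    seq <- toupper(f[10L])
    tags <- if (length(f) > 11L) f[12:length(f)] else character(0)
    cs <- pafTag(tags, "cs:Z:")
    md <- pafTag(tags, "MD:Z:")
    ref_span <- cigarRefSpan(cigar, line_no, src)
    if (!is.na(cs)) {
      ed <- parseCsMany(cs, rname, pos0, qname[i], line = line_no)
    } else if (!is.na(md)) {
      ed <- editsFromCigarMd(cigar, md, seq, rname, pos0, qname[i], line_no, src)
    } else {
      stop("SAM record at line ", line_no, " in ", src,
           " has neither cs nor MD tag; cannot extract edits")
    }
    j <- j + 1L
    aln_list[[j]] <- data.table(
      read_id = qname[i], contig = rname, ref_start = pos0,
      ref_end = pos0 + ref_span,
      strand = if (bitwAnd(flag[i], 16L)) "-" else "+",
      mapq = as.integer(f[5L]))
    ed_list[[j]] <- ed
  }
  aln <- rbindlist(aln_list)
  ed <- rbindlist(ed_list)
  if (!nrow(ed)) ed <- emptyEdits()
  setorderv(ed, c("read_id", "pos"))
  new("ReadAlignments", alignments = aln, edits = ed,
      nSecondary = as.integer(nSecondary), source = src)
}

cigarOps <- function(cigar, line_no, src) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  if (paste(toks, collapse = "") != cigar)
    stop("malformed CIGAR '", cigar, "' at line ", line_no, " in ", src)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

cigarRefSpan <- function(cigar, line_no, src) {
  cg <- cigarOps(cigar, line_no, src)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

# Derive SUB/INS/DEL events from CIGAR + MD.  MD supplies the reference
# base(s) at mismatches and deletions; SEQ supplies the read bases.
editsFromCigarMd <- function(cigar, md, seq, contig, refStart, read_id,
                             line_no, src) {
  cg <- cigarOps(cigar, line_no, src)
  refPos <- refStart
  qPos <- 0L                                  # 0-based index into seq
  m_ref <- integer(0); m_q <- integer(0)      # per-M-base coordinates
  evs <- list()
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      m_ref <- c(m_ref, refPos + seq_len(len) - 1L)
      m_q <- c(m_q, qPos + seq_len(len) - 1L)
      refPos <- refPos + len; qPos <- qPos + len
    } else if (op == "I") {
      evs[[length(evs) + 1L]] <- data.table(
        read_id = read_id, contig = contig, pos = refPos - 1L, kind = "INS",
        ref = "", alt = substr(seq, qPos + 1L, qPos + len), has_n = FALSE)
      qPos <- qPos + len
    } else if (op == "D") {
      evs[[length(evs) + 1L]] <- data.table(
        read_id = read_id, contig = contig, pos = refPos, kind = "DEL",
        ref = NA_character_, alt = "", has_n = FALSE)   # ref filled from MD
      refPos <- refPos + len
    } else if (op == "N") {
      refPos <- refPos + len
    } else if (op == "S") {
      qPos <- qPos + len
    }                                          # H/P: no cursor movement
  }
  # walk MD over the M-bases and D-runs
  mdt <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  if (paste(mdt, collapse = "") != md)
    stop("malformed MD tag '", md, "' at line ", line_no, " in ", src)
  mi <- 0L                                    # M-bases consumed
  di <- 0L                                    # deletion events consumed
  del_idx <- which(vapply(evs, function(e) e$kind[1L] == "DEL", logical(1)))
  for (t in mdt) {
    if (grepl("^[0-9]+$", t)) {
      mi <- mi + as.integer(t)
    } else if (startsWith(t, "^")) {
      di <- di + 1L
      if (di > length(del_idx))
        stop("MD/CIGAR deletion mismatch at line ", line_no, " in ", src)
      evs[[del_idx[di]]]$ref <- toupper(substring(t, 2L))
    } else {
      mi <- mi + 1L
      if (mi > length(m_ref))
        stop("MD/CIGAR length mismatch at line ", line_no, " in ", src)
      evs[[length(evs) + 1L]] <- data.table(
        read_id = read_id, contig = contig, pos = m_ref[mi], kind = "SUB",
        ref = toupper(t), alt = substr(seq, m_q[mi] + 1L, m_q[mi] + 1L),
        has_n = FALSE)
    }
  }
  if (di != length(del_idx))
    stop("MD/CIGAR deletion mismatch at line ", line_no, " in ", src)
  if (!length(evs)) return(emptyEdits())
  ed <- rbindlist(evs)
  ed[, `:=`(has_n = grepl("N", ref, fixed = TRUE) | grepl("N", alt, fixed = TRUE))]
  setorderv(ed, "pos")
  ed[]
}
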