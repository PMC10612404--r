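#' Extract edit events from a minimap2 short-form cs tag
#'
#' Walks the cs difference string and emits one reference-anchored event
#' per substituted base (`SUB`), one per maximal run of inserted bases
#' (`INS`) and one per maximal run of deleted bases (`DEL`).  The
#' reference cursor is advanced by `:len` matches, by 1 for each `*`
#' substitution and by the run length for `-` deletions; insertions do
#' not consume reference.  cs tags are written in reference orientation,
#' so no coordinate depends on the strand of the alignment.
#'
#' Coordinates are 0-based.  For an insertion, `pos` is the reference
#' coordinate immediately after which the inserted bases appear.
#'
#' @param cs the short-form cs string (operations `:len`, `*rq`, `+seq`,
#'   `-seq`), without the `cs:Z:` prefix.
#' @param contig reference contig name.
#' @param refStart 0-based reference start of the alignment.
#' @return A `data.frame` of events in reference order with columns
#'   `contig`, `pos`, `kind`, `ref`, `alt`, `has_n`.
#' @examples
#' extractEdits(":5*ac:3+g:2-tt:4", "c1", 100)
#' @export
extractEdits <- function(cs, contig, refStart) {
  stopifnot(length(cs) == 1L)
  out <- parseCsMany(cs, contig, as.integer(refStart), read_id = "q")
  as.data.frame(out[, c("contig", "pos", "kind", "ref", "alt", "has_n")])
}

# Vectorised cs parser over many records; returns a data.table of events
# with read_id attached.  `line` (optional) gives the source line number
# for error messages.
parseCsMany <- function(cs, contig, refStart, read_id, line = NULL) {
  n <- length(cs)
  stopifnot(length(contig) == n, length(refStart) == n, length(read_id) == n)
  if (n == 0L) return(emptyEdits())
  rx <- "(:[0-9]+)|(\\*[A-Za-z][A-Za-z])|(\\+[A-Za-z]+)|(-[A-Za-z]+)"
  m <- gregexpr(rx, cs, perl = TRUE)
  toks <- regmatches(cs, m)
  glued <- vapply(toks, paste, character(1), collapse = "")
  bad <- which(glued != cs)
  if (length(bad)) {
    i <- bad[1L]
    where <- if (is.null(line)) paste0("record ", i) else paste0("line ", line[i])
    # first position where the tokenisation diverges
    g <- glued[i]; s <- cs[i]
    k <- which(strsplit(g, "")[[1L]][seq_len(min(nchar(g), nchar(s)))] !=
               strsplit(s, "")[[1L]][seq_len(min(nchar(g), nchar(s)))])
    at <- if (length(k)) k[1L] else min(nchar(g), nchar(s)) + 1L
    stop("malformed cs string at ", where, ", near '",
         substr(s, at, min(nchar(s), at + 9L)), "'")
  }
  ntok <- lengths(toks)
  keep <- ntok > 0L
  if (!any(keep)) return(emptyEdits())
  tok <- unlist(toks[keep], use.names = FALSE)
  idx <- rep(which(keep), ntok[keep])
  op <- substr(tok, 1L, 1L)
  body <- substring(tok, 2L)
  adv <- integer(length(tok))
  adv[op == ":"] <- as.integer(body[op == ":"])
  adv[op == "*"] <- 1L
  adv[op == "-"] <- nchar(body[op == "-"])
  # reference cursor before each token, restarting at refStart per record
  cum <- cumsum(adv)
  first <- !duplicated(idx)
  base <- cum[first] - adv[first]               # cumulative offset at record start
  cursor <- refStart[idx] + (cum - adv) - base[match(idx, idx[first])]
  ev <- op != ":"
  if (!any(ev)) return(emptyEdits())
  op <- op[ev]; body <- toupper(body[ev]); cursor <- cursor[ev]; idx <- idx[ev]
  kind <- c("*" = "SUB", "+" = "INS", "-" = "DEL")[op]
  pos <- ifelse(op == "+", cursor - 1L, cursor)
  ref <- ifelse(op == "*", substr(body, 1L, 1L), ifelse(op == "-", body, ""))
  alt <- ifelse(op == "*", substr(body, 2L, 2L), ifelse(op == "+", body, ""))
  data.table(read_id = read_id[idx], contig = contig[idx], pos = as.integer(pos),
             kind = unname(kind), ref = ref, alt = alt,
             has_n = grepl("N", ref, fixed = TRUE) | grepl("N", alt, fixed = TRUE))
}

# Build a short-form cs string from an edit table for one read aligned at
# [refStart, refEnd) of `refseq` (full contig string).  Events must be
# sorted, non-overlapping and within the interval.
buildCs <- function(edits, refseq, refStart, refEnd) {
  parts <- character(0)
  cur <- refStart
  if (nrow(edits)) {
    o <- order(edits$pos, match(edits$kind, c("SUB", "DEL", "INS")))
    edits <- edits[o, ]
    for (i in seq_len(nrow(edits))) {
      k <- edits$kind[i]; p <- edits$pos[i]
      at <- if (k == "INS") p + 1L else p
      if (at > cur) parts <- c(parts, paste0(":", at - cur))
      cur <- at
      if (k == "SUB") {
        parts <- c(parts, paste0("*", tolower(edits$ref[i]), tolower(edits$alt[i])))
        cur <- cur + 1L
      } else if (k == "INS") {
        parts <- c(parts, paste0("+", tolower(edits$alt[i])))
      } else {
        parts <- c(parts, paste0("-", tolower(edits$ref[i])))
        cur <- cur + nchar(edits$ref[i])
      }
    }
  }
  if (refEnd > cur) parts <- c(parts, paste0(":", refEnd - cur))
  paste(parts, collapse = "")
}

# Apply the events of one read to the reference substring [refStart, refEnd)
# and return the read sequence implied by the alignment.  Used for
# round-trip checks and by the simulator.
applyEdits <- function(edits, refseq, refStart, refEnd) {
  ref <- substr(refseq, refStart + 1L, refEnd)
  if (!nrow(edits)) return(ref)
  o <- order(edits$pos, match(edits$kind, c("SUB", "DEL", "INS")))
  edits <- edits[o, ]
  out <- character(0)
  cur <- refStart
  for (i in seq_len(nrow(edits))) {
    k <- edits$kind[i]; p <- edits$pos[i]
    at <- if (k == "INS") p + 1L else p
    if (at > cur) out <- c(out, substr(refseq, cur + 1L, at))
    cur <- at
    if (k == "SUB") {
      out <- c(out, edits$alt[i]); cur <- cur + 1L
    } else if (k == "INS") {
      out <- c(out, edits$alt[i])
    } else {
      cur <- cur + nchar(edits$ref[i])
    }
  }
  if (refEnd > cur) out <- c(out, substr(refseq, cur + 1L, refEnd))
  paste(out, collapse = "")
}
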