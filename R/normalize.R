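#' Left-align insertion and deletion events against the reference
#'
#' The same biological indel can be reported at different reference
#' positions depending on how the aligner placed the gap (classically,
#' anywhere within a repeat).  Before comparing the edit events of a raw
#' and a corrected alignment, each `INS`/`DEL` event is shifted to its
#' smallest equivalent reference position (standard left-alignment, as
#' used for VCF normalization).  Substitutions are position-fixed and
#' pass through unchanged; output is re-sorted by position.
#'
#' @param x a [ReadAlignments-class] object, or a `data.frame` of edit
#'   events (columns `contig`, `pos`, `kind`, `ref`, `alt`).
#' @param ref the reference: a named `character` vector of contig
#'   sequences, a [Biostrings::DNAStringSet], or a FASTA path.
#' @return An object of the same class as `x` with indels left-aligned.
#' @export
normalizeIndels <- function(x, ref) {
  ref <- asRefSeqs(ref)
  if (is(x, "ReadAlignments")) {
    ed <- as.data.table(x@edits)
    ed <- normalizeEditTable(ed, ref)
    setorderv(ed, c("read_id", "pos"))
    out <- x
    out@edits <- ed
    return(out)
  }
  ed <- as.data.table(x)
  ed <- normalizeEditTable(ed, ref)
  if ("read_id" %in% names(ed)) setorderv(ed, c("read_id", "pos"))
  else setorderv(ed, c("contig", "pos"))
  as.data.frame(ed)
}

asRefSeqs <- function(ref) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref))
    ref <- Biostrings::readDNAStringSet(ref)
  if (is(ref, "DNAStringSet")) {
    out <- toupper(as.character(ref))
    names(out) <- firstWord(names(ref))
    return(out)
  }
  if (is.character(ref)) {
    if (is.null(names(ref))) stop("reference sequences must be named by contig")
    return(toupper(ref))
  }
  stop("unsupported reference type: ", class(ref)[1L])
}

normalizeEditTable <- function(ed, ref) {
  if (!nrow(ed)) return(ed)
  miss <- setdiff(unique(ed$contig), names(ref))
  if (length(miss))
    stop("contig(s) not present in reference: ", paste(miss, collapse = ", "))
  idx <- which(ed$kind != "SUB")
  if (!length(idx)) return(ed)
  newpos <- ed$pos
  newref <- ed$ref
  newalt <- ed$alt
  for (i in idx) {
    ctg <- ref[[ed$contig[i]]]
    L <- nchar(ctg)
    if (ed$pos[i] < 0L || ed$pos[i] >= L)
      stop("edit position ", ed$pos[i], " outside contig ", ed$contig[i])
    if (ed$kind[i] == "DEL") {
      sh <- leftShiftDel(ctg, ed$pos[i], nchar(ed$ref[i]))
      newpos[i] <- sh
      newref[i] <- substr(ctg, sh + 1L, sh + nchar(ed$ref[i]))
    } else {
      sh <- leftShiftIns(ctg, ed$pos[i], ed$alt[i])
      newpos[i] <- sh$pos
      newalt[i] <- sh$alt
    }
  }
  ed$pos <- newpos; ed$ref <- newref; ed$alt <- newalt
  ed$has_n <- grepl("N", ed$ref, fixed = TRUE) | grepl("N", ed$alt, fixed = TRUE)
  ed
}

# Deletion of ref[p .. p+len-1] (0-based) can move to p-1 iff the base
# before the deletion equals the last deleted base.
leftShiftDel <- function(ctg, p, len) {
  while (p > 0L && substr(ctg, p, p) == substr(ctg, p + len, p + len))
    p <- p - 1L
  p
}

# Insertion of `alt` after 0-based position p can move to p-1 iff the
# reference base at p equals the last inserted base; the inserted string
# rotates right as it moves.
leftShiftIns <- function(ctg, p, alt) {
  L <- nchar(alt)
  while (p >= 0L && p + 1L <= nchar(ctg) &&
         substr(ctg, p + 1L, p + 1L) == substr(alt, L, L)) {
    alt <- paste0(substr(ctg, p + 1L, p + 1L), substr(alt, 1L, L - 1L))
    p <- p - 1L
  }
  list(pos = p, alt = alt)
}
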