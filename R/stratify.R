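#' Load a BED file as a labelled region set
#'
#' Reads a 3+ column BED file (0-based, half-open), merges overlapping
#' and adjacent intervals, and returns a [RegionSet-class] for
#' stratifying correction errors.
#'
#' @param path BED file path, optionally gzipped.
#' @param label stratum label; defaults to the file name.
#' @param knownContigs optional character vector of truth-assembly contig
#'   names; intervals on other contigs trigger a warning but are kept.
#' @return A [RegionSet-class] object.
#' @export
loadBed <- function(path, label = NULL, knownContigs = NULL) {
  if (is.null(label)) label <- sub("\\.bed(\\.gz)?$", "", basename(path))
  lines <- readLines(gzfile(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(regionSet(label, GenomicRanges::GRanges()))
  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 columns")
  ctg <- vapply(fl, `[[`, character(1), 1L)
  s <- suppressWarnings(as.integer(vapply(fl, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.integer(vapply(fl, `[[`, character(1), 3L)))
  bad <- which(is.na(s) | is.na(e) | e <= s | s < 0L)
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path,
         ": need 0 <= start < end")
  if (!is.null(knownContigs)) {
    unk <- setdiff(unique(ctg), knownContigs)
    if (length(unk))
      warning("BED contig(s) not in the assembly: ", paste(unk, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(ctg, IRanges::IRanges(start = s + 1L, end = e))
  regionSet(label, gr)
}

#' Construct a RegionSet from a GRanges (merging intervals)
#'
#' @param label stratum label.
#' @param gr a `GRanges`; overlapping/adjacent intervals are merged.
#' @return A [RegionSet-class] object.
#' @export
regionSet <- function(label, gr) {
  new("RegionSet", label = label, regions = GenomicRanges::reduce(gr))
}

#' Annotate homopolymer runs of an assembly
#'
#' Finds every maximal run of a single base of length at least `minLen`
#' in the assembly and returns the runs as a region set, so correction
#' error rates can be stratified inside vs outside homopolymers.  On a
#' homopolymer-compressed assembly this is empty for `minLen >= 2` by
#' construction.
#'
#' @param assembly FASTA path, [Biostrings::DNAStringSet], or named
#'   character vector of contig sequences.
#' @param minLen minimum run length (default 3).
#' @return A [RegionSet-class] labelled `"homopolymer"`.
#' @export
annotateHomopolymers <- function(assembly, minLen = 3L) {
  seqs <- asRefSeqs(assembly)
  ctg_v <- character(0); start_v <- integer(0); end_v <- integer(0)
  for (ctg in names(seqs)) {
    r <- rle(strsplit(seqs[[ctg]], "", fixed = TRUE)[[1L]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= minLen
    if (any(keep)) {
      ctg_v <- c(ctg_v, rep(ctg, sum(keep)))
      start_v <- c(start_v, starts[keep])
      end_v <- c(end_v, ends[keep])
    }
  }
  regionSet("homopolymer",
            GenomicRanges::GRanges(ctg_v,
                                   IRanges::IRanges(start = start_v,
                                                    end = end_v)))
}

#' Stratify correction errors by genomic annotation
#'
#' Attributes each classified event of a [ReadEvaluationSet-class] to
#' every region set whose intervals contain its reference position (for
#' a deletion, any deleted base; for an insertion, its anchor base), and
#' computes per-stratum CC/UC/OC totals and FDR/FNR.  Strata are not
#' mutually exclusive: an event inside two supplied annotations counts
#' once in each.  Events falling in no supplied annotation make up the
#' residual `"other"` stratum; with no regions supplied a single `"all"`
#' stratum equals the global summary.
#'
#' @param evalset a [ReadEvaluationSet-class].
#' @param regionSets list of [RegionSet-class] objects (may be empty).
#' @return A `data.frame`: `label`, `CC`, `UC`, `OC`, `FDR`, `FNR`.
#' @export
stratifiedSummary <- function(evalset, regionSets = list()) {
  stopifnot(is(evalset, "ReadEvaluationSet"))
  ev <- as.data.table(evalset@events)
  row_of <- function(lab, cc, uc, oc) data.frame(
    label = lab, CC = cc, UC = uc, OC = oc,
    FDR = if (cc + oc > 0) oc / (cc + oc) else NA_real_,
    FNR = if (cc + uc > 0) uc / (cc + uc) else NA_real_)
  tally <- function(sub) row_of(NA, sum(sub$class == "CC"),
                                sum(sub$class == "UC"), sum(sub$class == "OC"))
  if (!length(regionSets)) {
    out <- tally(ev); out$label <- "all"
    return(out)
  }
  # event footprint: SUB/INS occupy one base at pos (anchor); DEL spans
  # its deleted bases
  w <- ifelse(ev$kind == "DEL", nchar(ev$ref), 1L)
  egr <- GenomicRanges::GRanges(ev$contig,
                                IRanges::IRanges(start = ev$pos + 1L,
                                                 width = pmax(w, 1L)))
  in_any <- rep(FALSE, nrow(ev))
  out <- list()
  for (rs in regionSets) {
    stopifnot(is(rs, "RegionSet"))
    hit <- unique(S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(egr, regions(rs)))))
    in_any[hit] <- TRUE
    r <- tally(ev[hit]); r$label <- regionLabel(rs)
    out[[length(out) + 1L]] <- r
  }
  r <- tally(ev[!in_any]); r$label <- "other"
  out[[length(out) + 1L]] <- r
  do.call(rbind, out)
}
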