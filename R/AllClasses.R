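#' @import methods
#' @importFrom data.table data.table as.data.table := setkeyv setorderv rbindlist setnames
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

EDIT_COLS <- c("read_id", "contig", "pos", "kind", "ref", "alt")
ALN_COLS  <- c("read_id", "contig", "ref_start", "ref_end", "strand", "mapq")

#' Per-read primary alignments with reference-anchored edit events
#'
#' Container for one alignment file's worth of primary alignments.  Each
#' read contributes exactly one record; its differences to the reference
#' (substitutions, insertions, deletions) are stored as a flat event table
#' in 0-based half-open reference coordinates.
#'
#' @slot alignments data.frame with columns `read_id`, `contig`,
#'   `ref_start`, `ref_end` (0-based, half-open), `strand`, `mapq`.
#' @slot edits data.frame with columns `read_id`, `contig`, `pos`, `kind`
#'   (`SUB`/`INS`/`DEL`), `ref`, `alt`.  For `INS`, `pos` is the reference
#'   coordinate immediately after which the inserted bases appear and
#'   `ref` is empty; for `DEL`, `alt` is empty.  Events carrying `N` are
#'   flagged in the logical column `has_n`.
#' @slot nSecondary number of secondary/supplementary records skipped.
#' @slot source path or label of the parsed file.
#' @export
setClass("ReadAlignments", representation(
  alignments = "data.frame",
  edits      = "data.frame",
  nSecondary = "integer",
  source     = "character"
))

setValidity("ReadAlignments", function(object) {
  a <- object@alignments
  e <- object@edits
  msg <- character()
  if (!all(ALN_COLS %in% names(a)))
    msg <- c(msg, paste("alignments must have columns:", paste(ALN_COLS, collapse = ", ")))
  if (!all(c(EDIT_COLS, "has_n") %in% names(e)))
    msg <- c(msg, paste("edits must have columns:", paste(c(EDIT_COLS, "has_n"), collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(a$read_id))
    msg <- c(msg, "duplicate read_id after primary selection")
  if (nrow(a) && any(a$ref_start >= a$ref_end))
    msg <- c(msg, "ref_start must be < ref_end")
  if (nrow(e) && !all(e$kind %in% c("SUB", "INS", "DEL")))
    msg <- c(msg, "edit kind must be SUB, INS or DEL")
  if (length(msg)) msg else TRUE
})

#' Per-read CC/UC/OC evaluation results
#'
#' Result of comparing each read's raw and corrected alignments.  The
#' per-read table carries the counts and the mapping-consistency flag;
#' the event table retains every classified event with its reference
#' coordinate so results can be stratified by genomic region.
#'
#' @slot perRead data.frame with one row per paired read: `read_id`,
#'   `contig`, `ovl_start`, `ovl_end`, `cc`, `uc`, `oc`,
#'   `mapping_consistent`, `trimmed_raw_events`.
#' @slot events data.frame of classified events (`class` is `CC`, `UC` or
#'   `OC`) for mapping-consistent reads, same columns as
#'   [edits()] plus `class`.
#' @slot dropped character vector of raw read ids with no corrected
#'   counterpart (reads discarded by the EC tool).
#' @slot orphans character vector of corrected read ids with no raw
#'   counterpart.
#' @slot params list of evaluation settings (`match_alt`, `drop_n`).
#' @export
setClass("ReadEvaluationSet", representation(
  perRead = "data.frame",
  events  = "data.frame",
  dropped = "character",
  orphans = "character",
  params  = "list"
))

setValidity("ReadEvaluationSet", function(object) {
  p <- object@perRead
  need <- c("read_id", "contig", "ovl_start", "ovl_end", "cc", "uc", "oc",
            "mapping_consistent", "trimmed_raw_events")
  if (!all(need %in% names(p)))
    return(paste("perRead must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) && any(p$cc < 0 | p$uc < 0 | p$oc < 0))
    return("counts must be non-negative")
  TRUE
})

#' Aggregate correction-accuracy summary
#'
#' Totals of correct corrections (CC), under-corrections (UC) and
#' over-corrections (OC) over mapping-consistent reads, with the two
#' headline metrics: FDR = OC/(CC+OC) and FNR = UC/(CC+UC).  Metrics are
#' `NA` when their denominator is zero.
#'
#' @slot nReads number of reads entering the totals.
#' @slot nExcluded number of mapping-inconsistent reads excluded.
#' @slot cc,uc,oc event totals.
#' @slot fdr,fnr rates in [0,1] or `NA`.
#' @export
setClass("EvaluationSummary", representation(
  nReads    = "integer",
  nExcluded = "integer",
  cc = "numeric", uc = "numeric", oc = "numeric",
  fdr = "numeric", fnr = "numeric"
))

setValidity("EvaluationSummary", function(object) {
  ok <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!ok(object@fdr) || !ok(object@fnr)) return("fdr/fnr must be in [0,1] or NA")
  TRUE
})

#' A labelled set of genomic intervals
#'
#' Sorted, merged 0-based half-open intervals used to stratify correction
#' errors by annotation (e.g. centromeric satellites, segmental
#' duplications, homopolymer runs).
#'
#' @slot label stratum name.
#' @slot regions a [GenomicRanges::GRanges] of merged intervals (the
#'   GRanges is 1-based internally; constructors convert from the 0-based
#'   half-open convention used by BED and PAF).
#' @export
setClass("RegionSet", representation(
  label   = "character",
  regions = "GRanges"
))

#' Contig name to (chromosome, haplotype) resolution rule
#'
#' Resolves truth-assembly contig names into a chromosome label and a
#' haplotype label via a regular expression with two capture groups, so
#' that reads whose raw and corrected alignments land on different
#' contigs can be classified as haplotype vs chromosome differences.
#' The default pattern handles `<chr>_<MAT|PAT>` / `<chr>_<hap1|hap2>`
#' style dual assemblies.
#'
#' @slot pattern regular expression with exactly two capture groups:
#'   chromosome first, haplotype second.
#' @export
setClass("HaplotypeMap", representation(pattern = "character"))

setValidity("HaplotypeMap", function(object) {
  if (length(object@pattern) != 1L || is.na(object@pattern))
    return("pattern must be a single string")
  TRUE
})

emptyEdits <- function() {
  data.table(read_id = character(), contig = character(), pos = integer(),
             kind = character(), ref = character(), alt = character(),
             has_n = logical())
}

emptyAlignments <- function() {
  data.table(read_id = character(), contig = character(),
             ref_start = integer(), ref_end = integer(),
             strand = character(), mapq = integer())
}
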