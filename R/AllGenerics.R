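#' Accessors for eceval classes
#'
#' `alignments()` and `edits()` return the record and event tables of a
#' [ReadAlignments-class]; `nReads()` the number of primary alignments.
#' `perRead()` and `events()` return the per-read and per-event tables of
#' a [ReadEvaluationSet-class]; `regions()` and `regionLabel()` the
#' interval set and label of a [RegionSet-class].
#'
#' @param x an eceval object.
#' @return A `data.frame` (tables), `integer` (counts), `GRanges` or
#'   `character` as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))
#' @rdname accessors
#' @export
setGeneric("edits", function(x) standardGeneric("edits"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))
#' @rdname accessors
#' @export
setGeneric("perRead", function(x) standardGeneric("perRead"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname accessors
#' @export
setMethod("alignments", "ReadAlignments", function(x) as.data.frame(x@alignments))
#' @rdname accessors
#' @export
setMethod("edits", "ReadAlignments", function(x) as.data.frame(x@edits))
#' @rdname accessors
#' @export
setMethod("nReads", "ReadAlignments", function(x) nrow(x@alignments))
#' @rdname accessors
#' @export
setMethod("perRead", "ReadEvaluationSet", function(x) as.data.frame(x@perRead))
#' @rdname accessors
#' @export
setMethod("events", "ReadEvaluationSet", function(x) as.data.frame(x@events))
#' @rdname accessors
#' @export
setMethod("nReads", "ReadEvaluationSet", function(x) nrow(x@perRead))
#' @rdname accessors
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("regionLabel", "RegionSet", function(x) x@label)

setMethod("show", "ReadAlignments", function(object) {
  cat("ReadAlignments object\n")
  cat("  source:             ", object@source, "\n", sep = "")
  cat("  primary alignments: ", nrow(object@alignments), "\n", sep = "")
  cat("  edit events:        ", nrow(object@edits), "\n", sep = "")
  cat("  secondary/suppl. skipped: ", object@nSecondary, "\n", sep = "")
  if (nrow(object@alignments)) {
    cat("  contigs: ", paste(utils::head(unique(object@alignments$contig), 5),
                             collapse = ", "),
        if (length(unique(object@alignments$contig)) > 5) ", ..." else "", "\n",
        sep = "")
  }
})

setMethod("show", "ReadEvaluationSet", function(object) {
  p <- object@perRead
  cat("ReadEvaluationSet object\n")
  cat("  paired reads:         ", nrow(p), "\n", sep = "")
  cat("  mapping-consistent:   ", sum(p$mapping_consistent), "\n", sep = "")
  cat("  dropped by EC tool:   ", length(object@dropped), "\n", sep = "")
  cat("  orphan corrected ids: ", length(object@orphans), "\n", sep = "")
  cons <- p[p$mapping_consistent, , drop = FALSE]
  cat("  CC/UC/OC (consistent): ", sum(cons$cc), "/", sum(cons$uc), "/",
      sum(cons$oc), "\n", sep = "")
})

setMethod("show", "EvaluationSummary", function(object) {
  fmt <- function(x, num, den) {
    if (is.na(x)) sprintf("NA (%d/%d)", num, den)
    else sprintf("%.6g (%d/%d)", x, num, den)
  }
  cc <- object@cc; uc <- object@uc; oc <- object@oc
  cat("EvaluationSummary\n")
  cat("  reads counted:  ", object@nReads, "\n", sep = "")
  cat("  reads excluded: ", object@nExcluded, " (mapping-inconsistent)\n", sep = "")
  cat("  CC: ", cc, "  UC: ", uc, "  OC: ", oc, "\n", sep = "")
  cat("  FNR = UC/(CC+UC) = ", fmt(object@fnr, uc, cc + uc), "\n", sep = "")
  cat("  FDR = OC/(CC+OC) = ", fmt(object@fdr, oc, cc + oc), "\n", sep = "")
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet \"", object@label, "\": ", length(object@regions),
      " merged intervals on ",
      length(unique(as.character(GenomicRanges::seqnames(object@regions)))),
      " contig(s)\n", sep = "")
})

setMethod("show", "HaplotypeMap", function(object) {
  cat("HaplotypeMap pattern: ", object@pattern, "\n", sep = "")
})
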