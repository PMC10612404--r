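#' Compare raw and corrected alignments and partition errors
#'
#' For every read present in both alignment sets, the edit events of the
#' raw and the corrected alignment are matched and partitioned into
#' correct corrections (`CC`, errors in the raw read but not in the
#' corrected read), under-corrections (`UC`, errors present in both) and
#' over-corrections (`OC`, new errors found only in the corrected read).
#' These play the roles of true positives, false negatives and false
#' positives of the error-correction step.
#'
#' Events are matched by the key `(contig, pos, kind, ref, alt)`; with
#' `matchAlt = FALSE` the alt allele is ignored, so a raw `A>C`
#' "corrected" into `A>G` at the same site counts as one UC rather than
#' CC+OC.  The comparison is restricted to the intersection of the two
#' reference intervals; raw events outside it (e.g. because the EC tool
#' trimmed the read) are tallied in `trimmed_raw_events`, not as CC.
#' A read is mapping-consistent when both alignments are on the same
#' contig with overlapping intervals; inconsistent reads get `cc=uc=oc=0`
#' here and are classified further by [classifyMappingDiffs()].
#'
#' @param raw,corr [ReadAlignments-class] objects for the raw and the
#'   corrected reads.
#' @param stripSuffix optional suffix removed from corrected read names
#'   before pairing (e.g. `"_corrected"`).
#' @param matchAlt include the alt allele in the event identity key
#'   (default `TRUE`).
#' @param dropN exclude events involving `N` (assembly gaps) from the
#'   counts (default `FALSE`).
#' @return A [ReadEvaluationSet-class] object.
#' @examples
#' # see the package vignette for an end-to-end example on simulated data
#' @export
evaluateReads <- function(raw, corr, stripSuffix = NULL, matchAlt = TRUE,
                          dropN = FALSE) {
  stopifnot(is(raw, "ReadAlignments"), is(corr, "ReadAlignments"))
  pr <- pairReads(raw, corr, stripSuffix = stripSuffix)

  raln <- as.data.table(raw@alignments)
  caln <- as.data.table(corr@alignments)
  caln[, read_id := applySuffixRule(read_id, stripSuffix)]
  red <- dedupeEvents(as.data.table(raw@edits), "raw")
  ced <- dedupeEvents(as.data.table(corr@edits), "corrected")
  ced[, read_id := applySuffixRule(read_id, stripSuffix)]
  if (dropN) {
    red <- red[!red$has_n]
    ced <- ced[!ced$has_n]
  }

  ids <- pr$paired
  ra <- raln[match(ids, raln$read_id)]
  ca <- caln[match(ids, caln$read_id)]
  consistent <- ra$contig == ca$contig &
    pmax(ra$ref_start, ca$ref_start) < pmin(ra$ref_end, ca$ref_end)
  ovl_start <- ifelse(consistent, pmax(ra$ref_start, ca$ref_start), NA_integer_)
  ovl_end <- ifelse(consistent, pmin(ra$ref_end, ca$ref_end), NA_integer_)

  per <- data.table(read_id = ids, contig = ra$contig,
                    ovl_start = as.integer(ovl_start),
                    ovl_end = as.integer(ovl_end),
                    cc = 0L, uc = 0L, oc = 0L,
                    mapping_consistent = consistent,
                    trimmed_raw_events = 0L)

  key <- if (matchAlt) c("read_id", "contig", "pos", "kind", "ref", "alt")
         else c("read_id", "contig", "pos", "kind")
  cons_ids <- ids[consistent]
  lim <- per[match(cons_ids, per$read_id)]

  inWindow <- function(ed) {
    ed <- ed[ed$read_id %in% cons_ids]
    w <- lim[match(ed$read_id, lim$read_id)]
    ed[ed$contig == w$contig & ed$pos >= w$ovl_start & ed$pos < w$ovl_end]
  }
  rin <- inWindow(red)
  cin <- inWindow(ced)
  rkey <- do.call(paste, c(rin[, key, with = FALSE], sep = "\r"))
  ckey <- do.call(paste, c(cin[, key, with = FALSE], sep = "\r"))
  rin[, class := ifelse(rkey %in% ckey, "UC", "CC")]
  cin[, class := ifelse(ckey %in% rkey, NA_character_, "OC")]
  ev <- rbind(rin, cin[!is.na(cin$class)])
  setorderv(ev, c("read_id", "pos"))

  if (nrow(ev)) {
    counts <- ev[, list(n = .N), by = c("read_id", "class")]
    for (cl in c("CC", "UC", "OC")) {
      cn <- counts[counts$class == cl]
      m <- match(cn$read_id, per$read_id)
      data.table::set(per, i = m, j = tolower(cl), value = cn$n)
    }
  }
  # raw events on paired, consistent reads that fall outside the overlap
  rout <- red[red$read_id %in% cons_ids]
  w <- lim[match(rout$read_id, lim$read_id)]
  rout <- rout[!(rout$contig == w$contig & rout$pos >= w$ovl_start &
                 rout$pos < w$ovl_end)]
  if (nrow(rout)) {
    tr <- rout[, list(n = .N), by = "read_id"]
    data.table::set(per, i = match(tr$read_id, per$read_id),
                    j = "trimmed_raw_events", value = tr$n)
  }
  new("ReadEvaluationSet", perRead = per, events = ev,
      dropped = pr$dropped, orphans = pr$orphans,
      params = list(match_alt = matchAlt, drop_n = dropN,
                    strip_suffix = stripSuffix))
}

#' Pair raw and corrected reads by name
#'
#' Matches read ids between the two alignment sets, optionally stripping
#' a suffix from corrected names first.  Raw reads with no corrected
#' counterpart were discarded by the EC tool and are reported in
#' `dropped`; corrected reads with no raw counterpart in `orphans`.
#'
#' @param raw,corr [ReadAlignments-class] objects.
#' @param stripSuffix optional suffix removed from corrected read names.
#' @return A list with `paired` (character vector of raw-side ids),
#'   `dropped` and `orphans`.
#' @export
pairReads <- function(raw, corr, stripSuffix = NULL) {
  rid <- raw@alignments$read_id
  cid <- applySuffixRule(corr@alignments$read_id, stripSuffix)
  paired <- intersect(rid, cid)
  dropped <- setdiff(rid, cid)
  orphans <- setdiff(cid, rid)
  if (!length(paired) && (length(rid) || length(cid)))
    warning("no read ids in common between raw and corrected alignments")
  list(paired = paired, dropped = dropped, orphans = orphans)
}

applySuffixRule <- function(ids, stripSuffix) {
  if (is.null(stripSuffix) || !nzchar(stripSuffix)) return(ids)
  sub(paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", stripSuffix), "$"), "", ids)
}

dedupeEvents <- function(ed, label) {
  if (!nrow(ed)) return(ed)
  k <- do.call(paste, c(ed[, EDIT_COLS, with = FALSE], sep = "\r"))
  if (anyDuplicated(k)) {
    warning("collapsing ", sum(duplicated(k)), " duplicate event key(s) in the ",
            label, " alignments")
    ed <- ed[!duplicated(k)]
  }
  ed
}

#' Aggregate an evaluation into CC/UC/OC totals and FDR/FNR
#'
#' Sums the per-read counts of a [ReadEvaluationSet-class] over
#' mapping-consistent reads (reads whose raw and corrected alignments
#' landed at different places are excluded from the rates, as their
#' events are not comparable) and computes
#' `FDR = OC/(CC+OC)` and `FNR = UC/(CC+UC)`, `NA` on a zero denominator.
#'
#' @param x a [ReadEvaluationSet-class], or a `data.frame`/list with
#'   elements/columns `cc`, `uc`, `oc` (and optionally
#'   `mapping_consistent`).
#' @param includeInconsistent also count mapping-inconsistent reads
#'   (default `FALSE`).
#' @return An [EvaluationSummary-class] object.
#' @examples
#' summarizeEvaluation(list(cc = 90, uc = 10, oc = 10))  # FNR = FDR = 0.10
#' @export
summarizeEvaluation <- function(x, includeInconsistent = FALSE) {
  if (is(x, "ReadEvaluationSet")) x <- x@perRead
  x <- as.data.frame(x)
  if (is.null(x$mapping_consistent)) x$mapping_consistent <- TRUE
  counted <- if (includeInconsistent) rep(TRUE, nrow(x)) else x$mapping_consistent
  cc <- sum(x$cc[counted]); uc <- sum(x$uc[counted]); oc <- sum(x$oc[counted])
  new("EvaluationSummary",
      nReads = sum(counted), nExcluded = sum(!x$mapping_consistent),
      cc = cc, uc = uc, oc = oc,
      fdr = if (cc + oc > 0) oc / (cc + oc) else NA_real_,
      fnr = if (cc + uc > 0) uc / (cc + uc) else NA_real_)
}

#' @rdname summarizeEvaluation
#' @param object an [EvaluationSummary-class] object.
#' @return `summaryTable()`: a one-row `data.frame` suitable for TSV output.
#' @export
summaryTable <- function(object) {
  stopifnot(is(object, "EvaluationSummary"))
  data.frame(n_reads = object@nReads, n_excluded = object@nExcluded,
             CC = object@cc, UC = object@uc, OC = object@oc,
             FDR = object@fdr, FNR = object@fnr)
}
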