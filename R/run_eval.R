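#' Run the full error-correction evaluation pipeline
#'
#' Orchestrates the core comparison: parses the raw and corrected
#' alignment files, optionally left-aligns indels against the assembly,
#' computes per-read CC/UC/OC, the aggregate FDR/FNR summary, the
#' mapping-difference classification, and (when region sets are given)
#' the stratified summary, writing each as TSV under `outPrefix`.
#'
#' Output files: `<prefix>.per_read.tsv`, `<prefix>.summary.tsv`,
#' `<prefix>.mapdiff.tsv`, `<prefix>.mapdiff_summary.tsv` and
#' `<prefix>.stratified.tsv` (the last only with regions).
#'
#' @param rawPaf,corrPaf alignment files (PAF with cs tags, or SAM).
#' @param outPrefix output path prefix; no files are written when `NULL`.
#' @param assembly optional truth-assembly FASTA (or named sequences);
#'   when supplied, indels are left-aligned before comparison.
#' @param regionSets optional list of [RegionSet-class] for
#'   stratification.
#' @param hmap [HaplotypeMap-class] used by the mapping-difference
#'   classification.
#' @param mapqThresholds MAPQ thresholds for the mapping-difference
#'   summary.
#' @param stripSuffix,matchAlt,dropN passed to [evaluateReads()].
#' @param format alignment format, `"auto"`/`"paf"`/`"sam"`.
#' @return A list with elements `status` (0 on success, 1 when zero
#'   read pairs, 2 on missing inputs), `evaluation`
#'   ([ReadEvaluationSet-class]), `summary` ([EvaluationSummary-class]),
#'   `mapdiff`, `mapdiffSummary`, `stratified` (or `NULL`), and `files`.
#' @export
runEval <- function(rawPaf, corrPaf, outPrefix = NULL, assembly = NULL,
                    regionSets = list(), hmap = haplotypeMap(),
                    mapqThresholds = c(2L, 10L), stripSuffix = NULL,
                    matchAlt = TRUE, dropN = FALSE,
                    format = c("auto", "paf", "sam")) {
  format <- match.arg(format)
  missing_in <- c(rawPaf, corrPaf)[!file.exists(c(rawPaf, corrPaf))]
  if (length(missing_in)) {
    message("missing input file(s): ", paste(missing_in, collapse = ", "))
    return(list(status = 2L))
  }
  raw <- readAlignments(rawPaf, format = format)
  corr <- readAlignments(corrPaf, format = format)
  if (!is.null(assembly)) {
    ref <- asRefSeqs(assembly)
    raw <- normalizeIndels(raw, ref)
    corr <- normalizeIndels(corr, ref)
  }
  ev <- evaluateReads(raw, corr, stripSuffix = stripSuffix,
                      matchAlt = matchAlt, dropN = dropN)
  if (nReads(ev) == 0L) {
    message("zero paired reads between raw and corrected alignments")
    return(list(status = 1L, evaluation = ev))
  }
  summ <- summarizeEvaluation(ev)
  md <- classifyMappingDiffs(raw, corr, hmap = hmap,
                             mapqMin = min(mapqThresholds),
                             stripSuffix = stripSuffix)
  mds <- mapdiffSummary(md, mapqThresholds)
  strat <- if (length(regionSets)) stratifiedSummary(ev, regionSets) else NULL

  files <- character(0)
  if (!is.null(outPrefix)) {
    wr <- function(x, what) {
      f <- paste0(outPrefix, ".", what, ".tsv")
      data.table::fwrite(as.data.frame(x), f, sep = "\t", na = "NA")
      f
    }
    files <- c(files, wr(perRead(ev), "per_read"),
               wr(summaryTable(summ), "summary"),
               wr(md, "mapdiff"), wr(mds, "mapdiff_summary"))
    if (!is.null(strat)) files <- c(files, wr(strat, "stratified"))
  }
  list(status = 0L, evaluation = ev, summary = summ, mapdiff = md,
       mapdiffSummary = mds, stratified = strat, files = files)
}

#' Align reads to an assembly with minimap2 and return the PAF path
#'
#' Thin wrapper over an external `minimap2` invocation using the HiFi
#' preset with cs tags (`-x map-hifi --cs -c`), for users who have reads
#' and an assembly but no alignments yet.  Requires `minimap2` on the
#' PATH; the package itself never aligns.
#'
#' @param assemblyFasta,readsFile input paths.
#' @param out output PAF path.
#' @param preset minimap2 preset (default `"map-hifi"`).
#' @return `out`, invisibly.
#' @export
alignWithMinimap2 <- function(assemblyFasta, readsFile,
                              out = tempfile(fileext = ".paf"),
                              preset = "map-hifi") {
  mm2 <- Sys.which("minimap2")
  if (!nzchar(mm2)) stop("minimap2 not found on PATH")
  status <- system2(mm2, c("-x", preset, "-c", "--cs", "-t", "1",
                           shQuote(assemblyFasta), shQuote(readsFile)),
                    stdout = out, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed with exit status ", status)
  invisible(out)
}
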