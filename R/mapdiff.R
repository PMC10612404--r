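#' Build a contig-to-(chromosome, haplotype) resolution rule
#'
#' @param pattern regular expression with exactly two capture groups, the
#'   first capturing the chromosome label and the second the haplotype
#'   label.  The default handles dual-assembly naming of the form
#'   `<chr>_<MAT|PAT>` or `<chr>_<hap1|hap2>` (case-insensitive suffix).
#' @return A [HaplotypeMap-class] object.
#' @examples
#' resolveContigs(haplotypeMap(), c("chr1_MAT", "chr1_PAT"))
#' @export
haplotypeMap <- function(pattern = "^(.*)_(MAT|PAT|[Hh]ap[12])$") {
  new("HaplotypeMap", pattern = pattern)
}

#' Resolve contig names to chromosome and haplotype labels
#'
#' @param hmap a [HaplotypeMap-class].
#' @param contigs character vector of contig names.
#' @return A `data.frame` with columns `contig`, `chrom`, `hap`;
#'   `chrom`/`hap` are `NA` for names the pattern does not match.
#' @export
resolveContigs <- function(hmap, contigs) {
  stopifnot(is(hmap, "HaplotypeMap"))
  m <- regmatches(contigs, regexec(hmap@pattern, contigs))
  ok <- lengths(m) == 3L
  data.frame(contig = contigs,
             chrom = ifelse(ok, vapply(m, function(g) if (length(g) == 3L) g[2L] else NA_character_, character(1)), NA_character_),
             hap = ifelse(ok, vapply(m, function(g) if (length(g) == 3L) g[3L] else NA_character_, character(1)), NA_character_))
}

#' Classify reads whose raw and corrected alignments disagree
#'
#' Reads mapped to the same contig with overlapping intervals before and
#' after correction are `consistent`.  The remaining reads are classed
#' as a `haplotype` difference (same chromosome, opposite parental
#' haplotype — the signature of an EC tool rewriting a read onto the
#' other haplotype), a `chromosome` difference (different chromosome) or
#' a `position` difference (same contig, disjoint intervals).  Following
#' the MAPQ convention for this analysis, a pair enters the categories
#' only if the raw *or* the corrected alignment has mapping quality at
#' least `mapqMin` (default 2); pairs failing the filter are reported as
#' `filtered`.  Contigs the haplotype rule cannot resolve yield
#' `unresolvable` (with a warning) when resolution is needed.
#'
#' @param raw,corr [ReadAlignments-class] objects.
#' @param hmap a [HaplotypeMap-class]; see [haplotypeMap()].
#' @param mapqMin minimum MAPQ (on at least one of the two alignments).
#' @param stripSuffix optional suffix removed from corrected read names.
#' @return A `data.frame` with one row per paired read: `read_id`,
#'   `category`, and the raw/corrected loci
#'   (`raw_contig`, `raw_start`, `raw_end`, `raw_mapq`, and `corr_*`).
#' @export
classifyMappingDiffs <- function(raw, corr, hmap = haplotypeMap(), mapqMin = 2L,
                                 stripSuffix = NULL) {
  stopifnot(is(raw, "ReadAlignments"), is(corr, "ReadAlignments"))
  pr <- pairReads(raw, corr, stripSuffix = stripSuffix)
  raln <- as.data.table(raw@alignments)
  caln <- as.data.table(corr@alignments)
  caln[, read_id := applySuffixRule(read_id, stripSuffix)]
  ra <- raln[match(pr$paired, raln$read_id)]
  ca <- caln[match(pr$paired, caln$read_id)]
  rec <- data.table(read_id = pr$paired,
                    raw_contig = ra$contig, raw_start = ra$ref_start,
                    raw_end = ra$ref_end, raw_mapq = ra$mapq,
                    corr_contig = ca$contig, corr_start = ca$ref_start,
                    corr_end = ca$ref_end, corr_mapq = ca$mapq)
  same_contig <- rec$raw_contig == rec$corr_contig
  overlap <- same_contig & pmax(rec$raw_start, rec$corr_start) <
    pmin(rec$raw_end, rec$corr_end)
  pass <- pmax(rec$raw_mapq, rec$corr_mapq) >= mapqMin

  cat_ <- rep(NA_character_, nrow(rec))
  cat_[overlap] <- "consistent"
  cat_[!pass & is.na(cat_)] <- "filtered"
  todo <- which(is.na(cat_))
  if (length(todo)) {
    rres <- resolveContigs(hmap, rec$raw_contig[todo])
    cres <- resolveContigs(hmap, rec$corr_contig[todo])
    same_ctg <- same_contig[todo]
    unres <- (is.na(rres$chrom) | is.na(cres$chrom)) & !same_ctg
    cls <- ifelse(same_ctg, "position",
           ifelse(unres, "unresolvable",
           ifelse(rres$chrom == cres$chrom & rres$hap != cres$hap, "haplotype",
                  "chromosome")))
    if (any(unres))
      warning(sum(unres), " read pair(s) on contigs the haplotype rule ",
              "cannot resolve; classed 'unresolvable'")
    cat_[todo] <- cls
  }
  rec[, category := cat_]
  data.table::setcolorder(rec, c("read_id", "category"))
  as.data.frame(rec)
}

#' Tabulate mapping-difference categories across MAPQ thresholds
#'
#' For each threshold, re-applies the "raw or corrected MAPQ at least t"
#' filter to the classified pairs and reports the count and percentage
#' of reads in each category among the reads passing the filter, with
#' explicit denominators.
#'
#' @param records output of [classifyMappingDiffs()] (any `mapqMin`
#'   no stricter than the smallest threshold requested).
#' @param mapqThresholds integer vector of thresholds.
#' @return A `data.frame` with columns `mapq_min`, `category`, `n`,
#'   `denominator`, `percent`.
#' @export
mapdiffSummary <- function(records, mapqThresholds = c(2L, 10L)) {
  records <- as.data.frame(records)
  cats <- c("haplotype", "chromosome", "position", "consistent")
  out <- list()
  for (t in sort(mapqThresholds)) {
    pass <- pmax(records$raw_mapq, records$corr_mapq) >= t &
      !records$category %in% c("unresolvable", "filtered")
    den <- sum(pass)
    for (cl in cats) {
      n <- sum(pass & records$category == cl)
      out[[length(out) + 1L]] <- data.frame(
        mapq_min = t, category = cl, n = n, denominator = den,
        percent = if (den > 0) 100 * n / den else NA_real_)
    }
  }
  do.call(rbind, out)
}
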