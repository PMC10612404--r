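#' Homopolymer-compress a nucleotide sequence
#'
#' Collapses every maximal run of identical bases to a single base and
#' records where each run started, so compressed coordinates can be
#' mapped back to the original sequence.  Some error-correction tools
#' only emit homopolymer-compressed (HPC) reads; compressing the truth
#' assembly and the raw reads the same way lets the whole evaluation run
#' in HPC space.
#'
#' Compression is case-insensitive (soft-masked lowercase must not split
#' a run) and the output is uppercase.  `N` runs compress like any other
#' base.
#'
#' @param seq a single nucleotide string over `A,C,G,T,N` (either case).
#' @return A list with elements `compressed` (the HPC string) and
#'   `run_starts` (integer vector, 0-based original start of the run
#'   behind each compressed position; same length as the compressed
#'   string).
#' @examples
#' hpcCompress("AAATTTGGGCCC")  # "ATGC", run_starts 0,3,6,9
#' @export
hpcCompress <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (nchar(s) == 0L)
    return(list(compressed = "", run_starts = integer()))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!v %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("non-nucleotide character '", v[bad[1L]], "' at position ", bad[1L] - 1L,
         " (0-based)")
  keep <- c(TRUE, v[-1L] != v[-length(v)])
  list(compressed = paste(v[keep], collapse = ""),
       run_starts = which(keep) - 1L)
}

#' Expand an HPC result back to the original sequence
#'
#' Inverse of [hpcCompress()] given the original total length: each
#' compressed base is repeated to fill the interval between consecutive
#' run starts.  Used mainly as a round-trip check.
#'
#' @param hpc a list as returned by [hpcCompress()].
#' @param originalLength length of the original sequence.
#' @return The reconstructed (uppercased) original string.
#' @export
hpcExpand <- function(hpc, originalLength) {
  n <- length(hpc$run_starts)
  if (n == 0L) return("")
  lens <- diff(c(hpc$run_starts, originalLength))
  v <- strsplit(hpc$compressed, "", fixed = TRUE)[[1L]]
  paste(rep(v, times = lens), collapse = "")
}

#' Homopolymer-compress every record of a sequence file
#'
#' Reads FASTA or FASTQ (optionally gzipped), compresses each record with
#' [hpcCompress()] and writes FASTA.  FASTQ quality strings are dropped:
#' per-base quality is undefined once a run of bases has been merged, so
#' the output is always FASTA.  Headers are preserved verbatim.
#'
#' @param infile input FASTA/FASTQ path, optionally `.gz`.
#' @param outfile output FASTA path.
#' @param format `"auto"` (default, by extension/first byte), `"fasta"`
#'   or `"fastq"`.
#' @return Invisibly, the number of records written.
#' @export
hpcCompressFile <- function(infile, outfile, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniffSeqFormat(infile)
  if (is.na(format)) {   # empty file
    file.create(outfile)
    return(invisible(0L))
  }
  seqs <- Biostrings::readDNAStringSet(infile, format = format)
  comp <- vapply(as.character(seqs),
                 function(s) hpcCompress(s)$compressed, character(1),
                 USE.NAMES = FALSE)
  out <- Biostrings::DNAStringSet(comp)
  names(out) <- names(seqs)
  Biostrings::writeXStringSet(out, outfile, format = "fasta")
  invisible(length(out))
}

# Decide fasta vs fastq from the first non-empty line; NA for empty files.
sniffSeqFormat <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0L) return(NA_character_)
    if (nzchar(l)) break
  }
  c1 <- substr(l, 1L, 1L)
  if (c1 == ">") "fasta"
  else if (c1 == "@") "fastq"
  else stop("cannot determine sequence format of ", path,
            ": first record starts with '", c1, "'")
}
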