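# Minimal SAM dialect for pre-mapped reads: header (@HD, @SQ), then
# QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL with 1-based POS,
# strand carried in FLAG bit 0x10, and simple all-match CIGARs. SEQ is always
# reported on the forward reference strand, as in SAM proper.

#' Write aligned reads as minimal SAM
#'
#' @param reads an \code{aligned_reads} data.frame (see
#'   \code{\link{simulate_reads}}).
#' @param path output file.
#' @param reference_length length of the reference sequence (for the @SQ
#'   header line).
#' @param reference_name reference name; defaults to the reads' rname.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(reads, path, reference_length,
                      reference_name = reads$rname[1]) {
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  lens <- nchar(reads$seq)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", reference_name, as.integer(reference_length)),
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            reads$qname, flag, reads$rname, reads$start + 1L, lens, reads$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read minimal SAM into aligned reads
#'
#' Parses the subset of SAM written by \code{\link{write_sam}}: header lines
#' are skipped, CIGARs must be pure matches (\code{<n>M}), and the strand is
#' taken from FLAG bit 0x10. Unmapped reads (FLAG 0x4) are dropped.
#'
#' @param path SAM file.
#' @return \code{aligned_reads} data.frame with 0-based \code{start}.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) {
    out <- data.frame(qname = character(0), rname = character(0),
                      start = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("aligned_reads", "data.frame")))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM line (fewer than 11 fields) at body line ",
         which(nf < 11L)[1])
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  cigar <- vapply(f, `[[`, character(1), 6L)
  if (any(!grepl("^[0-9]+M$", cigar)))
    stop("unsupported CIGAR (only pure matches are handled): ",
         cigar[!grepl("^[0-9]+M$", cigar)][1])
  seqs <- vapply(f, `[[`, character(1), 10L)
  if (any(as.integer(sub("M$", "", cigar)) != nchar(seqs)))
    stop("CIGAR length does not match SEQ length")
  out <- data.frame(
    qname = vapply(f, `[[`, character(1), 1L),
    rname = vapply(f, `[[`, character(1), 3L),
    start = as.integer(vapply(f, `[[`, character(1), 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    seq = seqs,
    stringsAsFactors = FALSE)
  rl <- unique(nchar(out$seq))
  structure(out, class = c("aligned_reads", "data.frame"),
            read_length = if (length(rl) == 1L) rl else NULL)
}
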