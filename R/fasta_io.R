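# FASTA input/output for gene records. The description line carries
# machine-readable key=value tags (molecule_class, start_override, name,
# cds_start) after the identifier, e.g.
#   >petD name=petD molecule_class=protein_coding start_override=ATA

#' Read gene records from a FASTA file
#'
#' @param path FASTA file. Each record's description may carry
#'   \code{key=value} tags: \code{name}, \code{molecule_class}
#'   ("protein_coding"/"rRNA"), \code{start_override} (codon), and
#'   \code{cds_start} (0-based offset of the CDS when the sequence is a whole
#'   minicircle rather than a bare CDS; stored as attribute "cds_start").
#' @return named list of \code{gene_record} objects.
#' @export
read_gene_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(xs), function(i) {
    desc <- names(xs)[i]
    toks <- strsplit(desc, "\\s+")[[1]]
    id <- toks[1]
    tags <- grep("=", toks[-1], fixed = TRUE, value = TRUE)
    kv <- list()
    for (t in tags) {
      eq <- regexpr("=", t, fixed = TRUE)
      kv[[substr(t, 1, eq - 1)]] <- substr(t, eq + 1, nchar(t))
    }
    seq <- as.character(xs[[i]])
    mc <- if (!is.null(kv$molecule_class)) kv$molecule_class
          else "protein_coding"
    if (!is.null(kv$cds_start) && as.integer(kv$cds_start) > 0L) {
      # whole-minicircle record: the CDS is a tagged substring, so the
      # record is built without the CDS length check
      if (is.null(kv$cds_length))
        stop("cds_start tag requires a cds_length tag (record ", id, ")")
      assert_dna(seq, "seq")
      g <- structure(
        list(gene_id = id, name = if (!is.null(kv$name)) kv$name else id,
             seq = seq, molecule_class = mc,
             start_override = kv$start_override, homolog_protein = NULL),
        class = "gene_record")
      attr(g, "cds_start") <- as.integer(kv$cds_start)
      attr(g, "cds_length") <- as.integer(kv$cds_length)
    } else {
      g <- gene_record(
        gene_id = id, seq = seq,
        name = if (!is.null(kv$name)) kv$name else id,
        molecule_class = mc,
        start_override = kv$start_override)
    }
    g
  })
  names(out) <- vapply(out, function(g) g$gene_id, character(1))
  out
}

#' Write gene records to a FASTA file
#'
#' @param genes list of \code{gene_record} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  if (inherits(genes, "gene_record")) genes <- list(genes)
  seqs <- vapply(genes, function(g) g$seq, character(1))
  descs <- vapply(genes, function(g) {
    d <- sprintf("%s name=%s molecule_class=%s", g$gene_id, g$name,
                 g$molecule_class)
    if (!is.null(g$start_override))
      d <- paste0(d, " start_override=", g$start_override)
    cs <- attr(g, "cds_start")
    if (!is.null(cs)) d <- paste0(d, " cds_start=", cs)
    cl <- attr(g, "cds_length")
    if (!is.null(cl)) d <- paste0(d, " cds_length=", cl)
    d
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- descs
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
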