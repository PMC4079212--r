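# Core domain types: gene records, translation, editing-type classification,
# and scalar sequence/protein descriptors.

#' Create a minicircle gene record
#'
#' A gene record holds the coding-strand DNA sequence of one minicircle gene
#' together with its molecule class and, for a handful of genes, an
#' alternative start codon. Dinoflagellate minicircle genes can initiate at
#' non-AUG codons (UUG, AUA, UUU are seen in the field); when
#' \code{start_override} is set it must equal the first codon of \code{seq}
#' and translation renders the first residue as methionine.
#'
#' @param gene_id short identifier, e.g. "petD".
#' @param seq coding-strand DNA sequence, 5'->3', over {A,C,G,T}. For
#'   protein-coding genes the length must be a multiple of 3 (CDS without the
#'   terminal stop codon).
#' @param name human-readable name; defaults to \code{gene_id}.
#' @param molecule_class "protein_coding" or "rRNA".
#' @param start_override optional alternative start codon as a DNA triplet
#'   (e.g. "TTG"); must equal the first codon of \code{seq}.
#' @param homolog_protein optional amino-acid sequence of a homolog used for
#'   identity analysis.
#' @return An object of class \code{gene_record}.
#' @examples
#' g <- gene_record("psbI", "TTGAAAGGT", start_override = "TTG")
#' translate_cds(g$seq, g$start_override)
#' @export
gene_record <- function(gene_id, seq, name = gene_id,
                        molecule_class = c("protein_coding", "rRNA"),
                        start_override = NULL, homolog_protein = NULL) {
  molecule_class <- match.arg(molecule_class)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  assert_dna(seq, "seq")
  if (molecule_class == "protein_coding" && nchar(seq) %% 3L != 0L)
    stop("protein-coding seq length must be a multiple of 3")
  if (!is.null(start_override)) {
    assert_dna(start_override, "start_override")
    if (nchar(start_override) != 3L)
      stop("start_override must be a codon (3 nt)")
    if (substr(seq, 1L, 3L) != start_override)
      stop("start_override must equal the first codon of seq")
  }
  structure(
    list(gene_id = gene_id, name = name, seq = seq,
         molecule_class = molecule_class,
         start_override = start_override,
         homolog_protein = homolog_protein),
    class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (%s), %d nt%s\n", x$gene_id,
              x$molecule_class, nchar(x$seq),
              if (is.null(x$start_override)) ""
              else paste0(", start=", x$start_override)))
  invisible(x)
}

#' Translate a coding sequence (plastid/bacterial code)
#'
#' Uses translation table 11. Internal stop codons are emitted as '*' rather
#' than truncating, so downstream code can detect premature stops. If
#' \code{start_override} equals the first codon, the first residue is
#' rendered as methionine regardless of the code.
#'
#' @param seq DNA string, length a multiple of 3, over {A,C,G,T}.
#' @param start_override optional alternative start codon (DNA triplet).
#' @return amino-acid string, '*' marking stop codons.
#' @examples
#' translate_cds("ATGGGT")
#' translate_cds("TTGAAA", "TTG")  # "MK"
#' @export
translate_cds <- function(seq, start_override = NULL) {
  assert_dna(seq, "seq")
  if (nchar(seq) %% 3L != 0L)
    stop("seq length must be a multiple of 3")
  codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  aa <- unname(GENETIC_CODE_11[codons])
  if (!is.null(start_override) && length(codons) &&
      codons[1L] == start_override)
    aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Classify one RNA-DNA difference into an editing type
#'
#' An editing type is written "X/Y": genomic base X read as transcript base Y,
#' with the RNA side in U notation (T is written U). Twelve ordered types
#' exist; four are transitions (purine-purine or pyrimidine-pyrimidine) and
#' eight are transversions.
#'
#' @param dna_base genomic base, one of A,C,G,T.
#' @param rna_base transcript base, one of A,C,G,T,U (T and U equivalent).
#' @return list of class \code{edit_type} with fields \code{dna_base},
#'   \code{rna_base} (U notation), \code{label}, \code{is_transversion}.
#' @examples
#' classify_edit("A", "G")$label       # "A/G"
#' classify_edit("G", "T")$is_transversion
#' @export
classify_edit <- function(dna_base, rna_base) {
  dna_base <- toupper(dna_base)
  rna_base <- toupper(rna_base)
  if (!dna_base %in% DNA_BASES) stop("invalid DNA base: ", dna_base)
  rna_dna <- chartr("U", "T", rna_base)       # canonical DNA alphabet
  if (!rna_dna %in% DNA_BASES) stop("invalid RNA base: ", rna_base)
  if (dna_base == rna_dna)
    stop("identical bases do not constitute an edit")
  is_tv <- (dna_base %in% PURINES) != (rna_dna %in% PURINES)
  structure(
    list(dna_base = dna_base,
         rna_base = chartr("T", "U", rna_base),
         label = paste(chartr("T", "U", dna_base),
                       chartr("T", "U", rna_dna), sep = "/"),
         is_transversion = is_tv),
    class = "edit_type")
}

#' Enumerate the twelve possible editing types
#'
#' @return data.frame with one row per ordered DNA->RNA substitution:
#'   \code{dna_base}, \code{rna_base}, \code{label}, \code{is_transversion}.
#' @export
edit_types <- function() {
  pairs <- expand.grid(dna = DNA_BASES, rna = DNA_BASES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$dna != pairs$rna, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    et <- classify_edit(pairs$dna[i], pairs$rna[i])
    data.frame(dna_base = et$dna_base, rna_base = et$rna_base,
               label = et$label, is_transversion = et$is_transversion,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[match(EDIT_TYPE_ORDER, out$label), ]
  rownames(out) <- NULL
  out
}

TRANSVERSION_LABELS <- c("G/C", "G/U", "U/G", "A/C", "A/U",
                         "C/A", "C/G", "U/A")

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues, the ProtParam GRAVY
#' statistic. Higher values are more hydrophobic; the score is bounded by the
#' scale extremes [-4.5, 4.5].
#'
#' @param protein amino-acid string over the 20 standard residues; '*' is not
#'   allowed (strip or handle premature stops upstream).
#' @return numeric GRAVY score.
#' @examples
#' gravy("I")     # 4.5
#' gravy("GGGG")  # -0.4
#' @export
gravy <- function(protein) {
  res <- protein_residues(protein)
  mean(KYTE_DOOLITTLE[res])
}

#' Protein molecular weight (average masses)
#'
#' Sum of ProtParam-compatible average residue masses plus one water.
#'
#' @inheritParams gravy
#' @return mass in daltons.
#' @examples
#' molecular_weight("G")  # ~75.07
#' @export
molecular_weight <- function(protein) {
  res <- protein_residues(protein)
  sum(RESIDUE_MASS[res]) + MASS_WATER
}

protein_residues <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0L)
    stop("protein must be a non-empty string")
  res <- seq_chars(toupper(protein))
  bad <- setdiff(unique(res), names(KYTE_DOOLITTLE))
  if (length(bad))
    stop("invalid residues in protein: ", paste(bad, collapse = ","))
  res
}

#' GC content of a DNA sequence
#'
#' @param seq non-empty DNA string.
#' @return percentage of G+C, 0-100.
#' @examples
#' gc_content("GGCC")  # 100
#' @export
gc_content <- function(seq) {
  assert_dna(seq, "seq")
  chars <- seq_chars(seq)
  100 * sum(chars == "G" | chars == "C") / length(chars)
}
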