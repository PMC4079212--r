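# Codon-level annotation of called sites, per-gene summaries, and aggregate
# consequence statistics (type spectrum, codon-position distribution, GC
# shift, homolog identity, MW/GRAVY shift, rank correlation).

#' Apply editing sites to a gene sequence
#'
#' @param gene a \code{gene_record}.
#' @param sites editing-sites data.frame with \code{cds_position} (0-based on
#'   the gene; falls back to \code{position}) and \code{dna_base},
#'   \code{rna_base} columns (DNA alphabet).
#' @return edited transcript sequence (DNA alphabet), same length.
#' @export
apply_edits <- function(gene, sites) {
  chars <- seq_chars(gene$seq)
  if (!nrow(sites)) return(gene$seq)
  pos <- site_gene_positions(sites)
  if (any(pos < 0L) || any(pos >= length(chars)))
    stop("site position outside the CDS")
  if (any(chars[pos + 1L] != sites$dna_base))
    stop("reference-base mismatch between sites and gene sequence")
  chars[pos + 1L] <- chartr("U", "T", sites$rna_base)
  chars_seq(chars)
}

site_gene_positions <- function(sites) {
  if ("cds_position" %in% names(sites) && !all(is.na(sites$cds_position)))
    as.integer(sites$cds_position)
  else
    as.integer(sites$position)
}

#' Annotate codon-level effects of editing sites
#'
#' All edits falling in the same codon are applied jointly, so a codon edited
#' at positions 1 and 2 is evaluated once with both substitutions in place
#' (e.g. ATG -> GCG, Met -> Ala) and each of its sites is flagged
#' non-synonymous. \code{stop_restoration} is TRUE where the reference codon
#' is a stop and the edited codon is not. rRNA genes receive no codon
#' annotation (columns stay NA).
#'
#' @param gene a protein-coding \code{gene_record} (rRNA passes through).
#' @param sites editing-sites data.frame.
#' @return \code{sites} with codon annotation columns filled:
#'   \code{codon_index} (0-based), \code{codon_position} (1/2/3),
#'   \code{ref_codon}, \code{alt_codon}, \code{ref_aa}, \code{alt_aa},
#'   \code{synonymous}, \code{stop_restoration}.
#' @export
annotate_codon_effects <- function(gene, sites) {
  if (!nrow(sites)) return(sites)
  if (gene$molecule_class != "protein_coding") return(sites)
  pos <- site_gene_positions(sites)
  if (any(pos < 0L) || any(pos >= nchar(gene$seq)))
    stop("site position beyond the CDS")
  chars <- seq_chars(gene$seq)
  if (any(chars[pos + 1L] != sites$dna_base))
    stop("reference-base mismatch between sites and gene sequence")
  ci <- pos %/% 3L
  cp <- pos %% 3L + 1L
  alt_chars <- chars
  alt_chars[pos + 1L] <- chartr("U", "T", sites$rna_base)
  ref_codon <- vapply(ci, function(k)
    chars_seq(chars[(3L * k + 1L):(3L * k + 3L)]), character(1))
  alt_codon <- vapply(ci, function(k)
    chars_seq(alt_chars[(3L * k + 1L):(3L * k + 3L)]), character(1))
  ref_aa <- unname(GENETIC_CODE_11[ref_codon])
  alt_aa <- unname(GENETIC_CODE_11[alt_codon])
  # an alternative start codon translates as Met in the reference
  if (!is.null(gene$start_override)) {
    ref_aa[ci == 0L & ref_codon == gene$start_override] <- "M"
  }
  sites$codon_index <- ci
  sites$codon_position <- cp
  sites$ref_codon <- ref_codon
  sites$alt_codon <- alt_codon
  sites$ref_aa <- ref_aa
  sites$alt_aa <- alt_aa
  sites$synonymous <- ref_aa == alt_aa
  sites$stop_restoration <- ref_aa == "*" & alt_aa != "*"
  sites
}

#' Per-gene editing summary
#'
#' One row in the style of a per-gene editing table: CDS length, edit count
#' and frequency, per-type counts, amino-acid substitution count (number of
#' edited sites whose codon translation changes - per-site counting, so both
#' sites of a doubly edited codon count) and percentage over the protein
#' length, and stop restorations. Percentages are rounded half-up to one
#' decimal.
#'
#' @param gene a \code{gene_record}.
#' @param annotated_sites sites for this gene, after
#'   \code{\link{annotate_codon_effects}}.
#' @return one-row data.frame (see details); type counts appear as one
#'   column per editing-type label.
#' @export
summarize_gene <- function(gene, annotated_sites) {
  s <- annotated_sites
  if (nrow(s) && !all(s$gene_id %in% c(gene$gene_id, "reference")))
    stop("sites do not belong to gene ", gene$gene_id)
  n_edits <- nrow(s)
  len <- nchar(gene$seq)
  type_counts <- table(factor(s$label, levels = EDIT_TYPE_ORDER))
  coding <- gene$molecule_class == "protein_coding"
  syn <- if ("synonymous" %in% names(s)) s$synonymous else logical(0)
  stop_rest <- if ("stop_restoration" %in% names(s)) s$stop_restoration
               else logical(0)
  n_aa <- if (coding) sum(!syn, na.rm = TRUE) else NA_integer_
  prot_len <- if (coding) len %/% 3L else NA_integer_
  out <- data.frame(
    gene_id = gene$gene_id,
    molecule_class = gene$molecule_class,
    cds_length_nt = len,
    n_edits = n_edits,
    edit_frequency_pct = round_half_up(100 * n_edits / len, 1),
    n_aa_substitutions = n_aa,
    protein_length_aa = prot_len,
    aa_substitution_pct = if (coding)
      round_half_up(100 * n_aa / prot_len, 1) else NA_real_,
    n_stop_restorations = if (coding)
      sum(stop_rest, na.rm = TRUE) else NA_integer_,
    identity_pre_pct = NA_real_, identity_post_pct = NA_real_,
    stringsAsFactors = FALSE, check.names = FALSE)
  for (lb in EDIT_TYPE_ORDER) out[[lb]] <- as.integer(type_counts[[lb]])
  out
}

#' Aggregate editing statistics across genes
#'
#' Totals and spectra in the conventional reporting units. Type spectrum and
#' transversion share are computed over all edits (mRNA + rRNA) from the
#' summaries' per-type counts, skipping rows with unknown (NA) type counts;
#' codon-position and substitution statistics cover mRNA edits only; GC
#' before/after is computed over the concatenated coding sequences before and
#' after applying the edits; the Spearman rank test relates post-editing
#' molecular weight to post-editing GRAVY across genes when shifts are
#' supplied.
#'
#' @param summaries data.frame of per-gene rows
#'   (\code{\link{summarize_gene}} or the packaged fixture).
#' @param annotated_sites optional combined annotated sites (codon-position
#'   statistics).
#' @param genes optional named list of \code{gene_record}s (GC shift; edits
#'   applied per gene from \code{annotated_sites}).
#' @param shifts optional data.frame from \code{\link{hydropathy_mw_shift}}
#'   rows (one per gene) for the rank correlation.
#' @return list of class \code{aggregate_stats}.
#' @export
aggregate_stats <- function(summaries, annotated_sites = NULL, genes = NULL,
                            shifts = NULL) {
  stopifnot(nrow(summaries) >= 1)
  coding <- summaries$molecule_class == "protein_coding"
  total_edits <- sum(summaries$n_edits)
  total_mrna <- sum(summaries$n_edits[coding])
  total_aa <- sum(summaries$n_aa_substitutions[coding], na.rm = TRUE)
  type_cols <- intersect(EDIT_TYPE_ORDER, names(summaries))
  tmat <- as.matrix(summaries[, type_cols, drop = FALSE])
  known <- stats::complete.cases(tmat)
  type_totals <- colSums(tmat[known, , drop = FALSE])
  spectrum_n <- sum(type_totals)
  type_spectrum_pct <- round_half_up(100 * type_totals / spectrum_n, 1)
  transversion_pct <- round_half_up(
    100 * sum(type_totals[intersect(TRANSVERSION_LABELS, type_cols)]) /
      spectrum_n, 1)
  codon_position_counts <- c(`1` = NA_integer_, `2` = NA_integer_,
                             `3` = NA_integer_)
  codon_position_pcts <- c(`1` = NA_real_, `2` = NA_real_, `3` = NA_real_)
  double_substitution_pct <- NA_real_
  if (!is.null(annotated_sites) && nrow(annotated_sites)) {
    cs <- annotated_sites[!is.na(annotated_sites$codon_position), ,
                          drop = FALSE]
    if (nrow(cs)) {
      tab <- table(factor(cs$codon_position, levels = 1:3))
      codon_position_counts <- stats::setNames(as.integer(tab), 1:3)
      codon_position_pcts <- round_half_up(100 * as.integer(tab) / nrow(cs), 0)
      names(codon_position_pcts) <- 1:3
      key <- paste(cs$gene_id, cs$codon_index)
      dbl <- vapply(split(cs$codon_position, key), function(v)
        all(c(1L, 2L) %in% v), logical(1))
      n_double_sites <- sum(cs$codon_position %in% c(1L, 2L) &
                              dbl[paste(cs$gene_id, cs$codon_index)])
      double_substitution_pct <- round_half_up(100 * n_double_sites /
                                                 nrow(cs), 1)
    }
  }
  gc_pre <- gc_post <- NA_real_
  if (!is.null(genes) && !is.null(annotated_sites)) {
    pre <- vapply(genes, function(g) g$seq, character(1))
    post <- vapply(genes, function(g) {
      s <- annotated_sites[annotated_sites$gene_id == g$gene_id, ,
                           drop = FALSE]
      if (nrow(s)) {
        p <- site_gene_positions(s)
        s <- s[p >= 0L & p < nchar(g$seq), , drop = FALSE]
      }
      apply_edits(g, s)
    }, character(1))
    gc_pre <- round_half_up(gc_content(paste(pre, collapse = "")), 2)
    gc_post <- round_half_up(gc_content(paste(post, collapse = "")), 2)
  }
  spearman_rho <- spearman_p <- NA_real_
  if (!is.null(shifts) && nrow(shifts) >= 3) {
    sp <- spearman_rank(shifts$mw_post, shifts$gravy_post)
    spearman_rho <- sp$rho
    spearman_p <- sp$p_value
  }
  structure(list(
    total_edits = total_edits,
    total_mrna_edits = total_mrna,
    total_aa_substitutions = total_aa,
    pct_aa_changing = round_half_up(100 * total_aa / total_mrna, 0),
    type_spectrum_pct = type_spectrum_pct,
    type_totals = type_totals,
    transversion_pct = transversion_pct,
    codon_position_counts = codon_position_counts,
    codon_position_pcts = codon_position_pcts,
    double_substitution_pct = double_substitution_pct,
    gc_pre_pct = gc_pre,
    gc_post_pct = gc_post,
    spearman_rho = spearman_rho,
    spearman_p = spearman_p), class = "aggregate_stats")
}

#' @export
print.aggregate_stats <- function(x, ...) {
  cat(sprintf("<aggregate_stats> %d edits (%d mRNA), %d aa substitutions (%d%%)\n",
              x$total_edits, x$total_mrna_edits, x$total_aa_substitutions,
              x$pct_aa_changing))
  cat("  top types:",
      paste(utils::head(names(sort(x$type_spectrum_pct, decreasing = TRUE)), 4),
            collapse = " "), "\n")
  invisible(x)
}

#' Percent identity to a homolog before and after editing
#'
#' Global pairwise alignment (Needleman-Wunsch, BLOSUM62, gap open 10 /
#' extend 0.5) of the unedited and edited conceptual translations against a
#' homolog protein. Identity is 100 x identical columns / alignment length,
#' rounded to the nearest integer.
#'
#' @param protein_pre,protein_post amino-acid strings (no '*').
#' @param homolog homolog amino-acid string.
#' @return named numeric: \code{identity_pre_pct}, \code{identity_post_pct}.
#' @export
identity_to_homolog <- function(protein_pre, protein_post, homolog) {
  c(identity_pre_pct = alignment_identity(protein_pre, homolog),
    identity_post_pct = alignment_identity(protein_post, homolog))
}

alignment_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  round_half_up(100 * sum(pa == sa & pa != "-") / length(pa), 0)
}

#' Molecular weight and GRAVY before and after editing
#'
#' Descriptors are computed on the conceptual translations of the reference
#' and the edited transcript. Premature stops ('*', expected pre-editing in
#' stop-restoration genes) are removed from the translation before computing
#' descriptors and flagged in the output.
#'
#' @param gene a protein-coding \code{gene_record}.
#' @param sites editing sites on the gene.
#' @return one-row data.frame: \code{gene_id}, \code{mw_pre}, \code{mw_post},
#'   \code{gravy_pre}, \code{gravy_post}, \code{premature_stop_pre},
#'   \code{premature_stop_post}.
#' @export
hydropathy_mw_shift <- function(gene, sites) {
  if (gene$molecule_class != "protein_coding")
    stop("hydropathy/MW shift requires a protein-coding gene")
  pre <- translate_cds(gene$seq, gene$start_override)
  post <- translate_cds(apply_edits(gene, sites), gene$start_override)
  strip <- function(p) gsub("*", "", p, fixed = TRUE)
  data.frame(gene_id = gene$gene_id,
             mw_pre = molecular_weight(strip(pre)),
             mw_post = molecular_weight(strip(post)),
             gravy_pre = gravy(strip(pre)),
             gravy_post = gravy(strip(post)),
             premature_stop_pre = grepl("*", pre, fixed = TRUE),
             premature_stop_post = grepl("*", post, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks use average ranks for ties; rho is the Pearson correlation of the
#' rank vectors; the p-value uses the t approximation with n - 2 degrees of
#' freedom (two-sided).
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return list: \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_rank <- function(xs, ys) {
  n <- length(xs)
  if (length(ys) != n) stop("xs and ys must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  if (anyNA(xs) || anyNA(ys)) stop("NA values not allowed")
  if (length(unique(xs)) == 1L || length(unique(ys)) == 1L)
    stop("correlation undefined for a constant vector")
  rx <- rank(xs, ties.method = "average")
  ry <- rank(ys, ties.method = "average")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
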