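# Editing-site calling from strand-resolved RNA/DNA pileups.
#
# The calling filters mirror established organellar RDD practice: a strict
# coverage floor ("more than 10 reads" = depth >= 11), a majority edited
# fraction, exclusion of positions that are polymorphic in DNA reads, and
# rejection of the two classic false-positive modes - all supporting reads
# on one strand, or all mismatches at read ends.

#' Calling parameters
#'
#' @param min_coverage minimum RNA depth at a site (strictly more than 10
#'   reads by default, i.e. 11).
#' @param min_edited_fraction minimum fraction of reads showing the edited
#'   base (majority rule by default; configurable for partial editing).
#' @param min_edited_reads minimum absolute number of edited reads.
#' @param max_dna_alt_fraction DNA alternate-allele fraction above which a
#'   position is treated as a genomic SNP and excluded.
#' @param strand_bias_p significance level of the two-sided Fisher exact
#'   strand test.
#' @param end_window_nt distance from a read end inside which an observation
#'   counts as "at the end of the alignment".
#' @param max_end_fraction fraction of edited observations at read ends at
#'   or above which the position-bias test fails.
#' @return list of class \code{calling_params}.
#' @export
calling_params <- function(min_coverage = 11L,
                           min_edited_fraction = 0.5,
                           min_edited_reads = 3L,
                           max_dna_alt_fraction = 0.01,
                           strand_bias_p = 0.005,
                           end_window_nt = 10L,
                           max_end_fraction = 0.9) {
  p <- list(min_coverage = as.integer(min_coverage),
            min_edited_fraction = min_edited_fraction,
            min_edited_reads = as.integer(min_edited_reads),
            max_dna_alt_fraction = max_dna_alt_fraction,
            strand_bias_p = strand_bias_p,
            end_window_nt = as.integer(end_window_nt),
            max_end_fraction = max_end_fraction)
  stopifnot(p$min_coverage >= 1L, p$min_edited_reads >= 0L,
            p$min_edited_fraction >= 0, p$min_edited_fraction <= 1,
            p$max_dna_alt_fraction >= 0, p$max_dna_alt_fraction <= 1,
            p$strand_bias_p > 0, p$strand_bias_p < 1,
            p$end_window_nt >= 0L,
            p$max_end_fraction >= 0, p$max_end_fraction <= 1)
  structure(p, class = "calling_params")
}

#' Build a strand-resolved pileup
#'
#' Piles up aligned reads on a reference. Read SEQ fields are already on the
#' forward reference strand (SAM convention), so reverse-strand reads
#' contribute their stored bases directly while their strand is tracked for
#' bias testing. Per-observation read offsets are retained so position-bias
#' tests can be run at candidate sites.
#'
#' @param reads an \code{aligned_reads} data.frame.
#' @param reference reference DNA string the reads were mapped to.
#' @return object of class \code{pileup}: reference, per-position
#'   strand-resolved base counts, and per-observation vectors.
#' @export
build_pileup <- function(reads, reference) {
  assert_dna(reference, "reference")
  L <- nchar(reference)
  lens <- nchar(reads$seq)
  if (nrow(reads) && (any(reads$start < 0L) || any(reads$start + lens > L)))
    stop("read overhangs the reference (coordinate error)")
  n_obs <- sum(lens)
  if (n_obs == 0L) {
    counts <- matrix(0L, nrow = 8L, ncol = L)
  }
  obs_pos <- integer(n_obs); obs_base <- integer(n_obs)
  if (nrow(reads)) {
    obs_pos <- rep(reads$start, lens) +
      (sequence(lens) - 1L)                       # 0-based template position
    obs_off <- sequence(lens) - 1L                # 0-based offset in read
    obs_readlen <- rep(lens, lens)
    chars <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
    obs_base <- match(chars, DNA_BASES)           # NA for ambiguity codes
    obs_strand <- rep(ifelse(reads$strand == "-", 2L, 1L), lens)
    keep <- !is.na(obs_base)
    if (!all(keep)) {
      obs_pos <- obs_pos[keep]; obs_base <- obs_base[keep]
      obs_strand <- obs_strand[keep]; obs_off <- obs_off[keep]
      obs_readlen <- obs_readlen[keep]
    }
    code <- (obs_base - 1L) * 2L + obs_strand     # 1..8: base x strand
    counts <- matrix(tabulate(as.double(obs_pos) * 8 + code,
                              nbins = 8 * L),
                     nrow = 8L, ncol = L)
  } else {
    obs_strand <- integer(0); obs_off <- integer(0); obs_readlen <- integer(0)
  }
  structure(
    list(reference = reference,
         ref_chars = seq_chars(reference),
         length = L,
         counts = counts,   # rows: A+,A-,C+,C-,G+,G-,T+,T- ; cols: positions
         obs = list(pos = obs_pos, base = obs_base, strand = obs_strand,
                    offset = obs_off, readlen = obs_readlen)),
    class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d nt reference, %d base observations, mean depth %.1f\n",
              x$length, length(x$obs$pos), length(x$obs$pos) / x$length))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pileup a \code{pileup}.
#' @param position 0-based reference position.
#' @return list: \code{position}, \code{ref_base}, \code{depth},
#'   \code{base_counts} (4x2 matrix, bases x strands), and \code{obs}
#'   (data.frame of base, strand, offset, readlen for every observation).
#' @export
pileup_column <- function(pileup, position) {
  if (position < 0L || position >= pileup$length)
    stop("position out of range")
  cnt <- matrix(pileup$counts[, position + 1L], nrow = 4L, byrow = TRUE,
                dimnames = list(DNA_BASES, c("+", "-")))
  idx <- which(pileup$obs$pos == position)
  obs <- data.frame(base = DNA_BASES[pileup$obs$base[idx]],
                    strand = c("+", "-")[pileup$obs$strand[idx]],
                    offset = pileup$obs$offset[idx],
                    readlen = pileup$obs$readlen[idx],
                    stringsAsFactors = FALSE)
  list(position = position,
       ref_base = pileup$ref_chars[position + 1L],
       depth = sum(cnt),
       base_counts = cnt,
       obs = obs)
}

#' Detect genomic variant positions from a DNA pileup
#'
#' Flags positions where any non-reference base is supported by at least two
#' reads and exceeds \code{max_dna_alt_fraction} of the depth. Called sites
#' falling on such positions are genomic polymorphisms, not RNA editing.
#'
#' @param dna_pileup a \code{pileup} built from DNA reads.
#' @param params a \code{calling_params}.
#' @return sorted integer vector of 0-based variant positions.
#' @export
detect_dna_variants <- function(dna_pileup, params = calling_params()) {
  cnt <- dna_pileup$counts
  base_tot <- cnt[c(1L, 3L, 5L, 7L), , drop = FALSE] +
    cnt[c(2L, 4L, 6L, 8L), , drop = FALSE]       # 4 x L, strands summed
  depth <- colSums(base_tot)
  ref_idx <- match(dna_pileup$ref_chars, DNA_BASES)
  L <- dna_pileup$length
  ref_cnt <- base_tot[cbind(ref_idx, seq_len(L))]
  alt_mat <- base_tot
  alt_mat[cbind(ref_idx, seq_len(L))] <- 0L
  alt_max <- alt_mat[cbind(max.col(t(alt_mat), ties.method = "first"),
                           seq_len(L))]
  variant <- depth > 0L & alt_max >= 2L &
    (alt_max / pmax(depth, 1L)) > params$max_dna_alt_fraction
  sort(which(variant)) - 1L
}

#' Strand- and position-bias tests at one pileup column
#'
#' Strand test: two-sided Fisher exact test on the 2x2 table of
#' reference/alternate counts by forward/reverse strand. The test fails only
#' when the p-value falls below \code{strand_bias_p} AND every alternate
#' observation sits on a single strand while both strands carry coverage -
#' the "all reads align only in one direction" false-positive mode. A
#' significant p-value alone does not fail strand-skewed but two-strand
#' supported sites.
#'
#' Position test: fails when at least \code{max_end_fraction} of the
#' alternate observations lie within \code{end_window_nt} of either read
#' end - the "mismatches at the end of the alignment" artefact mode.
#'
#' @param column a pileup column from \code{\link{pileup_column}}.
#' @param alt_base the alternate (edited) base, DNA alphabet.
#' @param params a \code{calling_params}.
#' @return list: \code{strand_bias_pass}, \code{position_bias_pass},
#'   \code{strand_p}, \code{end_fraction}.
#' @export
bias_tests <- function(column, alt_base, params = calling_params()) {
  bc <- column$base_counts
  if (!alt_base %in% rownames(bc)) stop("invalid alt base")
  alt_fwd <- bc[alt_base, "+"]; alt_rev <- bc[alt_base, "-"]
  if (alt_fwd + alt_rev == 0L)
    stop("no observations of alt base at this column")
  ref <- column$ref_base
  tab <- matrix(c(bc[ref, "+"], bc[ref, "-"], alt_fwd, alt_rev), nrow = 2L)
  p <- stats::fisher.test(tab)$p.value
  both_covered <- sum(bc[, "+"]) > 0L && sum(bc[, "-"]) > 0L
  one_sided_alt <- (alt_fwd == 0L) || (alt_rev == 0L)
  strand_fail <- (p < params$strand_bias_p) && one_sided_alt && both_covered
  alt_obs <- column$obs[column$obs$base == alt_base, , drop = FALSE]
  dist_end <- pmin(alt_obs$offset, alt_obs$readlen - 1L - alt_obs$offset)
  end_fraction <- mean(dist_end < params$end_window_nt)
  position_fail <- end_fraction >= params$max_end_fraction
  list(strand_bias_pass = !strand_fail,
       position_bias_pass = !position_fail,
       strand_p = p,
       end_fraction = end_fraction)
}

#' Call RNA editing sites from RNA and DNA pileups
#'
#' A position is called when: RNA depth >= \code{min_coverage}; the dominant
#' non-reference base reaches \code{min_edited_fraction} of the depth and
#' \code{min_edited_reads} reads; the position is not a DNA variant
#' (\code{\link{detect_dna_variants}}); and both bias tests pass. One site is
#' reported per position (the dominant alternate only); positions where a
#' second alternate base also has substantial support are withheld as
#' multi-allelic and reported in the \code{"multiallelic"} attribute.
#'
#' @param rna_pileup \code{pileup} from RNA reads.
#' @param dna_pileup \code{pileup} from DNA reads, or NULL to skip SNP
#'   exclusion.
#' @param gene optional \code{gene_record}; when supplied, the gene CDS must
#'   match the pileup reference at \code{cds_start} (identity check) and
#'   sites gain a \code{cds_position} column.
#' @param params a \code{calling_params}.
#' @param cds_start 0-based CDS offset on the pileup reference; defaults to
#'   the gene's \code{cds_start} attribute, else 0.
#' @return data.frame of editing sites (class \code{editing_sites}), sorted
#'   by position, with columns \code{gene_id}, \code{position} (0-based on
#'   the reference), \code{cds_position}, \code{dna_base}, \code{rna_base}
#'   (DNA alphabet), \code{label} (U notation), \code{is_transversion},
#'   \code{depth}, \code{edited_reads}, \code{edited_fraction},
#'   \code{strand_bias_pass}, \code{position_bias_pass}, plus NA codon
#'   annotation columns filled by
#'   \code{\link{annotate_codon_effects}}.
#' @export
call_editing_sites <- function(rna_pileup, dna_pileup = NULL, gene = NULL,
                               params = calling_params(), cds_start = NULL) {
  L <- rna_pileup$length
  if (!is.null(dna_pileup) && dna_pileup$length != L)
    stop("RNA and DNA pileups are not on the same reference")
  if (is.null(cds_start))
    cds_start <- if (!is.null(gene) && !is.null(attr(gene, "cds_start")))
      attr(gene, "cds_start") else 0L
  cds_start <- as.integer(cds_start)
  if (!is.null(gene)) {
    span <- substr(rna_pileup$reference, cds_start + 1L,
                   cds_start + nchar(gene$seq))
    if (span != gene$seq)
      stop("gene/pileup mismatch: CDS does not match the pileup reference ",
           "at cds_start=", cds_start)
  }
  cnt <- rna_pileup$counts
  base_tot <- cnt[c(1L, 3L, 5L, 7L), , drop = FALSE] +
    cnt[c(2L, 4L, 6L, 8L), , drop = FALSE]
  depth <- colSums(base_tot)
  ref_idx <- match(rna_pileup$ref_chars, DNA_BASES)
  alt_mat <- base_tot
  alt_mat[cbind(ref_idx, seq_len(L))] <- 0L
  alt_base_idx <- max.col(t(alt_mat), ties.method = "first")
  alt_best <- alt_mat[cbind(alt_base_idx, seq_len(L))]
  am2 <- alt_mat
  am2[cbind(alt_base_idx, seq_len(L))] <- 0L
  second_best <- am2[cbind(max.col(t(am2), ties.method = "first"),
                           seq_len(L))]
  cand <- which(depth >= params$min_coverage &
                  alt_best >= params$min_edited_reads &
                  alt_best / pmax(depth, 1L) >= params$min_edited_fraction)
  multi <- cand[second_best[cand] >= params$min_edited_reads &
                  second_best[cand] / depth[cand] > 0.1]
  cand <- setdiff(cand, multi)
  if (!is.null(dna_pileup)) {
    snp_pos <- detect_dna_variants(dna_pileup, params)
    cand <- setdiff(cand, snp_pos + 1L)
  }
  rows <- lapply(cand, function(j) {
    pos <- j - 1L
    ref <- rna_pileup$ref_chars[j]
    alt <- DNA_BASES[alt_base_idx[j]]
    col <- pileup_column(rna_pileup, pos)
    bias <- bias_tests(col, alt, params)
    et <- classify_edit(ref, alt)
    data.frame(gene_id = if (!is.null(gene)) gene$gene_id else "reference",
               position = pos,
               cds_position = pos - cds_start,
               dna_base = ref, rna_base = alt,
               label = et$label, is_transversion = et$is_transversion,
               depth = depth[j],
               edited_reads = alt_best[j],
               edited_fraction = alt_best[j] / depth[j],
               strand_bias_pass = bias$strand_bias_pass,
               position_bias_pass = bias$position_bias_pass,
               stringsAsFactors = FALSE)
  })
  sites <- if (length(rows)) do.call(rbind, rows) else empty_sites()
  sites <- sites[sites$strand_bias_pass & sites$position_bias_pass, ,
                 drop = FALSE]
  sites <- cbind(sites, empty_codon_annotation(nrow(sites)))
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("editing_sites", "data.frame"),
            multiallelic = multi - 1L)
}

empty_sites <- function() {
  data.frame(gene_id = character(0), position = integer(0),
             cds_position = integer(0), dna_base = character(0),
             rna_base = character(0), label = character(0),
             is_transversion = logical(0), depth = integer(0),
             edited_reads = integer(0), edited_fraction = numeric(0),
             strand_bias_pass = logical(0), position_bias_pass = logical(0),
             stringsAsFactors = FALSE)
}

empty_codon_annotation <- function(n) {
  data.frame(codon_index = rep(NA_integer_, n),
             codon_position = rep(NA_integer_, n),
             ref_codon = rep(NA_character_, n),
             alt_codon = rep(NA_character_, n),
             ref_aa = rep(NA_character_, n),
             alt_aa = rep(NA_character_, n),
             synonymous = rep(NA, n),
             stop_restoration = rep(NA, n),
             stringsAsFactors = FALSE)
}
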