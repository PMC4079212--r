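# Minicircle core-region feature scanning: GC-rich inverted repeats, the
# conserved RNA-binding motif (which contains a CCAAT-box), windowed GC
# profile, and TSS detection from 5'-end count tracks.

#' Find inverted repeats
#'
#' Seeds exact arm matches of length \code{min_arm} (left arm equal to the
#' reverse complement of the right arm), extends them maximally outward and
#' inward (allowing up to \code{max_mismatch} mismatched arm pairs), and
#' reports non-redundant repeats: overlapping repeats sharing at least half
#' of their arm span are merged, keeping the longest arm.
#'
#' @param seq DNA string.
#' @param min_arm minimum arm length (>= 3).
#' @param max_loop maximum loop (spacer) length between the arms.
#' @param max_mismatch mismatched pairs tolerated during arm extension
#'   (seeds are always exact).
#' @param min_arm_gc minimum GC percentage over both arms; 0 reports all
#'   repeats. AT-rich sequence is palindrome-prone (A pairs T), so scans of
#'   minicircle cores typically restrict to GC-rich repeats.
#' @return data.frame sorted by left-arm start, 0-based half-open spans:
#'   \code{left_start}, \code{left_end}, \code{right_start},
#'   \code{right_end}, \code{arm_length_nt}, \code{loop_length_nt},
#'   \code{arm_gc_pct}, \code{mismatches}.
#' @export
find_inverted_repeats <- function(seq, min_arm = 8L, max_loop = 60L,
                                  max_mismatch = 0L, min_arm_gc = 0) {
  if (min_arm < 3L) stop("min_arm must be at least 3")
  assert_dna(seq, "seq")
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 2L * min_arm) return(empty_ir_table())
  k <- as.integer(min_arm)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  rc <- vapply(kmers, revcomp, character(1), USE.NAMES = FALSE)
  index <- split(starts, kmers)
  comp <- complement_chars(chars)
  hits <- list()
  for (i in starts) {
    js <- index[[rc[i]]]
    if (is.null(js)) next
    js <- js[js >= i + k & js - (i + k) <= max_loop]
    for (j in js) {
      # arms: left [i, i+a), right [j, j+a); pair rule:
      # chars[i + t] complements chars[j + a - 1 - t]
      a <- k; li <- i; rj <- j
      mm <- 0L
      # outward extension: left grows left, right grows right
      while (li > 1L && rj + a <= n) {
        match_ok <- chars[li - 1L] == comp[rj + a]
        if (!match_ok && mm >= max_mismatch) break
        if (!match_ok) mm <- mm + 1L
        li <- li - 1L; a <- a + 1L
      }
      # inward extension: arms grow toward each other while loop remains
      while ((rj - 1L) - (li + a) >= 1L) {
        match_ok <- chars[li + a] == comp[rj - 1L]
        if (!match_ok && mm >= max_mismatch) break
        if (!match_ok) mm <- mm + 1L
        a <- a + 1L; rj <- rj - 1L
      }
      loop <- rj - (li + a)
      if (loop < 0L || loop > max_loop) next
      arm_seq <- c(chars[li:(li + a - 1L)], chars[rj:(rj + a - 1L)])
      hits[[length(hits) + 1L]] <- data.frame(
        left_start = li - 1L, left_end = li + a - 1L,
        right_start = rj - 1L, right_end = rj + a - 1L,
        arm_length_nt = a, loop_length_nt = loop,
        arm_gc_pct = 100 * mean(arm_seq %in% c("G", "C")),
        mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_ir_table())
  irs <- unique(do.call(rbind, hits))
  irs <- irs[irs$arm_gc_pct >= min_arm_gc, , drop = FALSE]
  if (!nrow(irs)) return(empty_ir_table())
  irs <- irs[order(-irs$arm_length_nt, irs$left_start), , drop = FALSE]
  # merge redundant repeats: >= 50% arm-span overlap keeps the longest arm
  kept <- list()
  for (r in seq_len(nrow(irs))) {
    cand <- irs[r, ]
    redundant <- FALSE
    for (kp in kept) {
      ov <- span_overlap(cand$left_start, cand$right_end,
                         kp$left_start, kp$right_end)
      if (ov >= 0.5 * (cand$right_end - cand$left_start)) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- cand
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

span_overlap <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1))
}

empty_ir_table <- function() {
  data.frame(left_start = integer(0), left_end = integer(0),
             right_start = integer(0), right_end = integer(0),
             arm_length_nt = integer(0), loop_length_nt = integer(0),
             arm_gc_pct = numeric(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan for a motif, allowing mismatches
#'
#' Sliding-window comparison over every position; overlapping hits allowed.
#'
#' @param seq DNA string.
#' @param motif motif to search (default: the conserved minicircle
#'   RNA-binding motif, which contains a CCAAT-box at offset 2).
#' @param max_mismatch mismatches tolerated per hit.
#' @return data.frame: \code{position} (0-based), \code{mismatches}.
#' @export
find_motif <- function(seq, motif = "CACCAATGCACC", max_mismatch = 0L) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  assert_dna(seq, "seq")
  m <- nchar(motif)
  n <- nchar(seq)
  if (m > n)
    return(data.frame(position = integer(0), mismatches = integer(0)))
  chars <- seq_chars(seq)
  mchars <- seq_chars(motif)
  n_win <- n - m + 1L
  mism <- integer(n_win)
  for (t in seq_len(m)) {
    mism <- mism + (chars[seq.int(t, t + n_win - 1L)] != mchars[t])
  }
  hit <- which(mism <= max_mismatch)
  data.frame(position = hit - 1L, mismatches = mism[hit])
}

#' Detect TSS candidates from a 5'-end count track
#'
#' Positions where the number of read 5' ends strictly exceeds the threshold
#' are reported as transcription start site candidates.
#'
#' @param five_prime_counts named numeric vector (names = 0-based positions)
#'   or two-column data.frame (position, count).
#' @param threshold count that must be strictly exceeded (default 50).
#' @return sorted integer vector of 0-based candidate positions.
#' @export
detect_tss <- function(five_prime_counts, threshold = 50) {
  if (is.data.frame(five_prime_counts)) {
    pos <- as.integer(five_prime_counts[[1]])
    cnt <- as.numeric(five_prime_counts[[2]])
  } else {
    pos <- as.integer(names(five_prime_counts))
    cnt <- as.numeric(five_prime_counts)
  }
  if (anyNA(pos)) stop("positions must be integers")
  if (any(cnt < 0)) stop("negative 5'-end count")
  sort(pos[cnt > threshold])
}

#' Annotate a minicircle sequence
#'
#' Bundles the inverted-repeat scan, motif scan (plus CCAAT-box positions),
#' TSS detection (when a 5'-end track is supplied) and a windowed GC profile.
#'
#' @param seq minicircle DNA string.
#' @param five_prime_counts optional 5'-end count track (see
#'   \code{\link{detect_tss}}).
#' @param ir_min_arm,ir_max_loop inverted-repeat scan parameters.
#' @param ir_min_gc minimum arm GC percentage for a repeat to be counted
#'   (default 60: the counted core elements are the GC-rich repeats).
#' @param motif motif sequence.
#' @param tss_threshold TSS count threshold.
#' @param gc_window,gc_step GC profile window and step (nt).
#' @return list of class \code{minicircle_annotation}: \code{ir_list},
#'   \code{ir_count}, \code{motif_hits}, \code{ccaat_positions},
#'   \code{tss_candidates}, \code{gc_profile} (data.frame: window_start
#'   0-based, gc_pct).
#' @export
annotate_minicircle <- function(seq, five_prime_counts = NULL,
                                ir_min_arm = 8L, ir_max_loop = 60L,
                                ir_min_gc = 60,
                                motif = "CACCAATGCACC", tss_threshold = 50,
                                gc_window = 50L, gc_step = 10L) {
  irs <- find_inverted_repeats(seq, min_arm = ir_min_arm,
                               max_loop = ir_max_loop,
                               min_arm_gc = ir_min_gc)
  hits <- find_motif(seq, motif)
  ccaat <- find_motif(seq, "CCAAT")$position
  tss <- if (is.null(five_prime_counts)) integer(0)
         else detect_tss(five_prime_counts, tss_threshold)
  n <- nchar(seq)
  starts <- seq.int(0L, max(0L, n - gc_window), by = gc_step)
  gc_prof <- data.frame(
    window_start = starts,
    gc_pct = vapply(starts, function(s)
      gc_content(substr(seq, s + 1L, min(n, s + gc_window))), numeric(1)))
  structure(list(ir_list = irs, ir_count = nrow(irs),
                 motif_hits = hits, ccaat_positions = ccaat,
                 tss_candidates = tss, gc_profile = gc_prof,
                 sequence_length = n),
            class = "minicircle_annotation")
}

#' @export
print.minicircle_annotation <- function(x, ...) {
  cat(sprintf("<minicircle_annotation> %d nt: %d IRs, %d motif hit(s), %d CCAAT box(es), %d TSS candidate(s)\n",
              x$sequence_length, x$ir_count, nrow(x$motif_hits),
              length(x$ccaat_positions), length(x$tss_candidates)))
  invisible(x)
}

#' Write minicircle features as GFF3
#'
#' Coordinates are converted to 1-based inclusive as GFF3 requires.
#'
#' @param annotation a \code{minicircle_annotation}.
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @return \code{path}, invisibly.
#' @export
write_features_gff3 <- function(annotation, path, seqid = "minicircle") {
  rows <- character(0)
  src <- "minied"
  irs <- annotation$ir_list
  if (nrow(irs)) {
    rows <- c(rows, sprintf(
      "%s\t%s\tinverted_repeat\t%d\t%d\t.\t.\t.\tID=ir%02d;arm_length=%d;loop_length=%d;arm_gc=%.1f",
      seqid, src, irs$left_start + 1L, irs$right_end, seq_len(nrow(irs)),
      irs$arm_length_nt, irs$loop_length_nt, irs$arm_gc_pct))
  }
  mh <- annotation$motif_hits
  if (nrow(mh)) {
    rows <- c(rows, sprintf(
      "%s\t%s\tsequence_motif\t%d\t%d\t.\t+\t.\tID=motif%02d;Name=core_motif;mismatches=%d",
      seqid, src, mh$position + 1L, mh$position + 12L, seq_len(nrow(mh)),
      mh$mismatches))
  }
  if (length(annotation$ccaat_positions)) {
    p <- annotation$ccaat_positions
    rows <- c(rows, sprintf(
      "%s\t%s\tCCAAT_motif\t%d\t%d\t.\t+\t.\tID=ccaat%02d",
      seqid, src, p + 1L, p + 5L, seq_along(p)))
  }
  if (length(annotation$tss_candidates)) {
    p <- annotation$tss_candidates
    rows <- c(rows, sprintf(
      "%s\t%s\tTSS\t%d\t%d\t.\t+\t.\tID=tss%02d",
      seqid, src, p + 1L, p + 1L, seq_along(p)))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
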