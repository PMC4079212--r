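# Small shared helpers.

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over {A,C,G,T}.
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("GATC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# Vectorised reverse complement on a character vector of bases.
revcomp_chars <- function(chars) {
  rev(chartr("ACGT", "TGCA", chars))
}

complement_chars <- function(chars) {
  chartr("ACGT", "TGCA", chars)
}

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up to a fixed number of decimals
#' (base R's round() rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_dna <- function(seq, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(sprintf("%s must be a single character string", what))
  if (nchar(seq) == 0L)
    stop(sprintf("%s must be non-empty", what))
  if (grepl("[^ACGT]", seq))
    stop(sprintf("%s contains characters outside {A,C,G,T}", what))
  invisible(seq)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

chars_seq <- function(chars) paste(chars, collapse = "")

# Derive a substream seed from a master seed, keeping the result a valid
# 32-bit integer. `k` separates independent uses of the same master seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647)
}
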