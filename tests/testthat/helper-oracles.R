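# Independent brute-force oracles used to cross-check package computations.
# These are written against primary definitions, not against package code.

# Kyte-Doolittle values transcribed independently (by residue groups).
ORACLE_KD <- local({
  v <- numeric(0)
  v[c("I", "V", "L")] <- c(4.5, 4.2, 3.8)
  v[c("F", "C", "M", "A")] <- c(2.8, 2.5, 1.9, 1.8)
  v[c("G", "T", "S", "W", "Y", "P")] <- c(-0.4, -0.7, -0.8, -0.9, -1.3, -1.6)
  v[c("H", "E", "Q", "D", "N", "K", "R")] <-
    c(-3.2, -3.5, -3.5, -3.5, -3.5, -3.9, -4.5)
  v
})

# ExPASy average amino-acid masses (free amino acids); residue mass is the
# amino-acid mass minus one water (18.01524 Da).
ORACLE_AA_MASS <- c(
  A = 89.0932, R = 174.2017, N = 132.1184, D = 133.1027, C = 121.1582,
  E = 147.1293, Q = 146.1445, G = 75.0669, H = 155.1546, I = 131.1736,
  L = 131.1736, K = 146.1882, M = 149.2124, F = 165.1900, P = 115.1310,
  S = 105.0930, T = 119.1197, W = 204.2262, Y = 181.1885, V = 117.1469)

oracle_gravy <- function(protein) {
  total <- 0
  res <- strsplit(protein, "")[[1]]
  for (r in res) total <- total + ORACLE_KD[[r]]
  total / length(res)
}

oracle_mw <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  total <- 18.01524
  for (r in res) total <- total + (ORACLE_AA_MASS[[r]] - 18.01524)
  total
}

oracle_motif_scan <- function(seq, motif, max_mismatch = 0L) {
  n <- nchar(seq); m <- nchar(motif)
  hits <- integer(0)
  if (m > n) return(hits)
  for (i in 1:(n - m + 1)) {
    window <- substr(seq, i, i + m - 1)
    mm <- sum(strsplit(window, "")[[1]] != strsplit(motif, "")[[1]])
    if (mm <= max_mismatch) hits <- c(hits, i - 1L)
  }
  hits
}

random_protein <- function(n) {
  paste(sample(names(ORACLE_KD), n, replace = TRUE), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random stop-free CDS beginning with ATG.
random_cds_oracle <- function(n_codons, gc = 0.4) {
  codons <- "ATG"
  while (length(codons) < n_codons) {
    cand <- random_dna(3, gc)
    if (!cand %in% c("TAA", "TAG", "TGA")) codons <- c(codons, cand)
  }
  paste(codons, collapse = "")
}

# Build an aligned_reads data.frame by hand for pileup tests.
manual_reads <- function(starts, strands, seqs, rname = "ref") {
  structure(data.frame(
    qname = sprintf("r%03d", seq_along(starts)), rname = rname,
    start = as.integer(starts), strand = strands, seq = seqs,
    stringsAsFactors = FALSE),
    class = c("aligned_reads", "data.frame"),
    read_length = unique(nchar(seqs))[1])
}

# Site rows in the caller's schema, for consequence tests without a caller
# run.
manual_sites <- function(gene, positions, rna_bases) {
  if (!length(positions)) {
    return(data.frame(gene_id = character(0), position = integer(0),
                      cds_position = integer(0), dna_base = character(0),
                      rna_base = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(gene$seq, "")[[1]]
  df <- data.frame(
    gene_id = gene$gene_id, position = as.integer(positions),
    cds_position = as.integer(positions),
    dna_base = chars[positions + 1],
    rna_base = chartr("U", "T", rna_bases),
    stringsAsFactors = FALSE)
  df$label <- mapply(function(d, r) classify_edit(d, r)$label,
                     df$dna_base, df$rna_base)
  df
}
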