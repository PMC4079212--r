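# Physico-chemical and genetic-code constants used across the package.

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values on the Kyte-Doolittle scale, the default
#' scale used by ProtParam-style GRAVY calculations. Values span [-4.5, 4.5].
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @keywords internal
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Average (not monoisotopic) residue masses in daltons, ProtParam-compatible.
# A residue mass is the amino-acid mass minus one water; a peptide's mass is
# the residue sum plus one water (MASS_WATER).
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

MASS_WATER <- 18.01524

# Bacterial/plastid genetic code (translation table 11). Codon assignments
# are identical to the standard code; only initiation differs, which this
# package handles through explicit start-codon overrides.
GENETIC_CODE_11 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Editing-type labels in the conventional reporting order: the four
# transitions first, then transversions. Labels are "DNA/RNA" with the RNA
# base in U notation (genomic T is written U on the RNA side).
EDIT_TYPE_ORDER <- c("A/G", "G/A", "C/U", "U/C",
                     "G/C", "G/U", "U/G", "A/C", "A/U",
                     "C/A", "C/G", "U/A")
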