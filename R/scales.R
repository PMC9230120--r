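# Physicochemical scale constants. All values are the published reference
# tables named in each comment; versions noted so downstream feature tables
# are reproducible.

# IUPAC ambiguity expansions (DNA). N and friends are accepted in input,
# excluded from compositional numerators/denominators, counted in length.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_ALPHABET <- names(IUPAC_EXPANSION)

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deoxynucleoside monophosphate residue masses (Da); chain MW subtracts one
# water (18.0153 Da) per phosphodiester bond.
DNA_RESIDUE_MASS <- c(A = 331.2218, C = 307.1971, G = 347.2212, T = 322.2085)

WATER_MASS <- 18.0153

# Average-isotopic amino-acid residue masses (Da), monomer minus water.
AA_RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

# Kyte & Doolittle (1982) hydropathy.
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8, G = -0.4, H = -3.2,
  I =  4.5, K = -3.9, L =  3.8, M =  1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Vihinen et al. (1994) normalized B-factor flexibility scale.
VIHINEN_FLEX <- c(
  A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915, G = 1.031,
  H = 0.950, I = 0.927, K = 1.102, L = 0.935, M = 0.952, N = 1.048,
  P = 1.049, Q = 1.037, R = 1.008, S = 1.046, T = 0.997, V = 0.931,
  W = 0.904, Y = 0.929
)

# Symmetric window-9 weights for the flexibility profile; centre weight 1,
# normalizer 5.25 = sum of weights, so a homopolymer window scores its
# residue's scale value.
FLEX_WINDOW_WEIGHTS <- c(0.25, 0.4375, 0.625, 0.8125, 1, 0.8125, 0.625, 0.4375, 0.25)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (DIWV). Rows = first residue, columns = second. Unlisted pairs weight 1.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

# Gill & von Hippel (1989) molar extinction coefficients at 280 nm.
EXTINCTION <- c(W = 5500, Y = 1490, cystine = 125)

# Bjellqvist pKa set used by the isoelectric-point solver; alternatives can
# be supplied to isoelectric_point() directly.
PKA_BJELLQVIST <- list(
  nterm = 7.50, cterm = 3.55,
  positive = c(H = 5.98, K = 10.00, R = 12.00),
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
)

# pepstats-convention amino-acid classes.
AA_CLASSES <- list(
  tiny      = c("A", "C", "G", "S", "T"),
  small     = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  aliphatic = c("A", "I", "L", "V"),
  aromatic  = c("F", "H", "W", "Y"),
  nonpolar  = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
  polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
  charged   = c("D", "E", "H", "K", "R"),
  basic     = c("H", "K", "R"),
  acidic    = c("D", "E")
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Canonical feature-column orders for the two feature tables.
NUCLEOTIDE_FEATURE_NAMES <- c(
  "length", "molecular_weight", "gc_content", "gc_pos1", "gc_pos2", "gc_pos3",
  "gc_skew_stdev", "at_skew_stdev", "melting_temperature", "shannon_entropy",
  "compression_ratio", "cai", "has_start_codon", "has_stop_codon"
)

PROTEIN_FEATURE_NAMES <- c(
  paste0("pct_", AA_STANDARD),
  "length", "molecular_weight", "isoelectric_point", "gravy", "aromaticity",
  "instability_index", "flexibility", "molar_ext_reduced", "molar_ext_oxidised",
  "aliphatic_index", "aliphaticity", "starts_with_met",
  paste0("pct_", names(AA_CLASSES))
)
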