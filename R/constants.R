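# Residue-level reference tables used across the toolkit.

# 20 standard residues plus the ambiguity/rare letters accepted on ingest.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_EXTENDED <- c(AA_STANDARD, c("B", "Z", "X", "U", "O", "J"))
NA_ALPHABET <- c("A", "C", "G", "T", "N")

# Average residue (monomer-in-chain) masses in Da; a peptide mass is the sum
# of its residue masses plus one water.
MASS_WATER <- 18.0153
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# Monoisotopic residue masses (selectable in annotate_properties()).
MASS_WATER_MONO <- 18.0105646863
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Kyte & Doolittle (1982) hydropathy values for GRAVY.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Ionizable-group pKa sets for the charge/pI model. EMBOSS values are the
# default; the Bjellqvist set is selectable.
PKA_SETS <- list(
  emboss = list(
    nterm = 8.6, cterm = 3.6,
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  ),
  bjellqvist = list(
    nterm = 7.5, cterm = 3.55,
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  )
)

# Pace et al. (1995) molar extinction coefficients at 280 nm.
EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

# Residue groups for grouped composition.
AA_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I", "M", "G"),
  aromatic  = c("F", "W", "Y"),
  polar     = c("S", "T", "C", "N", "Q"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  special   = c("P")
)

STOP_CODONS_STANDARD <- c("TAA", "TAG", "TGA")

# Start-codon presets for the sORF finder.
START_CODON_PRESETS <- list(
  canonical = "ATG",
  `near-cognate` = c("ATG", "CTG", "GTG", "TTG", "ACG")
)

# Feature controlled vocabulary and its PEFF rendering.
FEATURE_KINDS <- c("SIGNAL", "CHAIN", "PROPEP", "TRANSIT", "INIT_MET",
                   "VARIANT", "MOD_RES", "CONFLICT")

# kind -> term used inside the PEFF Processed tag
PROCESSED_TERMS <- c(
  SIGNAL = "signal peptide",
  CHAIN = "mature protein",
  PROPEP = "propeptide",
  TRANSIT = "transit peptide",
  INIT_MET = "initiator methionine"
)

# UniProt feature-table column label -> feature kind
UNIPROT_FEATURE_MAP <- c(
  "Signal peptide" = "SIGNAL",
  "Chain" = "CHAIN",
  "Propeptide" = "PROPEP",
  "Transit peptide" = "TRANSIT",
  "Initiator methionine" = "INIT_MET",
  "Natural variant" = "VARIANT",
  "Modified residue" = "MOD_RES",
  "Sequence conflict" = "CONFLICT"
)

# The TYPE token that opens each interval inside a UniProt TSV feature cell.
UNIPROT_CELL_TYPES <- c(
  SIGNAL = "SIGNAL", CHAIN = "CHAIN", PROPEP = "PROPEP", TRANSIT = "TRANSIT",
  INIT_MET = "INIT_MET", VARIANT = "VARIANT", MOD_RES = "MOD_RES",
  CONFLICT = "CONFLICT"
)
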