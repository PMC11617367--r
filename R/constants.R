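## Residue-level constant tables shared across modules.

#' The 20 canonical amino acids (one-letter codes)
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Average (chemical) residue masses in Da; peptide mass = sum + one water.
AA_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

WATER_AVG_MASS <- 18.0153

## Swiss-Prot background amino-acid frequencies (release-stable to ~0.1%),
## used by the proteome simulator.
AA_BACKGROUND_FREQ <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
)

## Van der Waals radii (Angstrom) for heavy atoms in SASA calculations.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

## Phosphorylated-residue bracket codes and the residue each may sit on.
PHOSPHO_MODS <- c(SEP = "S", TPO = "T", PTR = "Y")
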