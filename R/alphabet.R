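# Internal constants shared across modules.

# 20 standard amino acids, alphabetical one-letter order, then X (unknown),
# then the padding symbol.  This fixed column order defines every one-hot
# encoding in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_X <- "X"
AA_PAD <- "-"
AA22 <- c(AA20, AA_X, AA_PAD)

# Ionizable side chains plus the two terminal groups, in the fixed order used
# by composition vectors and by the 9-dimensional pKa parameter vector.
IONIZABLE_AA <- c("C", "D", "E", "H", "K", "R", "Y")
GROUP_ORDER <- c("n_term", "c_term", "C", "D", "E", "H", "K", "R", "Y")
# +1 for groups that are positive when protonated, -1 for groups that are
# neutral when protonated (acids).
GROUP_SIGN <- c(n_term = 1, c_term = -1, C = -1, D = -1, E = -1,
                H = 1, K = 1, R = 1, Y = -1)
BASIC_GROUPS  <- names(GROUP_SIGN)[GROUP_SIGN > 0]
ACIDIC_GROUPS <- names(GROUP_SIGN)[GROUP_SIGN < 0]

# Average (not monoisotopic) residue masses in Da; the 2D-PAGE convention.
RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.01524
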