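# Residue-level lookup tables shared across modules.

# the 20 standard amino acids, three-letter -> one-letter
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1 <- setNames(names(AA3), unname(AA3))

# Kyte-Doolittle hydropathy, used to parameterize the default pair wells
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# distance (Angstrom) of the side-chain pseudo-center beyond Cbeta, used when
# side-chain heavy atoms are absent from the input; roughly half the extent of
# the side chain beyond Cbeta
SC_EXTENSION <- c(A = 0.0, R = 2.6, N = 1.0, D = 1.0, C = 0.7,
                  Q = 1.6, E = 1.6, G = 0.0, H = 1.5, I = 1.1,
                  L = 1.3, K = 2.1, M = 1.6, F = 1.7, P = 0.7,
                  S = 0.4, T = 0.6, W = 2.0, Y = 2.1, V = 0.7)

CA_CB_LENGTH <- 1.53

# per-residue distance of the side-chain pseudo-center from Calpha (Gly gets
# the virtual-Cbeta distance so that it still has an excluded-volume center)
sc_pseudo_distance <- function(sequence1) {
  aa <- strsplit(sequence1, "")[[1]]
  unname(CA_CB_LENGTH + SC_EXTENSION[aa])
}

aa_index <- function(sequence1) {
  aa <- strsplit(sequence1, "")[[1]]
  idx <- match(aa, unname(AA3))
  if (anyNA(idx)) stop("sequence contains a non-standard one-letter code")
  idx
}

seq3_to_1 <- function(resnames) {
  out <- AA3[resnames]
  unname(out)
}

seq1_to_3 <- function(sequence1) {
  unname(AA1[strsplit(sequence1, "")[[1]]])
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
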