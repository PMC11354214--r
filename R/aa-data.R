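# Amino-acid reference tables used across the geometry operators.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.aa1 <- stats::setNames(names(.aa3), .aa3)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of the converted codes (`NA` for non-standard).
#' @examples
#' aa_1to3("K")
#' aa_3to1("LYS")
#' @export
aa_1to3 <- function(x) unname(.aa3[toupper(x)])

#' @rdname aa_1to3
#' @export
aa_3to1 <- function(x) unname(.aa1[toupper(x)])

# Full-name codes accepted by the variant parser ("Lys78Glu" dialect).
.aa_full <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              Ter = "*", Sec = "U", Pyl = "O")

# van der Waals radii (Angstrom), Chothia set as used by classic
# accessibility programs; unknown elements fall back to 1.8 with a warning.
.vdw_radii <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00, P = 1.80)
.vdw_default <- 1.8

# Reference maximum accessible surface per residue type (Angstrom^2),
# theoretical Gly-X-Gly values (Tien et al. 2013); basis for RSA.
.max_sasa <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
               Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
               L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
               S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Side-chain hydrogen-bond donor atoms. "rot" marks rotatable donors whose
# hydrogen is oriented toward the candidate acceptor (hydroxyls, NZ, SG);
# fixed sp2 donors get explicit in-plane hydrogens.
.sc_donors <- list(
  R = list(list(atom = "NE",  rot = FALSE), list(atom = "NH1", rot = FALSE),
           list(atom = "NH2", rot = FALSE)),
  N = list(list(atom = "ND2", rot = FALSE)),
  Q = list(list(atom = "NE2", rot = FALSE)),
  H = list(list(atom = "ND1", rot = FALSE), list(atom = "NE2", rot = FALSE)),
  K = list(list(atom = "NZ",  rot = TRUE)),
  S = list(list(atom = "OG",  rot = TRUE)),
  T = list(list(atom = "OG1", rot = TRUE)),
  Y = list(list(atom = "OH",  rot = TRUE)),
  W = list(list(atom = "NE1", rot = FALSE)),
  C = list(list(atom = "SG",  rot = TRUE))
)

# Side-chain acceptor atoms.
.sc_acceptors <- list(
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
  S = "OG", T = "OG1", Y = "OH", H = c("ND1", "NE2"), M = "SD"
)

# Charged-group atoms for salt-bridge detection. His counts as basic.
.basic_atoms <- list(K = "NZ", R = c("NE", "NH1", "NH2"), H = c("ND1", "NE2"))
.acidic_atoms <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"))

# Apolar side-chain carbons (carbon atoms not covalently bonded to N or O),
# the LigPlot-style basis for hydrophobic contacts.
.apolar_carbons <- list(
  A = "CB", R = c("CB", "CG"), N = "CB", D = "CB", C = "CB",
  Q = c("CB", "CG"), E = c("CB", "CG"), H = "CB",
  I = c("CB", "CG1", "CG2", "CD1"), L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD"), M = c("CB", "CG", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG"), S = character(), T = "CG2",
  W = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  V = c("CB", "CG1", "CG2")
)

# Compact backbone-independent rotamer library: common chi tuples (degrees)
# with prior weights (normalized at load). Ties in clash score are broken by
# weight, then by library order.
.rotamer_library <- list(
  ALA = list(list(chi = numeric(), w = 1)),
  GLY = list(list(chi = numeric(), w = 1)),
  SER = list(list(chi = -65, w = .45), list(chi = 180, w = .30), list(chi = 62, w = .25)),
  CYS = list(list(chi = -65, w = .50), list(chi = 180, w = .30), list(chi = 62, w = .20)),
  THR = list(list(chi = 62, w = .50), list(chi = -61, w = .40), list(chi = 180, w = .10)),
  VAL = list(list(chi = 175, w = .73), list(chi = -60, w = .20), list(chi = 65, w = .07)),
  LEU = list(list(chi = c(-65, 175), w = .60), list(chi = c(180, 65), w = .30),
             list(chi = c(-85, 65), w = .05), list(chi = c(65, 175), w = .05)),
  ILE = list(list(chi = c(-65, 170), w = .60), list(chi = c(-57, -60), w = .15),
             list(chi = c(62, 170), w = .15), list(chi = c(180, 165), w = .10)),
  MET = list(list(chi = c(-65, -65, -70), w = .30), list(chi = c(-65, 180, 75), w = .25),
             list(chi = c(180, 180, 75), w = .25), list(chi = c(-65, 180, 180), w = .20)),
  PRO = list(list(chi = c(-27, 36), w = .50), list(chi = c(28, -35), w = .50)),
  PHE = list(list(chi = c(-65, 90), w = .45), list(chi = c(180, 80), w = .35),
             list(chi = c(62, 90), w = .20)),
  TYR = list(list(chi = c(-65, 90), w = .45), list(chi = c(180, 80), w = .35),
             list(chi = c(62, 90), w = .20)),
  HIS = list(list(chi = c(-65, -70), w = .35), list(chi = c(-65, 80), w = .25),
             list(chi = c(180, -75), w = .25), list(chi = c(62, -75), w = .15)),
  TRP = list(list(chi = c(-65, 95), w = .35), list(chi = c(180, -105), w = .25),
             list(chi = c(180, 90), w = .25), list(chi = c(62, -90), w = .15)),
  ASP = list(list(chi = c(-70, -15), w = .50), list(chi = c(180, 10), w = .30),
             list(chi = c(62, 0), w = .20)),
  ASN = list(list(chi = c(-70, -20), w = .50), list(chi = c(180, 0), w = .30),
             list(chi = c(62, -10), w = .20)),
  GLU = list(list(chi = c(-65, 180, -10), w = .35), list(chi = c(-65, -65, -40), w = .25),
             list(chi = c(180, 180, 0), w = .25), list(chi = c(-65, 85, 0), w = .15)),
  GLN = list(list(chi = c(-65, 180, -10), w = .35), list(chi = c(-65, -65, -40), w = .25),
             list(chi = c(180, 180, 0), w = .25), list(chi = c(-65, 85, 0), w = .15)),
  LYS = list(list(chi = c(-65, 180, 180, 180), w = .40), list(chi = c(180, 180, 180, 180), w = .35),
             list(chi = c(-65, -65, 180, 180), w = .15), list(chi = c(-65, 180, 180, 65), w = .10)),
  ARG = list(list(chi = c(-65, 180, 180, 180), w = .30), list(chi = c(-65, 180, 65, 85), w = .25),
             list(chi = c(180, 180, 180, 180), w = .25), list(chi = c(-65, -65, 180, 180), w = .20))
)

# Ideal backbone internal coordinates (Engh-Huber style).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_ca_c_o = 120.8
)

.backbone_atoms <- c("N", "CA", "C", "O")

# Coarse phi/psi rectangle map for Ramachandran-style labels. Favored
# rectangles cover the alpha, beta and left-handed-alpha basins; "allowed"
# widens each rectangle by 20 degrees.
.rama_boxes <- list(
  alpha  = c(phi_min = -160, phi_max = -20, psi_min = -80, psi_max = -5),
  beta1  = c(phi_min = -180, phi_max = -45, psi_min = 90,  psi_max = 180),
  beta2  = c(phi_min = -180, phi_max = -45, psi_min = -180, psi_max = -150),
  lalpha = c(phi_min = 30,   phi_max = 90,  psi_min = -20, psi_max = 80)
)
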