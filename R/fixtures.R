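# Deterministic generators of synthetic structures with known ground truth.
# All coordinates come from ideal internal coordinates (standard peptide
# geometry); side chains are built from the idealized templates with
# library rotamers, so the same spec always yields bitwise-identical atoms.

# Build an ideal-geometry backbone chain from per-residue phi/psi (degrees).
# phi[1] and the final psi are only used for side-chain frames/O placement.
# Returns a list of per-residue named coordinate lists (N, CA, C, O).
.ideal_backbone <- function(phi, psi, omega = 180) {
  n <- length(phi)
  g <- .bb_geom
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C <- CA + g$ca_c * c(-cos(ang), sin(ang), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n - 1)) {
    r <- res[[i]]
    Nn <- .nerf(r$N, r$CA, r$C, g$c_n, g$ang_ca_c_n, psi[i])
    CAn <- .nerf(r$CA, r$C, Nn, g$n_ca, g$ang_c_n_ca, omega)
    Cn <- .nerf(r$C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi[i + 1])
    res[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    tor <- if (i < n) {
      .dihedral4(r$N, r$CA, r$C, res[[i + 1]]$N) + 180
    } else 180
    res[[i]]$O <- .nerf(r$N, r$CA, r$C, g$c_o, g$ang_ca_c_o, tor)
  }
  res
}

# Assemble an atom tibble from backbone residue list + sequence, adding
# side chains from the rotamer library (rotamer index per residue, default
# the top-weight rotamer; chi overrides win).
.atoms_from_backbone <- function(bb, aa, chain = "A", start_resno = 1L,
                                 chi_override = list()) {
  n <- length(bb)
  stopifnot(length(aa) == n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- bb[[i]]
    resno <- start_resno + i - 1L
    bb_tbl <- tibble::tibble(
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(r$N[1], r$CA[1], r$C[1], r$O[1]),
      y = c(r$N[2], r$CA[2], r$C[2], r$O[2]),
      z = c(r$N[3], r$CA[3], r$C[3], r$O[3])
    )
    aa3 <- aa_1to3(aa[i])
    chi <- chi_override[[as.character(resno)]] %||% .rotamer_library[[aa3]][[1]]$chi
    sc <- .build_side_chain(r$N, r$CA, r$C, aa3, chi)
    tbl <- dplyr::bind_rows(bb_tbl, sc)
    tbl$chain <- chain; tbl$resno <- resno; tbl$aa <- aa[i]; tbl$occ <- 1
    rows[[i]] <- tbl
  }
  dplyr::bind_rows(rows)[, c("chain", "resno", "aa", "atom", "element",
                             "x", "y", "z", "occ")]
}

.transform_atoms <- function(tbl, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(tbl[, c("x", "y", "z")]) %*% t(R)
  tbl$x <- xyz[, 1] + t[1]; tbl$y <- xyz[, 2] + t[2]; tbl$z <- xyz[, 3] + t[3]
  tbl
}

.rot_axis <- function(axis, deg) {
  u <- .unit(axis); th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation mapping unit vector a onto unit vector b.
.rot_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .vcross(a, b); c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) return(.rot_axis(.orth(a), 180))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

.orth <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.vcross(v, w))
}

# Canonicalize a segment: centroid of CA at origin, principal CA axis
# along +x (pointing from first to last residue), returns transformed tbl.
.canonical_segment <- function(tbl) {
  ca <- as.matrix(tbl[tbl$atom == "CA", c("x", "y", "z")])
  cen <- colMeans(ca)
  ax <- stats::prcomp(ca)$rotation[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
  R <- .rot_between(ax, c(1, 0, 0))
  .transform_atoms(tbl, R = R, t = -as.numeric(R %*% cen))
}

# Calibrated rigid transforms registering ideal antiparallel beta strands
# built with .ideal_backbone(phi = -139, psi = 135). T_UP places a copy one
# sheet position in +y; T_DOWN in -y. Values fixed by a one-off geometric
# calibration of the Kabsch-Sander bridge pattern on 5-residue strands.
.strand_pair <- list(
  up = list(flip_deg = 180, t = c(-0.75, 3.8, 0.0)),
  down = list(flip_deg = 180, t = c(0.75, -3.8, 0.0))
)

# Place an antiparallel partner of a canonical strand.
.antiparallel_copy <- function(tbl, side = c("up", "down")) {
  side <- match.arg(side)
  p <- .strand_pair[[side]]
  flipped <- .transform_atoms(tbl, R = .rot_axis(c(0, 0, 1), p$flip_deg))
  .transform_atoms(flipped, t = p$t)
}

#' Generate a synthetic test structure
#'
#' Deterministic builders of small structures with known ground truth:
#' \describe{
#'   \item{ideal_helix}{poly-Ala alpha helix (phi = -57, psi = -47).}
#'   \item{beta_hairpin}{two antiparallel 5-residue strands (numbering gap
#'     between them), registered for backbone H-bonding.}
#'   \item{disulfide_pair}{two cysteines with SG-SG placed at `distance`.}
#'   \item{salt_bridge_pair}{Lys and Glu with NZ-OE1 at `distance`.}
#'   \item{two_chain_complex}{two short helices in chains A and B with one
#'     constructed cross-chain Lys-Glu salt bridge (or none when
#'     `distance` exceeds the cutoff / `apart = TRUE`).}
#'   \item{random_coil}{random sequence and random favored-basin phi/psi,
#'     seeded.}
#' }
#' Ground truth (expected secondary structure, expected interaction pairs)
#' is attached as attribute `ground_truth`.
#'
#' @param kind fixture kind.
#' @param length number of residues (helix/coil kinds).
#' @param distance constructed pair distance, Angstrom.
#' @param seed RNG seed (random_coil only).
#' @param apart place the two chains ~50 A apart (two_chain_complex).
#' @return a [protein_structure][new_protein_structure] with attribute
#'   `ground_truth`.
#' @export
make_structure <- function(kind = c("ideal_helix", "beta_hairpin",
                                    "disulfide_pair", "salt_bridge_pair",
                                    "two_chain_complex", "random_coil"),
                           length = 15, distance = NULL, seed = 1L,
                           apart = FALSE) {
  kind <- match.arg(kind)
  out <- switch(kind,
    ideal_helix = .fx_helix(length),
    beta_hairpin = .fx_hairpin(),
    disulfide_pair = .fx_pair("C", "C", "SG", "SG", distance %||% 2.05,
                              gt_kind = "disulfide", gt_cut = 2.5),
    salt_bridge_pair = .fx_pair("K", "E", "NZ", "OE1", distance %||% 3.5,
                                gt_kind = "salt_bridge", gt_cut = 4.0),
    two_chain_complex = .fx_complex(distance %||% 3.5, apart = apart),
    random_coil = .fx_coil(length, seed)
  )
  out
}

.fx_helix <- function(n, aa = rep("A", n), chain = "A", start_resno = 1L) {
  bb <- .ideal_backbone(rep(-57, n), rep(-47, n))
  atoms <- .atoms_from_backbone(bb, aa, chain = chain, start_resno = start_resno)
  s <- new_protein_structure(atoms, source = sprintf("fixture:ideal_helix:%d", n))
  attr(s, "ground_truth") <- list(
    kind = "ideal_helix",
    helical_core = seq(3, n - 2),
    expected_bb_hbonds = n - 4
  )
  s
}

.fx_strand <- function(aa) {
  n <- length(aa)
  bb <- .ideal_backbone(rep(-139, n), rep(135, n))
  .canonical_segment(.atoms_from_backbone(bb, aa))
}

.fx_hairpin <- function(aa1 = rep("V", 5), aa2 = rep("T", 5)) {
  s1 <- .fx_strand(aa1)
  s2 <- .antiparallel_copy(.fx_strand(aa2), "up")
  s2$resno <- s2$resno + 7L  # numbering gap: no covalent connection
  # renumber second strand to ascend along the sheet
  atoms <- dplyr::bind_rows(s1, s2)
  s <- new_protein_structure(atoms, source = "fixture:beta_hairpin")
  attr(s, "ground_truth") <- list(
    kind = "beta_hairpin",
    strand1 = 1:5, strand2 = 8:12,
    strand_core = c(2:4, 9:11)
  )
  s
}

# Two isolated residues (resno 1 and 10) with a constructed atom-atom
# distance: residue B is rotated so its probe atom points back at A's, then
# translated onto the target distance.
.fx_pair <- function(aa_a, aa_b, atom_a, atom_b, distance,
                     gt_kind, gt_cut) {
  one <- function(aa, resno) {
    bb <- .ideal_backbone(c(-70, -70, -70), c(150, 150, 150))
    .atoms_from_backbone(bb, c("G", aa, "G"), start_resno = resno - 1L)
  }
  A <- one(aa_a, 2L)
  B <- one(aa_b, 10L)
  pa <- .tbl_xyz(A, 2L, atom_a); ca_a <- .tbl_xyz(A, 2L, "CA")
  pb <- .tbl_xyz(B, 10L, atom_b); ca_b <- .tbl_xyz(B, 10L, "CA")
  dir_a <- .unit(pa - ca_a)
  R <- .rot_between(.unit(ca_b - pb), dir_a)
  B <- .transform_atoms(B, R = R)
  pb <- .tbl_xyz(B, 10L, atom_b)
  target <- pa + distance * dir_a
  B <- .transform_atoms(B, t = target - pb)
  s <- new_protein_structure(dplyr::bind_rows(A, B),
                             source = sprintf("fixture:%s:%.2fA", gt_kind, distance))
  expected <- if (distance <= gt_cut) list(c(2L, 10L)) else list()
  attr(s, "ground_truth") <- list(kind = gt_kind, distance = distance,
                                  expected_pairs = expected)
  s
}

.tbl_xyz <- function(tbl, resno, atom) {
  i <- which(tbl$resno == resno & tbl$atom == atom)[1]
  c(tbl$x[i], tbl$y[i], tbl$z[i])
}

.fx_complex <- function(distance, apart = FALSE) {
  helixA <- .atoms_from_backbone(.ideal_backbone(rep(-57, 7), rep(-47, 7)),
                                 c("A", "A", "K", "A", "A", "A", "A"),
                                 chain = "A")
  helixB <- .atoms_from_backbone(.ideal_backbone(rep(-57, 7), rep(-47, 7)),
                                 c("A", "A", "E", "A", "A", "A", "A"),
                                 chain = "B")
  if (apart) {
    helixB <- .transform_atoms(helixB, t = c(50, 0, 0))
    expected <- list()
  } else {
    nz <- .tbl_xyz(helixA, 3L, "NZ"); ca_a <- .tbl_xyz(helixA, 3L, "CA")
    oe <- .tbl_xyz(helixB, 3L, "OE1"); ca_b <- .tbl_xyz(helixB, 3L, "CA")
    dir_a <- .unit(nz - ca_a)
    R <- .rot_between(.unit(ca_b - oe), dir_a)
    helixB <- .transform_atoms(helixB, R = R)
    oe <- .tbl_xyz(helixB, 3L, "OE1")
    helixB <- .transform_atoms(helixB, t = nz + distance * dir_a - oe)
    expected <- if (distance <= 4.0) list(c(3L, 3L)) else list()
  }
  s <- new_protein_structure(dplyr::bind_rows(helixA, helixB),
                             source = "fixture:two_chain_complex")
  attr(s, "ground_truth") <- list(kind = "two_chain_complex",
                                  expected_salt_bridges = expected)
  s
}

.fx_coil <- function(n, seed) {
  set.seed(seed)
  basins <- list(c(-57, -47), c(-139, 135), c(-75, 150), c(60, 40))
  pick <- sample(seq_along(basins), n, replace = TRUE)
  phi <- vapply(pick, function(k) basins[[k]][1] + stats::runif(1, -15, 15),
                numeric(1))
  psi <- vapply(pick, function(k) basins[[k]][2] + stats::runif(1, -15, 15),
                numeric(1))
  aa <- sample(setdiff(names(.aa3), c("G", "P")), n, replace = TRUE)
  atoms <- .atoms_from_backbone(.ideal_backbone(phi, psi), aa)
  s <- new_protein_structure(atoms, source = sprintf("fixture:random_coil:%d", seed))
  attr(s, "ground_truth") <- list(kind = "random_coil", seed = seed)
  s
}
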