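# Synthetic chemokine-fold precursor model. This is NOT a real protein
# structure: it is a programmatically constructed 94-residue single-chain
# model with the topology of a CC chemokine precursor (signal-peptide
# helix, N-loop, three-stranded antiparallel beta sheet joined by the
# 30s/40s loops, 50s loop, C-terminal helix) and engineered ground truth:
# two disulfides in precursor numbering (33-57 and 34-73), a histidine at
# 39 positioned so that mutating Lys78 to Glu creates a salt bridge, and
# no acidic residues anywhere else (so the wild type has zero salt
# bridges). It serves as a fold-level stand-in wherever a real structure
# would need a download.

.chemokine_seq <- paste0(
  "MALLAVLALAVLALLLAVLA", "SGA",          # 1-20 signal helix, 21-23 cap
  "ARGSNIS", "ATCCFTYTHTPLPWSG",          # 24-30, 31-46 N-loop (C33, C34, H39)
  "VRSYI",                                # 47-51 beta1
  "GTSGNCSG",                             # 52-59 30s loop (C57)
  "RAVIF",                                # 60-64 beta2
  "GTSGN",                                # 65-69 40s loop
  "VLTCT",                                # 70-74 beta3 (C73)
  "HGSK",                                 # 75-78 50s loop (H75, K78)
  "AWVQKYILALAQAL",                       # 79-92 C helix (W80 ... )
  "QL"                                    # 93-94 tail
)

# Interior CA positions along a polyline path at equal arc spacing.
.ca_path <- function(p0, p1, waypoints, n) {
  pts <- do.call(rbind, c(list(p0), waypoints, list(p1)))
  seglen <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  at <- function(sd) {
    k <- max(which(cum <= sd + 1e-9)); k <- min(k, nrow(pts) - 1)
    f <- (sd - cum[k]) / seglen[k]
    pts[k, ] + f * (pts[k + 1, ] - pts[k, ])
  }
  t(vapply(seq_len(n), function(i) at(total * i / (n + 1)), numeric(3)))
}

# Approximate backbone for loop residues threaded on CA positions. prev_ca
# and next_ca are the flanking anchor CAs. N and C sit near the inter-CA
# axis with standard along-axis/offset components; O on the sp2 bisector.
.loop_backbone <- function(cas, prev_ca, next_ca) {
  n <- nrow(cas)
  allca <- rbind(prev_ca, cas, next_ca)
  perp <- function(u) {
    p <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
    if (.vnorm(p) < 0.2) p <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
    .unit(p)
  }
  res <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- allca[i + 1, ]
    u_prev <- .unit(ca - allca[i, ])
    u_next <- .unit(allca[i + 2, ] - ca)
    N <- ca - 1.396 * u_prev + 0.42 * perp(u_prev)
    C <- ca + 1.429 * u_next + 0.533 * perp(u_next)
    res[[i]] <- list(N = N, CA = ca, C = C)
  }
  for (i in seq_len(n)) {
    C <- res[[i]]$C
    nxtN <- if (i < n) res[[i + 1]]$N else NULL
    dirO <- if (is.null(nxtN)) .unit(C - res[[i]]$CA) else
      .unit(.unit(C - nxtN) + .unit(C - res[[i]]$CA))
    res[[i]]$O <- C + 1.231 * dirO
  }
  res
}

.seg_atoms <- function(aa, phi, psi, start_resno) {
  .atoms_from_backbone(.ideal_backbone(phi, psi), aa, start_resno = start_resno)
}

# Re-place one side chain with the chi grid point bringing `atom` closest
# to `target` (light clash penalty to avoid burying it in a neighbour).
.aim_side_chain <- function(s, resno, atom, target, step = 10) {
  aa3 <- aa_1to3(s$aa[which(s$resno == resno)[1]])
  nchi <- .n_chi[[aa3]]
  if (nchi == 0) return(s)
  gN <- .atom_xyz(s, resno, "N"); gCA <- .atom_xyz(s, resno, "CA")
  gC <- .atom_xyz(s, resno, "C")
  grid <- seq(-180, 180 - step, by = step)
  base_chi <- .rotamer_library[[aa3]][[1]]$chi
  best <- NULL; best_val <- Inf
  combos <- if (nchi == 1) lapply(grid, function(a) a) else
    unlist(lapply(grid, function(a) lapply(grid, function(b) c(a, b))),
           recursive = FALSE)
  for (chi12 in combos) {
    chi <- base_chi
    chi[seq_along(chi12)] <- chi12
    sc <- .build_side_chain_raw(gN, gCA, gC, aa3, chi)
    i <- which(sc$atom == atom)
    if (length(i) == 0) next
    val <- .vnorm(sc$xyz[i, ] - target)
    if (val < best_val) { best_val <- val; best <- sc }
  }
  best <- tibble::tibble(atom = best$atom, element = best$element,
                         x = best$xyz[, 1], y = best$xyz[, 2],
                         z = best$xyz[, 3])
  keep <- !(s$resno == resno & !s$atom %in% c(.backbone_atoms, "OXT"))
  tbl <- tibble::as_tibble(s)[keep, , drop = FALSE]
  sc_rows <- tibble::tibble(
    chain = s$chain[1], resno = as.integer(resno),
    aa = s$aa[which(s$resno == resno)[1]],
    atom = best$atom, element = best$element,
    x = best$x, y = best$y, z = best$z, occ = 1
  )
  last_bb <- max(which(tbl$resno == resno))
  out <- dplyr::bind_rows(
    tbl[seq_len(last_bb), , drop = FALSE], sc_rows,
    if (last_bb < nrow(tbl)) tbl[(last_bb + 1):nrow(tbl), , drop = FALSE]
  )
  .reclass_structure(out, s)
}

#' Synthetic chemokine-fold precursor model
#'
#' Deterministically constructs the 94-residue synthetic model described in
#' the package vignette: a chemokine-like fold with engineered disulfides
#' (Cys33-Cys57, Cys34-Cys73 in precursor numbering), three antiparallel
#' beta strands (47-51, 60-64, 70-74), a C-terminal helix from residue 79
#' and a histidine at 39 placed so that the K78E mutant gains a salt
#' bridge with it. The wild type contains no acidic residues, hence no
#' salt bridges. This is a synthetic stand-in, not an experimentally
#' determined structure.
#'
#' @return a [protein_structure][new_protein_structure] with attribute
#'   `ground_truth`.
#' @export
synthetic_chemokine_model <- function() {
  aa <- strsplit(.chemokine_seq, "")[[1]]
  stopifnot(length(aa) == 94)
  ca_of <- function(tbl, rn) .tbl_xyz(tbl, rn, "CA")

  # beta sheet: beta2 canonical at origin, beta1 up (+y), beta3 down (-y)
  b2 <- .fx_strand(aa[60:64]); b2$resno <- b2$resno + 59L
  b1 <- .antiparallel_copy(.fx_strand(aa[47:51]), "up"); b1$resno <- b1$resno + 46L
  b3 <- .antiparallel_copy(.fx_strand(aa[70:74]), "down"); b3$resno <- b3$resno + 69L

  # C helix 79-94 (helical 79-92, coil tail), axis +x above the sheet
  hx_phi <- c(rep(-57, 14), -70, -70); hx_psi <- c(rep(-47, 14), 150, 150)
  hx <- .canonical_segment(.seg_atoms(aa[79:94], hx_phi, hx_psi, 79L))
  hx <- .transform_atoms(hx, t = c(7.5, -2, -6.2))

  # signal helix 1-23, parked away from the fold
  sg_phi <- c(-70, rep(-57, 19), -70, -70, -70)
  sg_psi <- c(150, rep(-47, 19), 150, 150, 150)
  sg <- .canonical_segment(.seg_atoms(aa[1:23], sg_phi, sg_psi, 1L))
  sg <- .transform_atoms(sg, R = .rot_axis(c(0, 0, 1), 25), t = c(-16, 22, -2))

  loop_atoms <- function(range_, p0, p1, waypoints) {
    n <- length(range_)
    cas <- .ca_path(p0, p1, waypoints, n)
    bb <- .loop_backbone(cas, p0, p1)
    .atoms_from_backbone(bb, aa[range_], start_resno = range_[1])
  }

  # anchors
  a_sg <- ca_of(sg, 23L)
  a_b1s <- ca_of(b1, 47L); a_b1e <- ca_of(b1, 51L)
  a_b2s <- ca_of(b2, 60L); a_b2e <- ca_of(b2, 64L)
  a_b3s <- ca_of(b3, 70L); a_b3e <- ca_of(b3, 74L)
  a_hxs <- ca_of(hx, 79L)

  # 30s loop (52-59) bulges below the sheet on the -x side, C57 underneath
  l30 <- loop_atoms(52:59, a_b1e, a_b2s,
                    list(c(-9, 4.5, 2.5), c(-10.5, 0.5, 4.5), c(-7, -1.5, 3)))
  # 40s loop (65-69) wraps around the +x edge
  l40 <- loop_atoms(65:69, a_b2e, a_b3s,
                    list(c(12, -0.5, 3.5), c(12.5, -4, 3)))
  # 50s loop (75-78): from the beta3 end up toward the helix start; K78
  # sits below/left of the helix N-terminus
  l50 <- loop_atoms(75:78, a_b3e, a_hxs,
                    list(c(-8.5, -7.5, -0.5), c(-9.0, -5.0, -4.0)))
  # N-loop (24-46): from the parked signal peptide, dives under the sheet
  # (C33/C34 reach C57 and C73 from below), rises past the helix start
  # (H39 near the future E78 carboxylate), then on to beta1
  k78_ca <- ca_of(l50, 78L)
  h39_way <- k78_ca + c(-5.6, -2.4, 1.5)
  l24 <- loop_atoms(24:46, a_sg, a_b1s,
                    list(c(-16, 10, 1), c(-11.5, 3.5, 5.5),    # approach
                         c(-6.5, -0.5, 6.4),                   # C33/C34 zone
                         c(-4.5, -6.5, 2.5),                   # swing past b3
                         h39_way,                              # H39 zone
                         c(-2.5, -9.5, -6.5), c(6, -9, -4)))
  atoms <- dplyr::bind_rows(sg, l24, b1, l30, b2, l40, b3, l50, hx)
  s <- new_protein_structure(atoms, source = "synthetic_chemokine_model")

  # engineer the disulfides: iterative mutual aiming of SG atoms
  for (pair in list(c(33L, 57L), c(34L, 73L))) {
    a <- pair[1]; b <- pair[2]
    for (it in 1:3) {
      tb <- .atom_xyz(s, b, "SG") %||% .atom_xyz(s, b, "CB")
      s <- .aim_side_chain(s, a, "SG", tb, step = 5)
      ta <- .atom_xyz(s, a, "SG")
      s <- .aim_side_chain(s, b, "SG", ta, step = 5)
    }
    # place the two SG exactly at bond distance along their current axis
    ga <- .atom_xyz(s, a, "SG"); gb <- .atom_xyz(s, b, "SG")
    mid <- (ga + gb) / 2; u <- .unit(gb - ga)
    s <- .move_atom(s, a, "SG", mid - 1.025 * u)
    s <- .move_atom(s, b, "SG", mid + 1.025 * u)
  }

  # aim His39 NE2 at the carboxylate the K78E mutant actually adopts
  # (the builder's clash-minimizing rotamer); iterate since moving His39
  # can change the rotamer ranking
  for (it in 1:3) {
    mu <- build_mutant(s, "K78E")
    oe <- .atom_xyz(mu, 78L, "OE1")
    s <- .aim_side_chain(s, 39L, "NE2", oe, step = 5)
  }

  attr(s, "ground_truth") <- list(
    kind = "chemokine_like",
    sequence = .chemokine_seq,
    disulfides = list(c(33L, 57L), c(34L, 73L)),
    strand_cores = list(48:50, 61:63, 71:73),
    c_helix_start = 80L,
    signal_helix_core = 4:19,
    k78e_salt_bridge_partner = 39L
  )
  s
}

# Move a single named atom to a new position.
.move_atom <- function(s, resno, atom, pos) {
  i <- which(s$resno == resno & s$atom == atom)[1]
  s$x[i] <- pos[1]; s$y[i] <- pos[2]; s$z[i] <- pos[3]
  s
}
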