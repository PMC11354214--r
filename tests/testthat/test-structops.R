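test_that("ideal helix is assigned H over its core", {
  h <- make_structure("ideal_helix", length = 15)
  ss <- assign_secondary_structure(h)
  expect_true(all(ss$ss[3:13] == "H"))
  expect_false(ss$ss[1] == "H")
  expect_false(ss$ss[15] == "H")
  # every residue gets exactly one label from the reduced alphabet
  expect_true(all(ss$ss %in% c("H", "G", "E", "T", "C")))
  expect_equal(nrow(ss), 15)
})

test_that("beta hairpin fixture yields two registered strands", {
  hp <- make_structure("beta_hairpin")
  ss <- assign_secondary_structure(hp)
  gt <- attr(hp, "ground_truth")
  core <- ss$resno %in% gt$strand_core
  expect_true(all(ss$ss[core] == "E"))
  seg <- ss_segments(ss, "E")
  expect_equal(nrow(seg), 2)
})

test_that("secondary structure matches an external DSSP implementation", {
  # mdtraj ships a DSSP implementation; compare at helix/strand/coil level
  run_dssp <- function(s) {
    pdb <- tempfile(fileext = ".pdb")
    write_pdb(s, pdb)
    out <- system2("python", c("-c", shQuote(paste0(
      "import mdtraj, sys\n",
      "t = mdtraj.load('", pdb, "')\n",
      "print(''.join(mdtraj.compute_dssp(t, simplified=True)[0]))"
    ))), stdout = TRUE, stderr = FALSE)
    strsplit(tail(out, 1), "")[[1]]
  }
  red3 <- function(ss) ifelse(ss %in% c("H", "G"), "H",
                       ifelse(ss == "E", "E", "C"))
  for (kind in c("ideal_helix", "beta_hairpin")) {
    s <- make_structure(kind, length = 15)
    mine <- red3(assign_secondary_structure(s)$ss)
    ref <- run_dssp(s)
    ref[ref == "NA"] <- "C"
    expect_gte(mean(mine == ref), 0.8)
    # strand/helix cores must agree exactly
    core <- ref %in% c("H", "E") & mine %in% c("H", "E")
    expect_equal(mine[core], ref[core])
  }
})

test_that("too-short chains come back all coil", {
  h <- make_structure("ideal_helix", length = 3)
  expect_true(all(assign_secondary_structure(h)$ss == "C"))
})

test_that("an isolated atom recovers the analytic sphere area", {
  s <- new_protein_structure(tibble::tibble(
    chain = "A", resno = 1L, aa = "A", atom = "CA", element = "C",
    x = 0, y = 0, z = 0, occ = 1
  ))
  sa <- compute_sasa(s)
  expect_equal(sa$sasa, 4 * pi * (1.87 + 1.4)^2, tolerance = 0.01)
})

test_that("two overlapping spheres match the closed-form solution", {
  d <- 2.0
  s <- new_protein_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L), aa = "A", atom = "CA", element = "C",
    x = c(0, d), y = 0, z = 0, occ = 1
  ))
  sa <- compute_sasa(s)
  R <- 1.87 + 1.4
  h <- R - d / 2
  expected <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_equal(sum(sa$sasa), expected, tolerance = 0.01 * expected)
})

test_that("per-residue SASA sums exactly to the structure total", {
  s <- chemokine_model()
  res <- compute_sasa(s, n_points = 240)
  at <- compute_sasa(s, n_points = 240, level = "atom")
  expect_equal(sum(res$sasa), sum(at$sasa))
  expect_true(all(res$sasa >= 0))
})

test_that("unknown elements fall back to the default radius with a warning", {
  s <- new_protein_structure(tibble::tibble(
    chain = "A", resno = 1L, aa = "A", atom = "CA", element = "X",
    x = 0, y = 0, z = 0, occ = 1
  ))
  expect_warning(sa <- compute_sasa(s), "unknown element")
  expect_equal(sa$sasa, 4 * pi * (1.8 + 1.4)^2, tolerance = 0.01)
})

test_that("RSA and burial classes follow the documented boundaries", {
  tbl <- tibble::tibble(resno = 1:4, aa = c("A", "A", "A", "G"),
                        sasa = c(0, 0.2 * 129, 0.5 * 129, 104))
  acc <- relative_accessibility(tbl)
  expect_equal(acc$rsa, c(0, 20, 50, 100))
  # boundary goes to the more exposed class
  expect_equal(as.character(acc$burial_class),
               c("buried", "partially_exposed", "exposed", "exposed"))
})

test_that("helix backbone H-bond ladder matches a brute-force scan", {
  n <- 15
  h <- make_structure("ideal_helix", length = n)
  hb <- detect_hbonds(h)
  bb <- hb[hb$type == "bb-bb", ]
  # N-4 i -> i+4 bonds on an N-residue ideal helix
  expect_equal(nrow(bb), n - 4)
  expect_true(all(bb$donor_resno - bb$acceptor_resno == 4))
  # brute force: every donor N (with bisector H) against every acceptor O
  found <- character()
  for (i in 2:n) for (j in 1:n) {
    if (abs(i - j) < 2 && j == i - 1) next
    if (i == j) next
    N <- atom_xyz(h, i, "N"); CA <- atom_xyz(h, i, "CA")
    Cp <- atom_xyz(h, i - 1, "C"); O <- atom_xyz(h, j, "O")
    u1 <- (N - Cp) / sqrt(sum((N - Cp)^2)); u2 <- (N - CA) / sqrt(sum((N - CA)^2))
    H <- N + (u1 + u2) / sqrt(sum((u1 + u2)^2))
    dda <- sqrt(sum((N - O)^2)); dha <- sqrt(sum((H - O)^2))
    cosang <- sum((N - H) * (O - H)) / (dha * 1)
    ang <- acos(max(-1, min(1, cosang))) * 180 / pi
    if (dda <= 3.9 && dha <= 2.5 && ang >= 90) found <- c(found, paste(i, j))
  }
  expect_setequal(paste(bb$donor_resno, bb$acceptor_resno), found)
})

test_that("distant residues form no bonds or bridges", {
  far <- make_structure("salt_bridge_pair", distance = 10)
  expect_equal(nrow(detect_salt_bridges(far)), 0)
  expect_equal(nrow(detect_hbonds(far)[
    detect_hbonds(far)$type == "sc-sc", , drop = FALSE]), 0)
})

test_that("constructed salt-bridge pair matches the all-pairs oracle", {
  for (d in c(3.5, 3.99, 4.01, 4.5)) {
    s <- make_structure("salt_bridge_pair", distance = d)
    det <- detect_salt_bridges(s)
    expect_setequal(paste(det$basic_resno, det$acidic_resno),
                    brute_salt_bridges(s))
    expect_equal(nrow(det), length(attr(s, "ground_truth")$expected_pairs))
  }
})

test_that("disulfide detection uses greedy closest matching", {
  s <- make_structure("disulfide_pair", distance = 2.05)
  expect_equal(nrow(detect_disulfides(s)), 1)
  expect_equal(detect_disulfides(s)$distance, 2.05, tolerance = 1e-6)
  none <- make_structure("disulfide_pair", distance = 4.0)
  expect_equal(nrow(detect_disulfides(none)), 0)
  # three cysteines, SG distances 2.0 / 2.1 / 4.1: only the closest pair
  sg <- function(rn, x) tibble::tibble(
    chain = "A", resno = rn, aa = "C", atom = c("CA", "CB", "SG"),
    element = c("C", "C", "S"), x = x + c(0, 0.8, 1.6), y = rn * 0.001,
    z = 0, occ = 1)
  s3 <- new_protein_structure(dplyr::bind_rows(sg(1L, 0), sg(5L, 2.0),
                                               sg(9L, 4.1)))
  d12 <- sqrt(sum((atom_xyz(s3, 1, "SG") - atom_xyz(s3, 5, "SG"))^2))
  d23 <- sqrt(sum((atom_xyz(s3, 5, "SG") - atom_xyz(s3, 9, "SG"))^2))
  expect_equal(d12, 2.0, tolerance = 1e-3)
  expect_equal(d23, 2.1, tolerance = 1e-3)
  det <- detect_disulfides(s3)
  expect_equal(nrow(det), 1)
  expect_equal(c(det$resno1, det$resno2), c(1L, 5L))
})

test_that("structures without cysteine give an empty disulfide list", {
  expect_equal(nrow(detect_disulfides(make_structure("ideal_helix", length = 6))), 0)
})

test_that("hydrophobic contacts match the apolar-carbon oracle", {
  s <- chemokine_model()
  det <- detect_hydrophobic_contacts(s)
  expect_setequal(paste(det$resno1, det$resno2), brute_hydrophobic(s))
  # an all-Gly chain has no apolar side-chain carbons
  bbsp <- make_structure("ideal_helix", length = 8)
  gly <- new_protein_structure(within(tibble::as_tibble(bbsp), {
    aa <- "G"
  })[bbsp$atom %in% c("N", "CA", "C", "O"), ])
  expect_equal(nrow(detect_hydrophobic_contacts(gly)), 0)
})

test_that("superposition RMSD has the metric properties", {
  s <- chemokine_model()
  expect_equal(as.numeric(superpose_rmsd(s, s)), 0, tolerance = 1e-9)
  # rigid motion invariance
  R <- varstruct:::.rot_axis(c(1, 2, 3), 35)
  moved <- varstruct:::.transform_atoms(tibble::as_tibble(s), R = R,
                                        t = c(10, -4, 2))
  moved <- new_protein_structure(moved)
  expect_equal(as.numeric(superpose_rmsd(s, moved)), 0, tolerance = 1e-6)
  # symmetry
  mut <- build_mutant(s, "K78E")
  expect_equal(as.numeric(superpose_rmsd(s, mut)),
               as.numeric(superpose_rmsd(mut, s)), tolerance = 1e-9)
})

test_that("RMSD of a single displaced CA matches the independent fit", {
  h <- make_structure("ideal_helix", length = 10)
  pert <- tibble::as_tibble(h)
  i <- which(pert$atom == "CA" & pert$resno == 5)
  pert$x[i] <- pert$x[i] + 1.0
  pert <- new_protein_structure(pert)
  mine <- as.numeric(superpose_rmsd(h, pert))
  # independent oracle: bio3d least-squares fit on the same CA sets
  ca_a <- as.matrix(h[h$atom == "CA", c("x", "y", "z")])
  ca_b <- as.matrix(pert[pert$atom == "CA", c("x", "y", "z")])
  ref <- bio3d::rmsd(as.numeric(t(ca_a)), as.numeric(t(ca_b)),
                     fit = TRUE)
  expect_equal(mine, as.numeric(ref), tolerance = 1e-3)
  expect_gt(mine, 0.1)
})

test_that("phi/psi match the direct dihedral formula and bio3d", {
  s <- make_structure("random_coil", length = 10, seed = 11)
  pp <- compute_phi_psi(s)
  expect_true(is.na(pp$phi[1]))
  expect_true(is.na(pp$psi[10]))
  for (i in c(3, 5, 8)) {
    phi_ref <- ref_dihedral(atom_xyz(s, i - 1, "C"), atom_xyz(s, i, "N"),
                            atom_xyz(s, i, "CA"), atom_xyz(s, i, "C"))
    psi_ref <- ref_dihedral(atom_xyz(s, i, "N"), atom_xyz(s, i, "CA"),
                            atom_xyz(s, i, "C"), atom_xyz(s, i + 1, "N"))
    expect_equal(pp$phi[i], phi_ref, tolerance = 1e-9)
    expect_equal(pp$psi[i], psi_ref, tolerance = 1e-9)
  }
  # cross-check against bio3d's torsion code
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(s, pdb)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(pdb, verbose = FALSE))
  expect_equal(pp$phi[2:9], unname(tor$phi[2:9]), tolerance = 0.05)
  expect_equal(pp$psi[2:9], unname(tor$psi[2:9]), tolerance = 0.05)
})

test_that("ideal helix dihedrals sit in the favored region", {
  h <- make_structure("ideal_helix", length = 8)
  pp <- compute_phi_psi(h)
  expect_equal(pp$phi[4], -57, tolerance = 0.1)
  expect_equal(pp$psi[4], -47, tolerance = 0.1)
  expect_equal(pp$rama[4], "favored")
  expect_true(is.na(pp$rama[1]))
  expect_equal(rama_label(120, -120), "outlier")
  expect_equal(rama_label(-57, -47), "favored")
})

test_that("every reported interaction satisfies its geometric criterion", {
  s <- chemokine_model()
  hb <- detect_hbonds(s)
  expect_true(all(hb$distance <= 3.9))
  expect_true(all(hb$d_ha <= 2.5))
  expect_true(all(hb$angle >= 90))
  sb <- detect_salt_bridges(build_mutant(s, "K78E"))
  expect_true(all(sb$distance <= 4.0))
  ds <- detect_disulfides(s)
  expect_true(all(ds$distance <= 2.5))
  expect_false(any(duplicated(c(ds$resno1, ds$resno2))))
  hp <- detect_hydrophobic_contacts(s)
  expect_true(all(hp$distance <= 3.9))
})
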