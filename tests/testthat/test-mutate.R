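test_that("backbone atoms are bitwise unchanged by mutation", {
  s <- chemokine_model()
  bb <- function(x) as.matrix(x[x$atom %in% c("N", "CA", "C", "O"),
                                c("x", "y", "z")])
  for (v in c("K78E", "W80G", "C34S", "A61V", "L12P")) {
    mut <- build_mutant(s, v)
    expect_identical(bb(mut), bb(s))
  }
})

test_that("mutation is deterministic and changes exactly one residue", {
  s <- chemokine_model()
  m1 <- build_mutant(s, "W80S")
  m2 <- build_mutant(s, "W80S")
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  seq_wt <- strsplit(structure_sequence(s), "")[[1]]
  seq_mut <- strsplit(structure_sequence(m1), "")[[1]]
  expect_equal(sum(seq_wt != seq_mut), 1)
  expect_equal(seq_mut[80], "S")
})

test_that("wild-type mismatch and identity substitutions error", {
  s <- chemokine_model()
  expect_error(build_mutant(s, "A78E"), "mismatch")
  expect_error(build_mutant(s, "K999E"), "not in structure")
})

test_that("Gly gains and losses handle the missing side chain", {
  s <- chemokine_model()
  g <- build_mutant(s, "W80G")
  expect_equal(sum(g$resno == 80), 4) # backbone only
  # Gly -> Ala: CB rebuilt with ideal tetrahedral geometry
  back <- build_mutant(g, "G80A")
  cb <- atom_xyz(back, 80, "CB"); ca <- atom_xyz(back, 80, "CA")
  n <- atom_xyz(back, 80, "N"); c3 <- atom_xyz(back, 80, "C")
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.02)
  ang <- function(a, b, cc) {
    v1 <- a - b; v2 <- cc - b
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  expect_equal(ang(n, ca, cb), 110.5, tolerance = 2)
  expect_equal(ang(c3, ca, cb), 110.5, tolerance = 2)
})

test_that("mutate then revert restores the original side chain closely", {
  s <- chemokine_model()
  fwd <- build_mutant(s, "A61V")
  back <- build_mutant(fwd, "V61A")
  xyz_a <- as.matrix(s[s$resno == 61, c("x", "y", "z")])
  xyz_b <- as.matrix(back[back$resno == 61, c("x", "y", "z")])
  expect_equal(nrow(xyz_a), nrow(xyz_b))
  expect_lt(sqrt(mean(rowSums((xyz_a - xyz_b)^2))), 0.2)
})

test_that("Cys substitution destroys its disulfide", {
  s <- chemokine_model()
  expect_equal(nrow(detect_disulfides(s)), 2)
  mut <- build_mutant(s, "C34S")
  ds <- detect_disulfides(mut)
  expect_equal(nrow(ds), 1)
  expect_equal(c(ds$resno1, ds$resno2), c(33L, 57L))
  expect_equal(sum(mut$resno == 34 & mut$atom == "SG"), 0)
})

test_that("clash score follows the squared-overlap formula", {
  # two alanines reduced to CA-CB, CB groups facing each other head-on
  two_ala <- function(d) {
    new_protein_structure(tibble::tibble(
      chain = "A", resno = c(1L, 1L, 5L, 5L),
      aa = "A", atom = c("CA", "CB", "CB", "CA"), element = "C",
      x = c(0, 1.53, 1.53 + d, 3.06 + d), y = 0, z = 0, occ = 1
    ))
  }
  # isolated side chain
  expect_equal(clash_score(two_ala(20), 1), 0)
  # exactly at vdW contact (C+C = 3.74): zero-penalty boundary
  expect_equal(clash_score(two_ala(3.74), 1), 0, tolerance = 1e-9)
  # overlap of 0.5 A -> penalty 0.5^2 = 0.25 from the CB-CB pair
  expect_equal(clash_score(two_ala(3.24), 1), 0.25, tolerance = 1e-6)
})

test_that("strained substitutions are flagged but still built", {
  s <- chemokine_model()
  # tryptophan into the packed core: no clash-free rotamer expected
  mut <- build_mutant(s, "T53W")
  expect_true(is.logical(attr(mut, "strained")))
  expect_equal(structure_sequence(mut, collapse = FALSE)[["53"]], "W")
})

test_that("mutant PDB export records variant provenance", {
  s <- chemokine_model()
  mut <- build_mutant(s, "K78E")
  tmp <- tempfile(fileext = ".pdb")
  write_mutant_pdb(mut, tmp, seed = 7)
  head <- readLines(tmp, n = 2)
  expect_match(head[1], "VARIANT K78E")
  expect_match(head[2], "SEED 7")
  reread <- read_pdb(tmp)
  expect_equal(nrow(reread), nrow(mut))
})
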