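test_that("fixture generation is deterministic", {
  a <- make_structure("random_coil", length = 12, seed = 5)
  b <- make_structure("random_coil", length = 12, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c1 <- make_structure("random_coil", length = 12, seed = 6)
  expect_false(identical(as.data.frame(a), as.data.frame(c1)))
  m1 <- synthetic_chemokine_model()
  m2 <- synthetic_chemokine_model()
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("constructed pair fixtures carry their ground truth", {
  ds <- make_structure("disulfide_pair", distance = 2.05)
  expect_equal(length(attr(ds, "ground_truth")$expected_pairs), 1)
  # boundary: a 4.5 A 'salt bridge' is beyond the 4.0 cutoff
  none <- make_structure("salt_bridge_pair", distance = 4.5)
  expect_equal(length(attr(none, "ground_truth")$expected_pairs), 0)
  expect_equal(nrow(detect_salt_bridges(none)), 0)
  # the constructed distance is exact
  sb <- make_structure("salt_bridge_pair", distance = 3.5)
  d <- sqrt(sum((atom_xyz(sb, 2, "NZ") - atom_xyz(sb, 10, "OE1"))^2))
  expect_equal(d, 3.5, tolerance = 1e-6)
})

test_that("every structops operator recovers its fixture's ground truth", {
  h <- make_structure("ideal_helix", length = 15)
  gt <- attr(h, "ground_truth")
  ss <- assign_secondary_structure(h)
  expect_true(all(ss$ss[gt$helical_core] == "H"))
  hb <- detect_hbonds(h)
  expect_equal(sum(hb$type == "bb-bb"), gt$expected_bb_hbonds)

  hp <- make_structure("beta_hairpin")
  gt <- attr(hp, "ground_truth")
  ss <- assign_secondary_structure(hp)
  expect_true(all(ss$ss[ss$resno %in% gt$strand_core] == "E"))

  cm <- synthetic_chemokine_model()
  gt <- attr(cm, "ground_truth")
  ds <- detect_disulfides(cm)
  expect_setequal(paste(ds$resno1, ds$resno2),
                  vapply(gt$disulfides, paste, "", collapse = " "))
  ss <- ss_segments(assign_secondary_structure(cm), "E")
  ss <- ss[ss$end - ss$start + 1 >= 2, ]
  expect_equal(nrow(ss), 3)
})

test_that("two-chain complex fixture has exactly the constructed contact", {
  cx <- make_structure("two_chain_complex", distance = 3.5)
  ic <- interface_contacts(cx)
  sb <- ic[ic$type == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(c(sb$pos_a, sb$pos_b), c(3L, 3L))
  far <- make_structure("two_chain_complex", apart = TRUE)
  expect_equal(nrow(interface_contacts(far)), 0)
})

test_that("variant cohorts resolve to their preset consensus calls", {
  cohort <- make_variant_cohort(100, seed = 3)
  expect_equal(nrow(cohort$variants), 100)
  expect_false(any(duplicated(cohort$variants$variant)))
  expect_true(all(cohort$variants$wt != cohort$variants$mut))
  res <- consensus_stability(cohort$predictors)
  expect_equal(as.character(res$call), cohort$truth$true_call)
  # fractions approximately honored
  expect_equal(sum(cohort$truth$true_call == "less_stable"), 50, tolerance = 2)
})

test_that("cohort generation respects edge cases", {
  empty <- make_variant_cohort(0, seed = 1)
  expect_equal(nrow(empty$variants), 0)
  expect_equal(nrow(empty$predictors), 0)
  expect_error(make_variant_cohort(10000, seed = 1, sequence = "ACDEF"),
               "exceeds")
  a <- make_variant_cohort(20, seed = 9)
  b <- make_variant_cohort(20, seed = 9)
  expect_identical(a$predictors, b$predictors)
})

test_that("fixture PDB files round-trip with their ground truth intact", {
  s <- make_structure("disulfide_pair", distance = 2.05)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb(s, tmp)
  back <- read_pdb(tmp)
  ds <- detect_disulfides(back)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$distance, 2.05, tolerance = 1e-2)
})
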