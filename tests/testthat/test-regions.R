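# hand-built secondary-structure table: signal 1-23, strands at 30-34,
# 40-44, 50-54, helix 60-70, tail 71-75
fake_ss <- function() {
  ss <- rep("C", 75)
  ss[30:34] <- "E"; ss[40:44] <- "E"; ss[50:54] <- "E"; ss[60:70] <- "H"
  tibble::tibble(chain = "A", resno = 1:75, aa = "A", ss = ss)
}

test_that("regions partition the sequence with ordered loop names", {
  ann <- derive_regions(fake_ss())
  expect_s3_class(ann, "region_annotation")
  expect_equal(region_of(1, ann), "signal_peptide")
  expect_equal(region_of(23, ann), "signal_peptide")
  expect_equal(region_of(25, ann), "N_loop")
  expect_equal(region_of(32, ann), "beta1")
  expect_equal(region_of(37, ann), "thirties_loop")
  expect_equal(region_of(47, ann), "forties_loop")
  expect_equal(region_of(57, ann), "fifties_loop")
  expect_equal(region_of(65, ann), "C_helix")
  expect_equal(region_of(73, ann), "other")
  # partition: covers everything exactly once
  cov <- unlist(Map(seq, ann$start, ann$end))
  expect_setequal(cov, 1:75)
  expect_false(any(duplicated(cov)))
})

test_that("wrong strand counts warn but still emit regions", {
  ss <- fake_ss()
  ss$ss[40:44] <- "C" # only two strands left
  expect_warning(ann <- derive_regions(ss), "found 2")
  cov <- unlist(Map(seq, ann$start, ann$end))
  expect_setequal(cov, 1:75)
})

test_that("interval overrides replace derived boundaries", {
  ann <- derive_regions(fake_ss(),
                        overrides = list(signal_peptide = c(1, 20),
                                         N_loop = c(21, 29)))
  expect_equal(region_of(22, ann), "N_loop")
  expect_equal(region_of(20, ann), "signal_peptide")
  # a broken override (coverage gap) errors
  expect_error(derive_regions(fake_ss(),
                              overrides = list(signal_peptide = c(5, 23))),
               "cover")
})

test_that("synthetic model regions place the worked-example residues", {
  cm <- chemokine_model()
  ann <- derive_regions(assign_secondary_structure(cm))
  expect_equal(region_of(78, ann), "fifties_loop")
  expect_equal(region_of(80, ann), "C_helix")
  expect_equal(region_of(57, ann), "thirties_loop")
  expect_equal(region_of(1, ann), "signal_peptide")
})

make_fake_reports <- function(flags) {
  n <- nrow(flags)
  tibble::tibble(
    variant = sprintf("A%dV", flags$position),
    position = flags$position, wt = "A", mut = "V",
    ss_changed = flags$ss, burial_changed = flags$burial,
    delta_rsa = 0,
    hbonds_gained = lapply(flags$hb_gain, function(k) if (k) "1-2" else character()),
    hbonds_lost = lapply(flags$hb_loss, function(k) if (k) "3-4" else character()),
    salt_bridges_gained = lapply(flags$sb_gain, function(k) if (k) "5-6" else character()),
    salt_bridges_lost = lapply(rep(FALSE, n), function(k) character()),
    hydrophobic_gained = lapply(rep(FALSE, n), function(k) character()),
    hydrophobic_lost = lapply(rep(FALSE, n), function(k) character()),
    disulfide_lost = flags$ds_lost, cys_introduced = FALSE,
    any_structural_change = flags$ss | flags$burial | flags$hb_gain |
      flags$hb_loss | flags$sb_gain | flags$ds_lost,
    call = factor(flags$call,
                  levels = c("less_stable", "more_stable", "uncertain")),
    conserved_flag = flags$conserved
  )
}

test_that("cohort summary counts match a hand tally", {
  flags <- tibble::tibble(
    position = c(2, 10, 25, 31, 41, 52, 61, 65, 72, 74),
    ss = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    burial = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hb_gain = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hb_loss = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    sb_gain = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    ds_lost = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    call = c("less_stable", "less_stable", "uncertain", "more_stable",
             "less_stable", "uncertain", "uncertain", "less_stable",
             "less_stable", "uncertain"),
    conserved = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                  TRUE, FALSE)
  )
  reports <- make_fake_reports(flags)
  ann <- derive_regions(fake_ss())
  cs <- cohort_summary(reports, ann)
  # hand tally:
  expect_equal(cs$counts$n_variants, 10)
  expect_equal(cs$counts$n_any_structural_change, 8)
  expect_equal(cs$counts$n_ss_change, 1)
  expect_equal(cs$counts$n_accessibility_change, 2)
  expect_equal(cs$counts$n_hbond_change, 4)
  expect_equal(cs$counts$n_salt_bridge_change, 1)
  expect_equal(cs$counts$n_salt_bridge_gain, 1)
  expect_equal(cs$counts$n_disulfide_lost, 1)
  expect_equal(cs$counts$n_less_stable, 5)
  # less-stable & (hbond/salt-bridge/disulfide loss): positions 41, 65
  expect_equal(cs$counts$n_stability_and_interaction_loss, 2)
  # less-stable with no structural change at all: position 72 only
  expect_equal(cs$counts$n_stability_only, 1)
  expect_equal(cs$counts$n_conserved_with_change, 3)
  expect_equal(cs$counts$n_conserved_without_change, 1)
  # per-region counts sum to the cohort size (partition property)
  expect_equal(sum(cs$per_region$n_variants), 10)
})

test_that("cohort summary is invariant to report order", {
  flags <- tibble::tibble(
    position = c(5, 30, 62), ss = c(TRUE, FALSE, FALSE),
    burial = c(FALSE, TRUE, FALSE), hb_gain = c(FALSE, FALSE, TRUE),
    hb_loss = FALSE, sb_gain = FALSE, ds_lost = FALSE,
    call = c("uncertain", "less_stable", "more_stable"),
    conserved = c(TRUE, FALSE, FALSE)
  )
  reports <- make_fake_reports(flags)
  ann <- derive_regions(fake_ss())
  a <- cohort_summary(reports, ann)
  b <- cohort_summary(reports[c(3, 1, 2), ], ann)
  expect_equal(a$counts, b$counts)
})

test_that("a paper-sized cohort distributes over regions and sums back", {
  cm <- chemokine_model()
  ann <- derive_regions(assign_secondary_structure(cm))
  seqv <- strsplit(structure_sequence(cm), "")[[1]]
  # per-region variant totals of the kind a chemokine variant census
  # reports: 25 signal, 10 N-loop, 8 30s, 2 40s, 6 50s, 20 strands,
  # 13 helix, 21 elsewhere = 105
  want <- c(signal_peptide = 25, N_loop = 10, thirties_loop = 8,
            forties_loop = 2, fifties_loop = 6, beta = 20, C_helix = 13,
            other = 21)
  pick_positions <- function(region, n) {
    rows <- ann[ann$region == region, ]
    pos <- unlist(Map(seq, rows$start, rows$end))
    rep(pos, length.out = n)
  }
  pos <- c(pick_positions("signal_peptide", 25), pick_positions("N_loop", 10),
           pick_positions("thirties_loop", 8), pick_positions("forties_loop", 2),
           pick_positions("fifties_loop", 6),
           rep(unlist(Map(seq, ann$start[grepl("beta", ann$region)],
                          ann$end[grepl("beta", ann$region)])),
               length.out = 20),
           pick_positions("C_helix", 13), pick_positions("other", 21))
  muts <- vapply(seq_along(pos), function(k) {
    cand <- setdiff(c("A", "V", "L", "S", "T", "G", "M", "F", "Y", "W", "R",
                      "N", "D", "Q", "E", "H", "I", "K", "P", "C"),
                    seqv[pos[k]])
    cand[1 + (k %% 17)]
  }, character(1))
  variants <- tibble::tibble(variant = sprintf("%s%d%s", seqv[pos], pos, muts),
                             position = pos, wt = seqv[pos], mut = muts)
  expect_equal(nrow(variants), 105)
  reg <- region_of(variants$position, ann)
  counts <- table(reg)
  expect_equal(sum(counts), 105)
  expect_equal(unname(counts["signal_peptide"]), 25)
  expect_equal(unname(counts["C_helix"]), 13)
  expect_equal(unname(sum(counts[c("beta1", "beta2", "beta3")])), 20)
})
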