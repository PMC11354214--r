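#' Detect hydrogen bonds by geometric criteria
#'
#' Polar hydrogens are rebuilt geometrically on donors (amide H in the
#' peptide plane; sp2 side-chain H in idealized planar geometry; rotatable
#' hydroxyl/ammonium/thiol H oriented toward the candidate acceptor). A bond
#' is reported when donor-acceptor distance <= `d_da_max`, H-acceptor
#' distance <= `d_ha_max` and the donor-H-acceptor angle >= `angle_min`.
#' Backbone-backbone, backbone-sidechain and sidechain-sidechain bonds are
#' all reported.
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param d_da_max donor-acceptor distance cutoff, Angstrom.
#' @param d_ha_max hydrogen-acceptor distance cutoff, Angstrom.
#' @param angle_min minimal donor-H-acceptor angle, degrees.
#' @return tibble, one row per bond: donor/acceptor chain, residue, atom,
#'   `distance` (D-A), `d_ha`, `angle`, and `type` (`bb-bb`, `bb-sc`,
#'   `sc-bb`, `sc-sc`).
#' @export
detect_hbonds <- function(s, d_da_max = 3.9, d_ha_max = 2.5, angle_min = 90) {
  res <- .residue_backbones(s)
  bbH <- .amide_hydrogens(res, "bisector")
  scH <- .sidechain_donor_hydrogens(s)

  donors <- list(); acceptors <- list()
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!is.null(r$N) && all(is.finite(bbH[i, ]))) {
      donors[[length(donors) + 1]] <- list(chain = r$chain, resno = r$resno,
        atom = "N", D = r$N, H = matrix(bbH[i, ], 1, 3), bb = TRUE)
    }
    if (!is.null(r$O)) {
      acceptors[[length(acceptors) + 1]] <- list(chain = r$chain, resno = r$resno,
        atom = "O", A = r$O, bb = TRUE)
    }
    for (d in .sc_donors[[r$aa]] %||% list()) {
      D <- .atom_xyz(s, r$resno, d$atom, r$chain)
      if (is.null(D)) next
      H <- if (d$rot) NULL else scH[[paste(r$chain, r$resno, d$atom, sep = "|")]]
      if (!d$rot && is.null(H)) next
      donors[[length(donors) + 1]] <- list(chain = r$chain, resno = r$resno,
        atom = d$atom, D = D, H = H, bb = FALSE)
    }
    for (aat in .sc_acceptors[[r$aa]] %||% character()) {
      A <- .atom_xyz(s, r$resno, aat, r$chain)
      if (is.null(A)) next
      acceptors[[length(acceptors) + 1]] <- list(chain = r$chain, resno = r$resno,
        atom = aat, A = A, bb = FALSE)
    }
  }
  ox <- which(s$atom == "OXT")
  for (i in ox) {
    acceptors[[length(acceptors) + 1]] <- list(chain = s$chain[i], resno = s$resno[i],
      atom = "OXT", A = c(s$x[i], s$y[i], s$z[i]), bb = TRUE)
  }
  if (length(donors) == 0 || length(acceptors) == 0) return(.empty_hbonds())

  Amat <- do.call(rbind, lapply(acceptors, `[[`, "A"))
  rows <- list()
  for (d in donors) {
    d2 <- .cross_dist2(matrix(d$D, 1, 3), Amat)[1, ]
    for (j in which(d2 <= d_da_max^2)) {
      a <- acceptors[[j]]
      if (a$chain == d$chain && a$resno == d$resno) next
      # exclude the covalently adjacent backbone N(i) ... O(i-1) pair
      if (d$bb && a$bb && a$chain == d$chain && a$resno == d$resno - 1) next
      dda <- sqrt(d2[j])
      H <- if (is.null(d$H)) matrix(d$D + .unit(a$A - d$D), 1, 3) else d$H
      ok <- FALSE; best_ha <- Inf; best_ang <- NA_real_
      for (k in seq_len(nrow(H))) {
        h <- H[k, ]
        dha <- .vnorm(a$A - h)
        ang <- .angle3(d$D, h, a$A)
        if (dha <= d_ha_max && ang >= angle_min && dha < best_ha) {
          ok <- TRUE; best_ha <- dha; best_ang <- ang
        }
      }
      if (!ok) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        donor_chain = d$chain, donor_resno = d$resno, donor_atom = d$atom,
        acceptor_chain = a$chain, acceptor_resno = a$resno, acceptor_atom = a$atom,
        distance = dda, d_ha = best_ha, angle = best_ang,
        type = paste0(if (d$bb) "bb" else "sc", "-", if (a$bb) "bb" else "sc")
      )
    }
  }
  if (length(rows) == 0) return(.empty_hbonds())
  dplyr::arrange(dplyr::bind_rows(rows), .data$donor_resno, .data$acceptor_resno)
}

.empty_hbonds <- function() {
  tibble::tibble(donor_chain = character(), donor_resno = integer(),
                 donor_atom = character(), acceptor_chain = character(),
                 acceptor_resno = integer(), acceptor_atom = character(),
                 distance = numeric(), d_ha = numeric(), angle = numeric(),
                 type = character())
}

#' Detect salt bridges
#'
#' A bridge is reported when any basic-group nitrogen (Lys NZ; Arg
#' NE/NH1/NH2; His ND1/NE2 -- histidine counts as positively charged) lies
#' within `cutoff` of any acidic-group oxygen (Asp OD1/OD2; Glu OE1/OE2).
#' One row per residue pair, carrying the closest atom pair.
#'
#' @inheritParams detect_hbonds
#' @param cutoff N-O distance cutoff, Angstrom (default 4.0).
#' @return tibble: `basic_chain`, `basic_resno`, `basic_atom`,
#'   `acidic_chain`, `acidic_resno`, `acidic_atom`, `distance`.
#' @export
detect_salt_bridges <- function(s, cutoff = 4.0) {
  pick <- function(defs) {
    idx <- which(purrr::map2_lgl(s$aa, s$atom, function(a, at) {
      at %in% (defs[[a]] %||% character())
    }))
    s[idx, , drop = FALSE]
  }
  bas <- pick(.basic_atoms); aci <- pick(.acidic_atoms)
  empty <- tibble::tibble(basic_chain = character(), basic_resno = integer(),
                          basic_atom = character(), acidic_chain = character(),
                          acidic_resno = integer(), acidic_atom = character(),
                          distance = numeric())
  if (nrow(bas) == 0 || nrow(aci) == 0) return(empty)
  d2 <- .cross_dist2(.coords(bas), .coords(aci))
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  out <- tibble::tibble(
    basic_chain = bas$chain[hits[, 1]], basic_resno = bas$resno[hits[, 1]],
    basic_atom = bas$atom[hits[, 1]],
    acidic_chain = aci$chain[hits[, 2]], acidic_resno = aci$resno[hits[, 2]],
    acidic_atom = aci$atom[hits[, 2]],
    distance = sqrt(d2[hits])
  )
  out |>
    dplyr::group_by(.data$basic_chain, .data$basic_resno,
                    .data$acidic_chain, .data$acidic_resno) |>
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$basic_resno, .data$acidic_resno)
}

#' Detect disulfide bonds
#'
#' Cys SG-SG pairs within `cutoff`, each cysteine in at most one pair
#' (closest-distance greedy matching). Cysteines lacking an SG atom are
#' skipped with a warning.
#'
#' @inheritParams detect_hbonds
#' @param cutoff SG-SG distance cutoff, Angstrom (default 2.5).
#' @return tibble: `resno1`, `resno2` (resno1 < resno2), `chain1`, `chain2`,
#'   `distance`.
#' @export
detect_disulfides <- function(s, cutoff = 2.5) {
  empty <- tibble::tibble(resno1 = integer(), resno2 = integer(),
                          chain1 = character(), chain2 = character(),
                          distance = numeric())
  res <- residue_table(s)
  cys <- res[res$aa == "C", , drop = FALSE]
  if (nrow(cys) == 0) return(empty)
  sg <- s[s$aa == "C" & s$atom == "SG", , drop = FALSE]
  no_sg <- dplyr::anti_join(cys, sg, by = c("chain", "resno"))
  if (nrow(no_sg) > 0) {
    warning("Cys without SG skipped: ", paste(no_sg$resno, collapse = ", "))
  }
  if (nrow(sg) < 2) return(empty)
  d <- sqrt(.cross_dist2(.coords(sg), .coords(sg)))
  cand <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  ord <- order(d[cand])
  used <- logical(nrow(sg))
  rows <- list()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    r1 <- sg$resno[i]; r2 <- sg$resno[j]
    sw <- r1 > r2
    rows[[length(rows) + 1]] <- tibble::tibble(
      resno1 = if (sw) r2 else r1, resno2 = if (sw) r1 else r2,
      chain1 = if (sw) sg$chain[j] else sg$chain[i],
      chain2 = if (sw) sg$chain[i] else sg$chain[j],
      distance = d[i, j]
    )
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$resno1)
}

#' Detect hydrophobic contacts
#'
#' A contact is reported when any apolar side-chain carbon (carbon not
#' covalently bonded to N or O) of one residue lies within `cutoff` of an
#' apolar side-chain carbon of another residue. One row per residue pair
#' with the closest atom pair.
#'
#' @inheritParams detect_hbonds
#' @param cutoff C-C distance cutoff, Angstrom (default 3.9).
#' @return tibble: `resno1`, `resno2` (resno1 < resno2 within chain order),
#'   `chain1`, `chain2`, `atom1`, `atom2`, `distance`.
#' @export
detect_hydrophobic_contacts <- function(s, cutoff = 3.9) {
  empty <- tibble::tibble(resno1 = integer(), resno2 = integer(),
                          chain1 = character(), chain2 = character(),
                          atom1 = character(), atom2 = character(),
                          distance = numeric())
  idx <- which(purrr::map2_lgl(s$aa, s$atom, function(a, at) {
    at %in% (.apolar_carbons[[a]] %||% character())
  }))
  ap <- s[idx, , drop = FALSE]
  if (nrow(ap) < 2) return(empty)
  d <- sqrt(.cross_dist2(.coords(ap), .coords(ap)))
  same_res <- outer(paste(ap$chain, ap$resno), paste(ap$chain, ap$resno), "==")
  cand <- which(upper.tri(d) & d <= cutoff & !same_res, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  out <- tibble::tibble(
    resno1 = ap$resno[cand[, 1]], resno2 = ap$resno[cand[, 2]],
    chain1 = ap$chain[cand[, 1]], chain2 = ap$chain[cand[, 2]],
    atom1 = ap$atom[cand[, 1]], atom2 = ap$atom[cand[, 2]],
    distance = d[cand]
  )
  sw <- out$resno1 > out$resno2
  out[sw, c("resno1", "resno2", "chain1", "chain2", "atom1", "atom2")] <-
    out[sw, c("resno2", "resno1", "chain2", "chain1", "atom2", "atom1")]
  out |>
    dplyr::group_by(.data$chain1, .data$resno1, .data$chain2, .data$resno2) |>
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$resno1, .data$resno2)
}
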