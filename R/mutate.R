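# Rigid-backbone point-mutant construction: the side chain at the variant
# position is rebuilt from idealized internal coordinates using a compact
# backbone-independent rotamer library, choosing the rotamer with the lowest
# steric clash score. Backbone atoms are never touched.

# Build side-chain heavy atoms for residue type `aa3` given backbone N, CA,
# C positions and a chi-angle vector (degrees; padded with library values
# when short). Raw variant returns plain vectors/matrix (hot path for
# rotamer searches); the tibble wrapper is the public shape.
.build_side_chain_raw <- function(N, CA, C, aa3, chi = numeric()) {
  tmpl <- .sidechain_templates[[aa3]]
  n <- length(tmpl)
  if (n == 0) {
    return(list(atom = character(), element = character(),
                xyz = matrix(numeric(), 0, 3)))
  }
  pos <- list(N = N, CA = CA, C = C)
  xyz <- matrix(NA_real_, n, 3)
  atoms <- character(n); els <- character(n)
  for (k in seq_len(n)) {
    t <- tmpl[[k]]
    tor <- if (is.na(t$chi)) t$tor else {
      chi_k <- if (length(chi) >= t$chi) chi[t$chi] else 180
      chi_k + t$tor
    }
    p <- .nerf(pos[[t$A]], pos[[t$B]], pos[[t$C]], t$b, t$ang, tor)
    pos[[t$atom]] <- p
    xyz[k, ] <- p
    atoms[k] <- t$atom; els[k] <- t$el
  }
  list(atom = atoms, element = els, xyz = xyz)
}

.build_side_chain <- function(N, CA, C, aa3, chi = numeric()) {
  raw <- .build_side_chain_raw(N, CA, C, aa3, chi)
  tibble::tibble(atom = raw$atom, element = raw$element,
                 x = raw$xyz[, 1], y = raw$xyz[, 2], z = raw$xyz[, 3])
}

# Bonded-pair exclusions (1-2 and 1-3) between the rebuilt side chain and
# the rest of the residue: CB-CA (1-2), CB-N/C and gamma-CA (1-3).
.clash_exclusions <- function(aa3) {
  tmpl <- .sidechain_templates[[aa3]]
  if (is.null(tmpl)) return(list())
  gamma <- vapply(Filter(function(t) t$C == "CB", tmpl), `[[`, character(1), "atom")
  c(list(c("CB", "CA"), c("CB", "N"), c("CB", "C")),
    lapply(gamma, function(g) c(g, "CA")))
}

#' Steric clash score of a residue's side chain
#'
#' Sum over atom pairs (side chain at `position` against all other atoms,
#' excluding pairs within two covalent bonds) of
#' `max(0, r_vdw_sum - d)^2`, with the package van der Waals radii.
#' Zero means no sphere overlap.
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param position residue number (precursor numbering).
#' @param chain chain id (default first).
#' @return non-negative numeric scalar.
#' @export
clash_score <- function(s, position, chain = NULL) {
  if (is.null(chain)) chain <- s$chain[1]
  own <- s$chain == chain & s$resno == position
  sc <- own & !s$atom %in% c(.backbone_atoms, "OXT")
  if (!any(sc)) return(0)
  rest <- !sc
  aa3 <- aa_1to3(s$aa[which(own)[1]])
  excl <- .clash_exclusions(aa3)
  rad <- function(el) {
    r <- .vdw_radii[toupper(el)]
    ifelse(is.na(r), .vdw_default, r)
  }
  A <- s[sc, , drop = FALSE]; B <- s[rest, , drop = FALSE]
  d <- sqrt(.cross_dist2(.coords(A), .coords(B)))
  rsum <- outer(rad(A$element), rad(B$element), "+")
  pen <- pmax(rsum - d, 0)^2
  own_b <- which(B$chain == chain & B$resno == position)
  for (e in excl) {
    i <- which(A$atom == e[1]); j <- own_b[B$atom[own_b] == e[2]]
    if (length(i) && length(j)) pen[i, j] <- 0
  }
  sum(pen)
}

#' Build a point-mutant structure
#'
#' Replaces the side chain at the variant position with the target residue
#' type rebuilt from idealized geometry, with a rigid backbone: N, CA, C, O
#' (and OXT) of every residue are bitwise-unchanged. The rotamer is chosen
#' to minimize [clash_score()]; ties break by rotamer prior weight, then
#' library order. Mutation to Gly removes the side chain. If no clash-free
#' rotamer exists the lowest-clash one is kept and the result is flagged
#' `strained` (attribute). The construction is deterministic; `seed` only
#' matters for the optional stochastic chi-jitter mode.
#'
#' @param s wild-type [protein_structure][new_protein_structure].
#' @param variant one-row variant specification (tibble with `position`,
#'   `wt`, `mut`, e.g. one row of [parse_variant()]), or a string like
#'   `"K78E"`.
#' @param seed integer seed for the jitter mode.
#' @param chi_jitter_sd standard deviation (degrees) of Gaussian chi jitter;
#'   0 (default) disables it.
#' @param chain chain id (default first).
#' @return the mutant `protein_structure`; attributes `variant` and
#'   `strained` record provenance.
#' @export
build_mutant <- function(s, variant, seed = 1L, chi_jitter_sd = 0,
                         chain = NULL) {
  if (is.character(variant)) variant <- parse_variant(variant)
  v <- variant[1, ]
  if (is.null(chain)) chain <- s$chain[1]
  own <- s$chain == chain & s$resno == v$position
  if (!any(own)) stop("position ", v$position, " not in structure")
  wt_here <- s$aa[which(own)[1]]
  if (!identical(wt_here, v$wt)) {
    stop("wild-type mismatch at position ", v$position, ": structure has ",
         wt_here, ", variant says ", v$wt)
  }
  if (identical(v$wt, v$mut)) stop("wild-type and mutant residue are identical")

  keep <- !(own & !s$atom %in% c(.backbone_atoms, "OXT"))
  base <- tibble::as_tibble(s)[keep, , drop = FALSE]
  base$aa[base$chain == chain & base$resno == v$position] <- v$mut

  gN <- .atom_xyz(s, v$position, "N", chain)
  gCA <- .atom_xyz(s, v$position, "CA", chain)
  gC <- .atom_xyz(s, v$position, "C", chain)
  if (is.null(gN) || is.null(gCA) || is.null(gC)) {
    stop("incomplete backbone at position ", v$position)
  }

  aa3 <- aa_1to3(v$mut)
  rotamers <- .rotamer_library[[aa3]]
  strained <- FALSE
  new_sc <- NULL
  if (!identical(v$mut, "G")) {
    if (chi_jitter_sd > 0) set.seed(seed)
    cand <- purrr::map(rotamers, function(r) {
      chi <- r$chi
      if (chi_jitter_sd > 0 && length(chi) > 0) {
        chi <- chi + stats::rnorm(length(chi), 0, chi_jitter_sd)
      }
      .build_side_chain(gN, gCA, gC, aa3, chi)
    })
    scores <- purrr::map_dbl(cand, function(sc_tbl) {
      trial <- .assemble_mutant(base, sc_tbl, chain, v$position, s)
      clash_score(trial, v$position, chain)
    })
    w <- purrr::map_dbl(rotamers, "w")
    ord <- order(scores, -w, seq_along(scores))
    best <- ord[1]
    strained <- scores[best] > 0
    new_sc <- cand[[best]]
  }
  out <- .assemble_mutant(base, new_sc, chain, v$position, s)
  attr(out, "variant") <- sprintf("%s%d%s", v$wt, v$position, v$mut)
  attr(out, "strained") <- strained
  out
}

# Insert rebuilt side-chain rows after the mutated residue's backbone rows.
.assemble_mutant <- function(base, sc_tbl, chain, position, template) {
  if (!is.null(sc_tbl) && nrow(sc_tbl) > 0) {
    sc_rows <- tibble::tibble(
      chain = chain, resno = as.integer(position),
      aa = base$aa[base$chain == chain & base$resno == position][1],
      atom = sc_tbl$atom, element = sc_tbl$element,
      x = sc_tbl$x, y = sc_tbl$y, z = sc_tbl$z, occ = 1
    )
    last_bb <- max(which(base$chain == chain & base$resno == position))
    base <- dplyr::bind_rows(
      base[seq_len(last_bb), , drop = FALSE],
      sc_rows,
      if (last_bb < nrow(base)) base[(last_bb + 1):nrow(base), , drop = FALSE]
    )
  }
  .reclass_structure(base, template)
}

#' Write a mutant model with provenance REMARKs
#'
#' @param s mutant structure from [build_mutant()].
#' @param path output PDB path.
#' @param seed seed recorded in the header.
#' @export
write_mutant_pdb <- function(s, path, seed = 1L) {
  write_pdb(s, path, remarks = c(
    sprintf("VARIANT %s", attr(s, "variant") %||% "?"),
    sprintf("SEED %d  ROTAMER-LIBRARY compact-1.0  STRAINED %s",
            as.integer(seed), isTRUE(attr(s, "strained")))
  ))
}
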