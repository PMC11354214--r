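#' Backbone phi/psi dihedrals with a coarse Ramachandran label
#'
#' `phi(i)` = C(i-1)-N(i)-CA(i)-C(i), `psi(i)` = N(i)-CA(i)-C(i)-N(i+1), in
#' degrees in (-180, 180]; undefined at chain termini and across breaks.
#' Labels come from a documented rectangle map over the alpha, beta and
#' left-handed-alpha basins: inside a rectangle is `favored`, within 20
#' degrees of one `allowed`, else `outlier`; residues with an undefined
#' angle are labelled `NA`.
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param chain optional chain id.
#' @return tibble: `chain`, `resno`, `aa`, `phi`, `psi`, `rama`.
#' @export
compute_phi_psi <- function(s, chain = NULL) {
  res <- .residue_backbones(s, chain = chain)
  n <- length(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- res[[i]]
    if (i > 1 && r$linked_prev) {
      p <- res[[i - 1]]
      if (!is.null(p$C) && !is.null(r$N) && !is.null(r$CA) && !is.null(r$C)) {
        phi[i] <- .dihedral4(p$C, r$N, r$CA, r$C)
      }
    }
    if (i < n && res[[i + 1]]$linked_prev) {
      nx <- res[[i + 1]]
      if (!is.null(r$N) && !is.null(r$CA) && !is.null(r$C) && !is.null(nx$N)) {
        psi[i] <- .dihedral4(r$N, r$CA, r$C, nx$N)
      }
    }
  }
  tibble::tibble(
    chain = purrr::map_chr(res, "chain"),
    resno = purrr::map_int(res, function(r) as.integer(r$resno)),
    aa = purrr::map_chr(res, "aa"),
    phi = phi, psi = psi,
    rama = rama_label(phi, psi)
  )
}

#' @rdname compute_phi_psi
#' @param phi,psi numeric vectors of dihedrals, degrees.
#' @export
rama_label <- function(phi, psi) {
  inside <- function(box, pad = 0) {
    phi >= box["phi_min"] - pad & phi <= box["phi_max"] + pad &
      psi >= box["psi_min"] - pad & psi <= box["psi_max"] + pad
  }
  fav <- Reduce(`|`, lapply(.rama_boxes, inside, pad = 0))
  alw <- Reduce(`|`, lapply(.rama_boxes, inside, pad = 20))
  out <- ifelse(fav, "favored", ifelse(alw, "allowed", "outlier"))
  out[is.na(phi) | is.na(psi)] <- NA_character_
  unname(out)
}

#' Optimal-superposition CA RMSD (Kabsch)
#'
#' Least-squares superposes the CA atoms of the selected residues and
#' returns the RMSD. The selection must pick equal numbers of CA atoms from
#' both structures; by default the intersection of residue numbers is used.
#'
#' @param a,b [protein_structure][new_protein_structure] objects.
#' @param selection residue numbers to superpose on (default: common
#'   numbers of `a` and `b`).
#' @return RMSD in Angstrom (numeric scalar), with the rotation matrix in
#'   attribute `rotation`.
#' @export
superpose_rmsd <- function(a, b, selection = NULL) {
  ca_a <- a[a$atom == "CA", , drop = FALSE]
  ca_b <- b[b$atom == "CA", , drop = FALSE]
  if (is.null(selection)) selection <- intersect(ca_a$resno, ca_b$resno)
  ca_a <- ca_a[match(selection, ca_a$resno), , drop = FALSE]
  ca_b <- ca_b[match(selection, ca_b$resno), , drop = FALSE]
  if (anyNA(ca_a$resno) || anyNA(ca_b$resno)) {
    stop("selection contains residues missing a CA in one structure")
  }
  if (nrow(ca_a) != nrow(ca_b) || nrow(ca_a) < 3) {
    stop("selections of equal length >= 3 required")
  }
  fit <- .kabsch(.coords(ca_a), .coords(ca_b))
  out <- fit$rmsd
  attr(out, "rotation") <- fit$R
  out
}
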