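#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` deterministic golden-spiral points on each atom's
#' solvent-expanded sphere (van der Waals radius + probe) and counts points
#' not buried inside any neighbouring sphere. Radii are the Chothia set
#' (C 1.87, N 1.65, O 1.40, S 1.85 A); unknown elements fall back to 1.8 A
#' with a warning. The computation is seed-free and deterministic for a
#' given `n_points`.
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @param level `"residue"` (default) or `"atom"`.
#' @return At residue level a tibble `chain`, `resno`, `aa`, `sasa`
#'   (Angstrom^2), with the atom-level table in attribute `atom_sasa`;
#'   at atom level the full atom table with a `sasa` column.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960,
                         level = c("residue", "atom")) {
  level <- match.arg(level)
  el <- toupper(s$element)
  unknown <- !el %in% names(.vdw_radii)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using radius ", .vdw_default, " A")
  }
  radii <- ifelse(unknown, .vdw_default, .vdw_radii[el])
  xyz <- .coords(s)
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  rexp <- radii + probe
  d2 <- .cross_dist2(xyz, xyz)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rexp[i] + rexp)^2 & seq_len(n) != i)
    p <- sweep(pts * rexp[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      free <- n_points
    } else {
      pd2 <- .cross_dist2(p, xyz[nb, , drop = FALSE])
      buried <- rowSums(pd2 < matrix(rexp[nb]^2, n_points, length(nb),
                                     byrow = TRUE)) > 0
      free <- sum(!buried)
    }
    sasa[i] <- 4 * pi * rexp[i]^2 * free / n_points
  }
  atom_tbl <- tibble::as_tibble(s)
  atom_tbl$sasa <- sasa
  if (level == "atom") return(atom_tbl)
  res <- atom_tbl |>
    dplyr::group_by(.data$chain, .data$resno, .data$aa) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno)
  attr(res, "atom_sasa") <- atom_tbl
  attr(res, "params") <- list(probe = probe, n_points = n_points)
  res
}

#' Relative solvent accessibility and burial class
#'
#' Converts per-residue SASA into percent of the residue-type maximum
#' (theoretical Gly-X-Gly reference values) and classifies burial:
#' `buried` below `buried_max`, `partially_exposed` up to `exposed_min`,
#' `exposed` above. A value exactly on a boundary goes to the more exposed
#' class. RSA may exceed 100 for extended conformations.
#'
#' @param sasa_tbl per-residue tibble from [compute_sasa()] (columns
#'   `resno`, `aa`, `sasa`).
#' @param buried_max buried/partially-exposed boundary, percent RSA.
#' @param exposed_min partially-exposed/exposed boundary, percent RSA.
#' @return the input tibble with `rsa` (percent) and `burial_class` added.
#' @export
relative_accessibility <- function(sasa_tbl, buried_max = 20, exposed_min = 50) {
  stopifnot(all(c("aa", "sasa") %in% names(sasa_tbl)))
  rsa <- 100 * sasa_tbl$sasa / .max_sasa[sasa_tbl$aa]
  sasa_tbl$rsa <- unname(rsa)
  sasa_tbl$burial_class <- burial_class(rsa, buried_max, exposed_min)
  sasa_tbl
}

#' @rdname relative_accessibility
#' @param rsa numeric vector of RSA percentages.
#' @export
burial_class <- function(rsa, buried_max = 20, exposed_min = 50) {
  cls <- ifelse(rsa < buried_max, "buried",
         ifelse(rsa < exposed_min, "partially_exposed", "exposed"))
  factor(cls, levels = c("buried", "partially_exposed", "exposed"))
}
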