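#' Atom-table protein structures
#'
#' A `protein_structure` is a tibble of heavy atoms (one row per atom) with
#' columns `chain`, `resno` (precursor numbering), `aa` (one-letter code),
#' `atom` (PDB atom name), `element`, `x`, `y`, `z` (Angstrom) and `occ`,
#' carrying the numbering offset and provenance as attributes. All geometry
#' operators in the package take this table as their first argument, so
#' calls chain naturally with the pipe.
#'
#' @param atoms data frame with the columns above.
#' @param offset integer added to file numbering to reach precursor
#'   numbering (already applied; stored for provenance).
#' @param source free-text provenance string.
#' @return a `protein_structure` tibble.
#' @export
new_protein_structure <- function(atoms, offset = 0L, source = "") {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("chain", "resno", "aa", "atom", "element", "x", "y", "z", "occ")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  atoms$resno <- as.integer(atoms$resno)
  s <- structure(atoms,
    class = c("protein_structure", class(tibble::tibble())),
    offset = as.integer(offset), source = source
  )
  validate_structure(s)
  s
}

#' @rdname new_protein_structure
#' @param s object to validate.
#' @export
validate_structure <- function(s) {
  if (!all(is.finite(c(s$x, s$y, s$z)))) stop("non-finite coordinates")
  for (ch in unique(s$chain)) {
    rn <- unique(s$resno[s$chain == ch])
    if (is.unsorted(rn, strictly = TRUE)) {
      stop("residue numbers not strictly increasing in chain ", ch)
    }
  }
  bad <- !s$aa %in% names(.aa3)
  if (any(bad)) {
    stop("non-standard residue code(s): ", paste(unique(s$aa[bad]), collapse = ", "))
  }
  res <- residue_table(s)
  no_ca <- res$resno[!res$has_ca]
  if (length(no_ca) > 0) {
    warning("residue(s) without CA atom retained: ", paste(no_ca, collapse = ", "))
  }
  invisible(s)
}

#' Per-residue summary of a structure
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param chain optional chain id to restrict to.
#' @return tibble with one row per residue: `chain`, `resno`, `aa`,
#'   `n_atoms`, `has_ca`.
#' @export
residue_table <- function(s, chain = NULL) {
  if (!is.null(chain)) s <- s[s$chain %in% chain, ]
  tibble::as_tibble(s) |>
    dplyr::group_by(.data$chain, .data$resno, .data$aa) |>
    dplyr::summarise(
      n_atoms = dplyr::n(),
      has_ca = any(.data$atom == "CA"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chain, .data$resno)
}

#' Extract the amino-acid sequence of a structure
#'
#' @inheritParams residue_table
#' @param collapse return a single string (default) or a named vector of
#'   one-letter codes keyed by residue number.
#' @export
structure_sequence <- function(s, chain = NULL, collapse = TRUE) {
  res <- residue_table(s, chain = chain)
  if (collapse) paste(res$aa, collapse = "") else stats::setNames(res$aa, res$resno)
}

# Coordinate matrix for a selection of atoms (n x 3, rownames dropped).
.coords <- function(s, idx = NULL) {
  if (is.null(idx)) as.matrix(s[, c("x", "y", "z")]) else
    as.matrix(s[idx, c("x", "y", "z")])
}

# Single-atom coordinate lookup; NULL when absent.
.atom_xyz <- function(s, resno, atom, chain = NULL) {
  i <- which(s$resno == resno & s$atom == atom &
               (if (is.null(chain)) TRUE else s$chain == chain))
  if (length(i) == 0) return(NULL)
  c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
}

# Infer element from a PDB atom name.
.element_from_name <- function(name) {
  el <- substr(gsub("^[0-9]", "", name), 1, 1)
  ifelse(el %in% names(.vdw_radii), el, "C")
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf(
    "<protein_structure> %d atoms, %d residues, chain(s) %s, offset %+d\n",
    nrow(x), nrow(res), paste(unique(x$chain), collapse = ","), attr(x, "offset")
  ))
  if (nzchar(attr(x, "source") %||% "")) cat("source:", attr(x, "source"), "\n")
  NextMethod()
}

# Subsetting a protein_structure returns a plain tibble unless all atom
# columns survive; keep it simple and re-class explicitly where needed.
.reclass_structure <- function(atoms, template) {
  new_protein_structure(atoms,
    offset = attr(template, "offset") %||% 0L,
    source = attr(template, "source") %||% ""
  )
}
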