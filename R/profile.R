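#' Full per-residue structural profile
#'
#' Runs all geometry operators on a structure: secondary structure, SASA,
#' relative accessibility and burial class, hydrogen bonds, salt bridges,
#' disulfides and hydrophobic contacts.
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param probe,n_points see [compute_sasa()].
#' @param salt_bridge_cutoff see [detect_salt_bridges()].
#' @param buried_max,exposed_min see [relative_accessibility()].
#' @param hbond_args list of overrides for [detect_hbonds()].
#' @return a `structural_profile` object: list with `residues` (tibble:
#'   `chain`, `resno`, `aa`, `ss`, `sasa`, `rsa`, `burial_class`),
#'   `hbonds`, `salt_bridges`, `disulfides`, `hydrophobic` tibbles and the
#'   parameter set. Use [generics::tidy()] for a flat per-residue table.
#' @export
structural_profile <- function(s, probe = 1.4, n_points = 960,
                               salt_bridge_cutoff = 4.0,
                               buried_max = 20, exposed_min = 50,
                               hbond_args = list()) {
  ss <- assign_secondary_structure(s)
  acc <- compute_sasa(s, probe = probe, n_points = n_points) |>
    relative_accessibility(buried_max = buried_max, exposed_min = exposed_min)
  residues <- dplyr::left_join(ss, acc, by = c("chain", "resno", "aa"))
  structure(list(
    residues = residues,
    hbonds = do.call(detect_hbonds, c(list(s), hbond_args)),
    salt_bridges = detect_salt_bridges(s, cutoff = salt_bridge_cutoff),
    disulfides = detect_disulfides(s),
    hydrophobic = detect_hydrophobic_contacts(s),
    params = list(probe = probe, n_points = n_points,
                  salt_bridge_cutoff = salt_bridge_cutoff,
                  buried_max = buried_max, exposed_min = exposed_min,
                  hbond_args = hbond_args),
    source = attr(s, "source")
  ), class = "structural_profile")
}

#' @export
print.structural_profile <- function(x, ...) {
  cat(sprintf(
    "<structural_profile> %d residues | ss: %s | %d H-bonds, %d salt bridges, %d disulfides, %d hydrophobic contacts\n",
    nrow(x$residues),
    paste(sprintf("%s=%d", names(table(x$residues$ss)), table(x$residues$ss)),
          collapse = " "),
    nrow(x$hbonds), nrow(x$salt_bridges), nrow(x$disulfides), nrow(x$hydrophobic)
  ))
  invisible(x)
}

# Partner positions of `resno` in an interaction table with two residue
# columns.
.partners_of <- function(tbl, col1, col2, resno) {
  sort(unique(c(tbl[[col2]][tbl[[col1]] == resno],
                tbl[[col1]][tbl[[col2]] == resno])))
}

#' Tidy a structural profile into one row per residue
#'
#' Interaction partners are collapsed into comma-separated position lists.
#'
#' @param x a `structural_profile`.
#' @param ... unused.
#' @export
tidy.structural_profile <- function(x, ...) {
  res <- x$residues
  fmt <- function(v) if (length(v) == 0) "" else paste(v, collapse = ",")
  res$hbond_partners <- vapply(res$resno, function(r) {
    fmt(.partners_of(x$hbonds, "donor_resno", "acceptor_resno", r))
  }, character(1))
  res$salt_bridge_partners <- vapply(res$resno, function(r) {
    fmt(.partners_of(x$salt_bridges, "basic_resno", "acidic_resno", r))
  }, character(1))
  res$hydrophobic_partners <- vapply(res$resno, function(r) {
    fmt(.partners_of(x$hydrophobic, "resno1", "resno2", r))
  }, character(1))
  res$disulfide_partner <- vapply(res$resno, function(r) {
    fmt(.partners_of(x$disulfides, "resno1", "resno2", r))
  }, character(1))
  res
}

#' One-row summary of a structural profile
#'
#' @inheritParams tidy.structural_profile
#' @export
glance.structural_profile <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$residues),
    total_sasa = sum(x$residues$sasa),
    n_helix = sum(x$residues$ss == "H"),
    n_strand = sum(x$residues$ss == "E"),
    n_hbonds = nrow(x$hbonds),
    n_salt_bridges = nrow(x$salt_bridges),
    n_disulfides = nrow(x$disulfides),
    n_hydrophobic = nrow(x$hydrophobic)
  )
}

#' Write a structural profile to TSV and/or JSON
#'
#' @param x a `structural_profile`.
#' @param tsv,json output paths (`NULL` to skip).
#' @return the tidy per-residue tibble, invisibly.
#' @export
write_profile <- function(x, tsv = NULL, json = NULL) {
  td <- tidy.structural_profile(x)
  if (!is.null(tsv)) {
    utils::write.table(td, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(residues = td, hbonds = x$hbonds, salt_bridges = x$salt_bridges,
           disulfides = x$disulfides, hydrophobic = x$hydrophobic),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(td)
}

#' Per-residue profile plot
#'
#' RSA per residue coloured by burial class, with a secondary-structure
#' track along the x axis.
#'
#' @param object a `structural_profile`.
#' @param ... unused.
#' @export
autoplot.structural_profile <- function(object, ...) {
  res <- object$residues
  ggplot2::ggplot(res, ggplot2::aes(x = .data$resno, y = .data$rsa,
                                    fill = .data$burial_class)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_tile(
      data = res[res$ss %in% c("H", "G", "E"), ],
      ggplot2::aes(x = .data$resno, y = -6,
                   height = 6, fill = NULL, colour = .data$ss),
      width = 1, show.legend = TRUE, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "residue (precursor numbering)", y = "RSA (%)",
                  fill = "burial", colour = "secondary structure") +
    ggplot2::theme_minimal()
}
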