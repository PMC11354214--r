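#' Derive chemokine-fold regions from a secondary-structure assignment
#'
#' Partitions the precursor sequence into named fold elements: the signal
#' peptide (1..`signal_len`), the N-loop up to the first beta strand, the
#' three sheet strands (`beta1`..`beta3`, the E segments after the signal
#' peptide), the connecting 30s/40s loops, the 50s loop between the last
#' strand and the C-terminal helix, the `C_helix` (final H segment), and
#' `other` for anything after it. If the number of detected strands is not
#' three the regions are still emitted with a warning, loop names assigned
#' by order. Any interval can be overridden.
#'
#' @param ss_tbl per-residue tibble from [assign_secondary_structure()] on
#'   the full precursor model.
#' @param signal_len signal-peptide length (default 23 residues).
#' @param overrides named list `region = c(start, end)` replacing derived
#'   intervals.
#' @param min_strand,min_helix minimal segment lengths counted as a strand
#'   or as the C-terminal helix.
#' @return a `region_annotation` tibble: `region`, `start`, `end` (1-based
#'   inclusive, precursor numbering), a partition of the sequence.
#' @export
derive_regions <- function(ss_tbl, signal_len = 23, overrides = NULL,
                           min_strand = 2, min_helix = 4) {
  last <- max(ss_tbl$resno)
  seg <- ss_segments(ss_tbl, labels = c("H", "E"))
  strands <- seg[seg$ss == "E" & seg$start > signal_len &
                   (seg$end - seg$start + 1) >= min_strand, , drop = FALSE]
  if (nrow(strands) != 3) {
    warning("expected 3 beta strands after the signal peptide, found ",
            nrow(strands), "; loop names assigned by order")
  }
  helices <- seg[seg$ss == "H" &
                   (seg$end - seg$start + 1) >= min_helix &
                   seg$start > (if (nrow(strands)) max(strands$end) else signal_len), ,
                 drop = FALSE]
  helix <- if (nrow(helices)) helices[nrow(helices), , drop = FALSE] else NULL

  rows <- list(tibble::tibble(region = "signal_peptide", start = 1L,
                              end = as.integer(signal_len)))
  add <- function(region, start, end) {
    if (start <= end) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        region = region, start = as.integer(start), end = as.integer(end))
    }
  }
  cursor <- signal_len + 1
  strand_names <- c("beta1", "beta2", "beta3")
  loop_names <- c("N_loop", "thirties_loop", "forties_loop", "fifties_loop")
  for (k in seq_len(nrow(strands))) {
    loop <- if (k == 1) "N_loop" else if (k <= length(loop_names)) loop_names[k] else "other"
    add(loop, cursor, strands$start[k] - 1)
    add(if (k <= 3) strand_names[k] else "other", strands$start[k], strands$end[k])
    cursor <- strands$end[k] + 1
  }
  if (!is.null(helix)) {
    add(if (nrow(strands) >= 1) "fifties_loop" else "other", cursor, helix$start - 1)
    add("C_helix", helix$start, helix$end)
    cursor <- helix$end + 1
  }
  add("other", cursor, last)
  ann <- dplyr::bind_rows(rows)

  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      iv <- overrides[[nm]]
      ann <- ann[ann$region != nm, , drop = FALSE]
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        region = nm, start = as.integer(iv[1]), end = as.integer(iv[2])))
    }
    ann <- dplyr::arrange(ann, .data$start)
  }
  .validate_regions(ann, last)
  structure(ann, class = c("region_annotation", class(ann)))
}

.validate_regions <- function(ann, last) {
  ann <- dplyr::arrange(ann, .data$start)
  cov <- unlist(purrr::map2(ann$start, ann$end, seq))
  if (anyDuplicated(cov)) stop("region intervals overlap")
  if (!setequal(cov, seq_len(last))) stop("region intervals do not cover 1..", last)
  invisible(ann)
}

#' Region label of residue positions
#'
#' @param positions integer positions (precursor numbering).
#' @param annotation a `region_annotation` from [derive_regions()].
#' @return character vector of region names.
#' @export
region_of <- function(positions, annotation) {
  out <- rep(NA_character_, length(positions))
  for (k in seq_len(nrow(annotation))) {
    hit <- positions >= annotation$start[k] & positions <= annotation$end[k]
    out[hit] <- annotation$region[k]
  }
  out
}

#' Cohort-level summary counts
#'
#' Aggregates a set of per-variant impact reports: variants per fold
#' region, counts of variants changing each structural parameter, stability
#' calls, overlap counts (stability loss together with interaction loss;
#' stability-only), and conservation overlap when a `conserved_flag` column
#' is present.
#'
#' @param reports impact-report tibble (rows from [diff_profiles()]),
#'   optionally augmented with `call` (stability) and `conserved_flag`.
#' @param annotation a `region_annotation`, or `NULL` to skip region
#'   counts.
#' @return a `cohort_summary` list; see [tidy.cohort_summary()] /
#'   [glance.cohort_summary()].
#' @export
cohort_summary <- function(reports, annotation = NULL) {
  stopifnot(nrow(reports) >= 1)
  nz <- function(col) lengths(reports[[col]]) > 0
  hb_change <- nz("hbonds_gained") | nz("hbonds_lost")
  sb_change <- nz("salt_bridges_gained") | nz("salt_bridges_lost")
  interaction_loss <- nz("hbonds_lost") | nz("salt_bridges_lost") |
    reports$disulfide_lost
  less <- if ("call" %in% names(reports)) {
    !is.na(reports$call) & reports$call == "less_stable"
  } else rep(NA, nrow(reports))

  counts <- list(
    n_variants = nrow(reports),
    n_any_structural_change = sum(reports$any_structural_change),
    n_ss_change = sum(reports$ss_changed),
    n_accessibility_change = sum(reports$burial_changed),
    n_hbond_change = sum(hb_change),
    n_salt_bridge_change = sum(sb_change),
    n_salt_bridge_gain = sum(nz("salt_bridges_gained")),
    n_disulfide_lost = sum(reports$disulfide_lost),
    n_cys_introduced = sum(reports$cys_introduced),
    n_less_stable = if (anyNA(less)) NA_integer_ else sum(less),
    n_more_stable = if ("call" %in% names(reports)) {
      sum(!is.na(reports$call) & reports$call == "more_stable")
    } else NA_integer_,
    n_uncertain = if ("call" %in% names(reports)) {
      sum(!is.na(reports$call) & reports$call == "uncertain")
    } else NA_integer_,
    n_stability_and_interaction_loss =
      if (anyNA(less)) NA_integer_ else sum(less & interaction_loss),
    n_stability_only = if (anyNA(less)) NA_integer_ else
      sum(less & !reports$any_structural_change),
    n_conserved_with_change = if ("conserved_flag" %in% names(reports)) {
      sum(reports$conserved_flag & reports$any_structural_change, na.rm = TRUE)
    } else NA_integer_,
    n_conserved_without_change = if ("conserved_flag" %in% names(reports)) {
      sum(reports$conserved_flag & !reports$any_structural_change, na.rm = TRUE)
    } else NA_integer_
  )
  per_region <- NULL
  if (!is.null(annotation)) {
    per_region <- tibble::tibble(
      region = region_of(reports$position, annotation)
    ) |>
      dplyr::count(.data$region, name = "n_variants")
  }
  structure(list(counts = counts, per_region = per_region),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-34s %s\n", nm, x$counts[[nm]]))
  if (!is.null(x$per_region)) {
    cat("  variants per region:\n")
    for (k in seq_len(nrow(x$per_region))) {
      cat(sprintf("    %-20s %d\n", x$per_region$region[k],
                  x$per_region$n_variants[k]))
    }
  }
  invisible(x)
}

#' Tidy / summarise a cohort summary
#'
#' `tidy()` returns the counts as a long tibble (`metric`, `n`);
#' `glance()` returns them as one wide row.
#'
#' @param x a `cohort_summary`.
#' @param ... unused.
#' @export
tidy.cohort_summary <- function(x, ...) {
  tibble::tibble(metric = names(x$counts),
                 n = as.integer(unlist(x$counts)))
}

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::as_tibble(x$counts)
}

#' Write a cohort summary as JSON and/or a Markdown table
#'
#' @param x a `cohort_summary`.
#' @param json,md output paths (`NULL` to skip).
#' @export
write_summary <- function(x, json = NULL, md = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(list(counts = x$counts, per_region = x$per_region),
                         json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(md)) {
    td <- tidy.cohort_summary(x)
    lines <- c("| metric | n |", "|---|---|",
               sprintf("| %s | %s |", td$metric, td$n))
    if (!is.null(x$per_region)) {
      lines <- c(lines, "", "| region | variants |", "|---|---|",
                 sprintf("| %s | %d |", x$per_region$region,
                         x$per_region$n_variants))
    }
    writeLines(lines, md)
  }
  invisible(x)
}
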