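# WT-vs-mutant profile diffing: one impact report row per variant.

.pair_keys <- function(tbl, col1, col2) {
  if (nrow(tbl) == 0) return(character())
  a <- pmin(tbl[[col1]], tbl[[col2]]); b <- pmax(tbl[[col1]], tbl[[col2]])
  unique(paste0(a, "-", b))
}

.pairs_touching <- function(keys, position) {
  if (length(keys) == 0) return(keys)
  m <- do.call(rbind, strsplit(keys, "-"))
  keys[m[, 1] == as.character(position) | m[, 2] == as.character(position)]
}

#' Diff wild-type and mutant structural profiles
#'
#' Site-focused comparison of two profiles computed on structures of
#' identical length and numbering. Interaction gains/losses are the
#' residue-pair set differences (with a rigid-backbone mutant only pairs
#' touching the mutated side chain can change, so this equals the
#' interactions involving the variant position plus any pair whose partner
#' set changed). Secondary-structure and burial-class change are evaluated
#' at the variant position; `disulfide_lost` is set when a wild-type
#' disulfide involving the position disappears, `cys_introduced` when the
#' mutant residue is a cysteine. `any_structural_change` is the OR of the
#' secondary-structure, burial, H-bond, salt-bridge and disulfide flags.
#'
#' @param wt,mut `structural_profile` objects from [structural_profile()].
#' @param variant one-row variant tibble (`position`, `wt`, `mut`) or a
#'   string like `"K78E"`.
#' @return a one-row `impact_report` tibble; interaction deltas are
#'   list-columns of `"i-j"` residue-pair keys.
#' @export
diff_profiles <- function(wt, mut, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  v <- variant[1, ]
  rw <- wt$residues; rm_ <- mut$residues
  if (nrow(rw) != nrow(rm_) || !all(rw$resno == rm_$resno)) {
    stop("profiles have mismatched residue numbering")
  }
  i <- match(v$position, rw$resno)
  if (is.na(i)) stop("variant position ", v$position, " not in profile")

  setdiffs <- function(tblw, tblm, c1, c2) {
    kw <- .pair_keys(tblw, c1, c2); km <- .pair_keys(tblm, c1, c2)
    list(gained = setdiff(km, kw), lost = setdiff(kw, km))
  }
  hb <- setdiffs(wt$hbonds, mut$hbonds, "donor_resno", "acceptor_resno")
  sb <- setdiffs(wt$salt_bridges, mut$salt_bridges, "basic_resno", "acidic_resno")
  hp <- setdiffs(wt$hydrophobic, mut$hydrophobic, "resno1", "resno2")

  wt_ds <- .pair_keys(wt$disulfides, "resno1", "resno2")
  mut_ds <- .pair_keys(mut$disulfides, "resno1", "resno2")
  disulfide_lost <- length(setdiff(.pairs_touching(wt_ds, v$position), mut_ds)) > 0

  delta_rsa <- rm_$rsa[i] - rw$rsa[i]
  burial_changed <- !identical(as.character(rw$burial_class[i]),
                               as.character(rm_$burial_class[i]))
  ss_changed <- !identical(rw$ss[i], rm_$ss[i])
  any_change <- ss_changed || burial_changed ||
    length(c(hb$gained, hb$lost)) > 0 || length(c(sb$gained, sb$lost)) > 0 ||
    disulfide_lost || identical(v$mut, "C")

  out <- tibble::tibble(
    variant = sprintf("%s%d%s", v$wt, v$position, v$mut),
    position = v$position, wt = v$wt, mut = v$mut,
    ss_wt = rw$ss[i], ss_mut = rm_$ss[i], ss_changed = ss_changed,
    burial_wt = as.character(rw$burial_class[i]),
    burial_mut = as.character(rm_$burial_class[i]),
    burial_changed = burial_changed, delta_rsa = delta_rsa,
    hbonds_gained = list(hb$gained), hbonds_lost = list(hb$lost),
    salt_bridges_gained = list(sb$gained), salt_bridges_lost = list(sb$lost),
    hydrophobic_gained = list(hp$gained), hydrophobic_lost = list(hp$lost),
    disulfide_lost = disulfide_lost, cys_introduced = identical(v$mut, "C"),
    any_structural_change = any_change
  )
  class(out) <- c("impact_report", class(out))
  out
}

#' Partner positions of the variant in an impact-report delta column
#'
#' @param report an `impact_report` row.
#' @param field one of the delta list-columns, e.g. `"hbonds_gained"`.
#' @return integer vector of partner residue positions.
#' @export
impact_partners <- function(report, field) {
  keys <- .pairs_touching(report[[field]][[1]], report$position[1])
  if (length(keys) == 0) return(integer())
  m <- do.call(rbind, strsplit(keys, "-"))
  sort(unique(setdiff(as.integer(m), report$position[1])))
}

# Flatten list-columns for TSV export.
.flatten_report <- function(reports) {
  listcols <- names(reports)[vapply(reports, is.list, logical(1))]
  for (cc in listcols) {
    reports[[cc]] <- vapply(reports[[cc]], function(v) paste(v, collapse = ";"),
                            character(1))
  }
  reports
}
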