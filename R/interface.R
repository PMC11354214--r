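#' Inter-chain contacts of a two-chain complex
#'
#' Runs the hydrogen-bond and salt-bridge detectors on the complex and keeps
#' cross-chain pairs only.
#'
#' @param s a two-chain [protein_structure][new_protein_structure].
#' @param chains the two chain ids to compare (default: the structure's
#'   two chains).
#' @param ... passed to [detect_hbonds()] / [detect_salt_bridges()].
#' @return tibble: `pos_a`, `pos_b` (residue numbers in chains 1 and 2),
#'   `type` (`hbond`/`salt_bridge`), `distance`.
#' @export
interface_contacts <- function(s, chains = NULL, ...) {
  if (is.null(chains)) chains <- unique(s$chain)
  if (length(chains) != 2) {
    stop("exactly two chains required, found: ", paste(chains, collapse = ", "))
  }
  sub <- .reclass_structure(tibble::as_tibble(s)[s$chain %in% chains, ], s)
  hb <- detect_hbonds(sub)
  sb <- detect_salt_bridges(sub)
  norm <- function(c1, r1, c2, r2, type, dist) {
    cross <- c1 != c2
    if (!any(cross)) return(NULL)
    sw <- c1[cross] != chains[1]
    tibble::tibble(
      pos_a = ifelse(sw, r2[cross], r1[cross]),
      pos_b = ifelse(sw, r1[cross], r2[cross]),
      type = type, distance = dist[cross]
    )
  }
  out <- dplyr::bind_rows(
    norm(hb$donor_chain, hb$donor_resno, hb$acceptor_chain, hb$acceptor_resno,
         "hbond", hb$distance),
    norm(sb$basic_chain, sb$basic_resno, sb$acidic_chain, sb$acidic_resno,
         "salt_bridge", sb$distance)
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(pos_a = integer(), pos_b = integer(),
                          type = character(), distance = numeric()))
  }
  dplyr::distinct(dplyr::arrange(out, .data$pos_a, .data$pos_b))
}

#' Map interface contact positions onto a reference sequence
#'
#' Each ligand-chain contact position is carried through the alignment to
#' the reference sequence; positions falling in reference gaps are dropped
#' (count in attribute `n_dropped`).
#'
#' @param contacts tibble from [interface_contacts()].
#' @param aln an `msa` containing both sequences.
#' @param ligand name of the aligned sequence matching the complex's ligand
#'   chain (whose positions are in `pos_a`).
#' @param reference name of the reference sequence.
#' @return tibble: `ligand_position`, `reference_position`, `type`, flagged
#'   `interface_analogous = TRUE`.
#' @export
map_interface_positions <- function(contacts, aln, ligand, reference) {
  for (id in c(ligand, reference)) {
    if (!id %in% names(aln$seqs)) stop("sequence not in alignment: ", id)
  }
  mapped <- .aln_transfer(aln, ligand, reference, contacts$pos_a)
  dropped <- is.na(mapped)
  out <- tibble::tibble(
    ligand_position = contacts$pos_a[!dropped],
    reference_position = mapped[!dropped],
    type = contacts$type[!dropped],
    interface_analogous = TRUE
  )
  out <- dplyr::distinct(out)
  attr(out, "n_dropped") <- sum(dropped)
  out
}
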