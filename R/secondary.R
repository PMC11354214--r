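#' Assign secondary structure (Kabsch-Sander style)
#'
#' Backbone amide hydrogens are placed geometrically (1.0 A from N along the
#' preceding carbonyl C->O direction) and the classic electrostatic
#' hydrogen-bond energy
#' `E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332` kcal/mol
#' is evaluated for every CO(i)...HN(j) pair; a bond is assigned when
#' `E < -0.5`. Patterns are reduced to a five-letter alphabet: two
#' consecutive i->i+4 turns give `H` (alpha helix), i->i+3 give `G` (3-10),
#' ladder (bridge) patterns give `E`, remaining turn residues `T`, all else
#' `C`. Chain breaks (CA-CA > 4.5 A or a numbering gap) split the
#' assignment windows; chains shorter than 4 linked residues come back all
#' `C`.
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param chain optional chain id to restrict to.
#' @param e_cut hydrogen-bond energy threshold, kcal/mol.
#' @return tibble: `chain`, `resno`, `aa`, `ss` with `ss` in
#'   `{H, G, E, T, C}`.
#' @export
assign_secondary_structure <- function(s, chain = NULL, e_cut = -0.5) {
  res <- .residue_backbones(s, chain = chain)
  n <- length(res)
  out <- tibble::tibble(
    chain = purrr::map_chr(res, "chain"),
    resno = purrr::map_int(res, function(r) as.integer(r$resno)),
    aa = purrr::map_chr(res, "aa"),
    ss = rep("C", n)
  )
  if (n < 4) return(out)
  H <- .amide_hydrogens(res, "dssp")
  hb <- .ks_hbond_matrix(res, H, e_cut)

  linked_run <- function(i, j) {
    # all residues i+1..j linked to their predecessor (same segment)
    if (j > n || i < 1) return(FALSE)
    all(vapply(seq(i + 1, j), function(k) res[[k]]$linked_prev, logical(1)))
  }
  turn <- function(nlen) {
    v <- rep(FALSE, n)
    for (i in seq_len(n - nlen)) v[i] <- hb[i, i + nlen] && linked_run(i, i + nlen)
    v
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  ss <- rep("C", n)
  # turns first (lowest priority), then G, E, H overwrite
  for (i in which(t3)) ss[(i + 1):(i + 2)] <- "T"
  for (i in which(t4)) ss[(i + 1):(i + 3)] <- "T"
  for (i in which(t5)) ss[(i + 1):(i + 4)] <- "T"
  for (i in which(t3)) if (i > 1 && t3[i - 1]) ss[i:(i + 2)] <- "G"

  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (!linked_run(i - 1, i + 1)) next
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      if (!linked_run(j - 1, j + 1)) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }
  ss[bridge] <- "E"
  for (i in which(t4)) if (i > 1 && t4[i - 1]) ss[i:(i + 3)] <- "H"
  out$ss <- ss
  out
}

# Kabsch-Sander H-bond matrix: hb[i, j] is TRUE when the carbonyl of residue
# i accepts the amide hydrogen of residue j with E < e_cut.
.ks_hbond_matrix <- function(res, H, e_cut) {
  n <- length(res)
  hb <- matrix(FALSE, n, n)
  q <- 27.888 # 0.084 * 332 kcal/mol
  ca <- do.call(rbind, lapply(res, function(r) r$CA %||% rep(NA_real_, 3)))
  for (i in seq_len(n)) {
    ri <- res[[i]]
    if (is.null(ri$C) || is.null(ri$O)) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      rj <- res[[j]]
      if (is.null(rj$N) || !all(is.finite(H[j, ]))) next
      if (all(is.finite(ca[i, ])) && all(is.finite(ca[j, ])) &&
          sum((ca[i, ] - ca[j, ])^2) > 81) next
      h <- H[j, ]
      e <- q * (1 / .vnorm(ri$O - rj$N) + 1 / .vnorm(ri$C - h) -
                1 / .vnorm(ri$O - h) - 1 / .vnorm(ri$C - rj$N))
      if (e < e_cut) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Collapse per-residue labels into segments
#'
#' @param ss_tbl tibble from [assign_secondary_structure()].
#' @param labels labels to report segments for.
#' @return tibble: `ss`, `start`, `end` (residue numbers, inclusive).
#' @export
ss_segments <- function(ss_tbl, labels = c("H", "G", "E")) {
  r <- rle(ss_tbl$ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- tibble::tibble(
    ss = r$values,
    start = ss_tbl$resno[starts],
    end = ss_tbl$resno[ends]
  )
  seg[seg$ss %in% labels, , drop = FALSE]
}
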