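# Geometric placement of polar hydrogens. Input structures are heavy-atom
# only (read_pdb discards file hydrogens); donors get idealized hydrogens so
# wild-type and mutant models are treated identically.

# Backbone amide hydrogens. convention = "bisector" places H in the peptide
# plane bisecting C(i-1)-N-CA (used for H-bond detection); "dssp" places H
# 1.0 A from N along the C(i-1)->O(i-1) carbonyl direction (used by the
# secondary-structure energy term). First residue of a segment and prolines
# carry no NH.
.amide_hydrogens <- function(res, convention = c("bisector", "dssp")) {
  convention <- match.arg(convention)
  n <- length(res)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    ri <- res[[i]]; rp <- res[[i - 1]]
    if (ri$aa == "P") next
    if (!ri$linked_prev) next
    if (is.null(ri$N) || is.null(rp$C) || is.null(rp$O)) next
    H[i, ] <- if (convention == "dssp") {
      ri$N + .unit(rp$C - rp$O)
    } else {
      if (is.null(ri$CA)) next
      ri$N + .unit(.unit(ri$N - rp$C) + .unit(ri$N - ri$CA))
    }
  }
  H
}

# Internal per-residue backbone list: N/CA/C/O coordinates plus chain
# linkage flags (linked_prev is FALSE across chain breaks, CA-CA > 4.5 A or
# a residue-number gap).
.residue_backbones <- function(s, chain = NULL) {
  if (!is.null(chain)) s <- s[s$chain %in% chain, , drop = FALSE]
  res_tab <- residue_table(s)
  res <- vector("list", nrow(res_tab))
  for (i in seq_len(nrow(res_tab))) {
    rn <- res_tab$resno[i]; ch <- res_tab$chain[i]
    res[[i]] <- list(
      chain = ch, resno = rn, aa = res_tab$aa[i],
      N = .atom_xyz(s, rn, "N", ch), CA = .atom_xyz(s, rn, "CA", ch),
      C = .atom_xyz(s, rn, "C", ch), O = .atom_xyz(s, rn, "O", ch),
      linked_prev = FALSE
    )
  }
  for (i in seq_len(length(res))[-1]) {
    a <- res[[i - 1]]; b <- res[[i]]
    b$linked_prev <- identical(a$chain, b$chain) &&
      (b$resno == a$resno + 1) &&
      !is.null(a$CA) && !is.null(b$CA) && .vnorm(b$CA - a$CA) <= 4.5
    res[[i]] <- b
  }
  res
}

# Explicit hydrogens for fixed (sp2) side-chain donor atoms. Returns a list
# of H coordinate matrices keyed by "<chain>|<resno>|<donor atom>"; rotatable
# donors are absent here (handled at evaluation time).
.sidechain_donor_hydrogens <- function(s) {
  out <- list()
  add <- function(ch, rn, atom, H) {
    key <- paste(ch, rn, atom, sep = "|")
    out[[key]] <<- rbind(out[[key]], H)
  }
  res_tab <- residue_table(s)
  for (i in seq_len(nrow(res_tab))) {
    rn <- res_tab$resno[i]; ch <- res_tab$chain[i]; aa <- res_tab$aa[i]
    donors <- .sc_donors[[aa]]
    if (is.null(donors)) next
    g <- function(a) .atom_xyz(s, rn, a, ch)
    for (d in donors) {
      if (d$rot) next
      D <- g(d$atom)
      if (is.null(D)) { warning("donor ", d$atom, " missing at residue ", rn); next }
      H <- switch(paste(aa, d$atom),
        "R NE"  = .bisector_h(D, g("CD"), g("CZ")),
        "R NH1" = .sp2_pair_h(g("NE"), g("CZ"), D),
        "R NH2" = .sp2_pair_h(g("NE"), g("CZ"), D),
        "N ND2" = .sp2_pair_h(g("CB"), g("CG"), D),
        "Q NE2" = .sp2_pair_h(g("CG"), g("CD"), D),
        "H ND1" = .bisector_h(D, g("CG"), g("CE1")),
        "H NE2" = .bisector_h(D, g("CD2"), g("CE1")),
        "W NE1" = .bisector_h(D, g("CD1"), g("CE2")),
        NULL
      )
      if (is.null(H)) { warning("cannot place H on ", d$atom, " at residue ", rn); next }
      add(ch, rn, d$atom, H)
    }
  }
  out
}

.bisector_h <- function(D, n1, n2) {
  if (is.null(n1) || is.null(n2)) return(NULL)
  matrix(D + .unit(.unit(D - n1) + .unit(D - n2)), 1, 3)
}

# Two in-plane hydrogens on a terminal sp2 NH2 group with antecedents A-B-N.
.sp2_pair_h <- function(A, B, N) {
  if (is.null(A) || is.null(B)) return(NULL)
  rbind(.nerf(A, B, N, 1.0, 120, 0), .nerf(A, B, N, 1.0, 120, 180))
}
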