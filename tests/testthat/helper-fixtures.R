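# Shared fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoized synthetic chemokine-fold model (construction ~2 s)
chemokine_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_chemokine_model()
    cache
  }
})

# brute-force all-pairs geometric scans, independent of the detectors
brute_salt_bridges <- function(s, cutoff = 4.0) {
  basic <- list(K = "NZ", R = c("NE", "NH1", "NH2"), H = c("ND1", "NE2"))
  acidic <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"))
  out <- character()
  for (i in seq_len(nrow(s))) for (j in seq_len(nrow(s))) {
    if (!(s$atom[i] %in% basic[[s$aa[i]]])) next
    if (!(s$atom[j] %in% acidic[[s$aa[j]]])) next
    d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
    if (d <= cutoff) out <- c(out, paste(s$resno[i], s$resno[j]))
  }
  sort(unique(out))
}

brute_disulfide_candidates <- function(s, cutoff = 2.5) {
  sg <- which(s$aa == "C" & s$atom == "SG")
  out <- character()
  for (i in sg) for (j in sg) {
    if (s$resno[i] >= s$resno[j]) next
    d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
    if (d <= cutoff) out <- c(out, paste(s$resno[i], s$resno[j]))
  }
  sort(unique(out))
}

brute_hydrophobic <- function(s, cutoff = 3.9) {
  apolar <- list(
    A = "CB", R = c("CB", "CG"), N = "CB", D = "CB", C = "CB",
    Q = c("CB", "CG"), E = c("CB", "CG"), H = "CB",
    I = c("CB", "CG1", "CG2", "CD1"), L = c("CB", "CG", "CD1", "CD2"),
    K = c("CB", "CG", "CD"), M = c("CB", "CG", "CE"),
    F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    P = c("CB", "CG"), S = character(), T = "CG2",
    W = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
    Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
    V = c("CB", "CG1", "CG2")
  )
  out <- character()
  for (i in seq_len(nrow(s))) for (j in seq_len(nrow(s))) {
    if (s$resno[i] >= s$resno[j]) next
    if (!(s$atom[i] %in% apolar[[s$aa[i]]])) next
    if (!(s$atom[j] %in% apolar[[s$aa[j]]])) next
    d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
    if (d <= cutoff) out <- c(out, paste(s$resno[i], s$resno[j]))
  }
  sort(unique(out))
}

# Independent brute-force H-bond scan: plain loops, hydrogen construction
# re-derived from the documented rules (bisector amide H; sp2 side-chain H
# by in-plane rotation; rotatable donors oriented toward the acceptor).
brute_hbonds <- function(s, d_da = 3.9, d_ha = 2.5, ang_min = 90) {
  sc_donors <- list(
    R = list(NE = "ring", NH1 = "nh2", NH2 = "nh2"), N = list(ND2 = "nh2"),
    Q = list(NE2 = "nh2"), H = list(ND1 = "ring", NE2 = "ring"),
    K = list(NZ = "rot"), S = list(OG = "rot"), T = list(OG1 = "rot"),
    Y = list(OH = "rot"), W = list(NE1 = "ring"), C = list(SG = "rot")
  )
  ring_nb <- list("R.NE" = c("CD", "CZ"), "H.ND1" = c("CG", "CE1"),
                  "H.NE2" = c("CD2", "CE1"), "W.NE1" = c("CD1", "CE2"))
  nh2_par <- list("R.NH1" = c("NE", "CZ"), "R.NH2" = c("NE", "CZ"),
                  "N.ND2" = c("CB", "CG"), "Q.NE2" = c("CG", "CD"))
  sc_acc <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1",
                 Q = "OE1", S = "OG", T = "OG1", Y = "OH",
                 H = c("ND1", "NE2"), M = "SD")
  unitv <- function(v) v / sqrt(sum(v^2))
  rodrigues <- function(v, axis, deg) {
    k <- unitv(axis); th <- deg * pi / 180
    v * cos(th) + c(k[2] * v[3] - k[3] * v[2], k[3] * v[1] - k[1] * v[3],
                    k[1] * v[2] - k[2] * v[1]) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  res <- unique(s[, c("chain", "resno", "aa")])
  g <- function(rn, at, ch) {
    i <- which(s$resno == rn & s$atom == at & s$chain == ch)
    if (length(i) == 0) NULL else c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
  }
  donors <- list(); acceptors <- list()
  for (k in seq_len(nrow(res))) {
    rn <- res$resno[k]; ch <- res$chain[k]; aa <- res$aa[k]
    N <- g(rn, "N", ch); CA <- g(rn, "CA", ch)
    Cp <- g(rn - 1, "C", ch); Op <- g(rn - 1, "O", ch); CAp <- g(rn - 1, "CA", ch)
    linked <- !is.null(CAp) && !is.null(CA) && sqrt(sum((CA - CAp)^2)) <= 4.5
    if (aa != "P" && linked && !is.null(N) && !is.null(Cp) && !is.null(CA)) {
      H <- N + unitv(unitv(N - Cp) + unitv(N - CA))
      donors[[length(donors) + 1]] <- list(rn = rn, ch = ch, atom = "N",
                                           D = N, H = list(H), bb = TRUE)
    }
    O <- g(rn, "O", ch)
    if (!is.null(O)) acceptors[[length(acceptors) + 1]] <-
      list(rn = rn, ch = ch, atom = "O", A = O, bb = TRUE)
    OXT <- g(rn, "OXT", ch)
    if (!is.null(OXT)) acceptors[[length(acceptors) + 1]] <-
      list(rn = rn, ch = ch, atom = "OXT", A = OXT, bb = TRUE)
    for (dn in names(sc_donors[[aa]] %||% list())) {
      kind <- sc_donors[[aa]][[dn]]
      D <- g(rn, dn, ch)
      if (is.null(D)) next
      key <- paste(aa, dn, sep = ".")
      Hs <- if (kind == "ring") {
        nb <- ring_nb[[key]]
        p1 <- g(rn, nb[1], ch); p2 <- g(rn, nb[2], ch)
        list(D + unitv(unitv(D - p1) + unitv(D - p2)))
      } else if (kind == "nh2") {
        par <- nh2_par[[key]]
        A2 <- g(rn, par[1], ch); B2 <- g(rn, par[2], ch)
        nrm <- unitv(c(
          (B2 - A2)[2] * (D - B2)[3] - (B2 - A2)[3] * (D - B2)[2],
          (B2 - A2)[3] * (D - B2)[1] - (B2 - A2)[1] * (D - B2)[3],
          (B2 - A2)[1] * (D - B2)[2] - (B2 - A2)[2] * (D - B2)[1]))
        u <- unitv(B2 - D)
        list(D + rodrigues(u, nrm, 120), D + rodrigues(u, nrm, -120))
      } else "rot"
      donors[[length(donors) + 1]] <- list(rn = rn, ch = ch, atom = dn,
                                           D = D, H = Hs, bb = FALSE)
    }
    for (an in sc_acc[[aa]] %||% character()) {
      A <- g(rn, an, ch)
      if (!is.null(A)) acceptors[[length(acceptors) + 1]] <-
        list(rn = rn, ch = ch, atom = an, A = A, bb = FALSE)
    }
  }
  out <- character()
  for (d in donors) for (a in acceptors) {
    if (d$rn == a$rn && d$ch == a$ch) next
    if (d$bb && a$bb && d$ch == a$ch && a$rn == d$rn - 1) next
    dda <- sqrt(sum((d$D - a$A)^2))
    if (dda > d_da) next
    Hs <- if (identical(d$H, "rot")) list(d$D + unitv(a$A - d$D)) else d$H
    hit <- FALSE
    for (H in Hs) {
      dha <- sqrt(sum((H - a$A)^2))
      cosang <- sum((d$D - H) * (a$A - H)) /
        (sqrt(sum((d$D - H)^2)) * dha)
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (dha <= d_ha && ang >= ang_min) hit <- TRUE
    }
    if (hit) out <- c(out, paste(d$rn, d$atom, a$rn, a$atom))
  }
  sort(unique(out))
}

# independent greedy disulfide oracle (enumerate, sort, greedily match)
brute_disulfides_greedy <- function(s, cutoff = 2.5) {
  sg <- which(s$aa == "C" & s$atom == "SG")
  cand <- list()
  for (i in sg) for (j in sg) {
    if (s$resno[i] >= s$resno[j]) next
    d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
    if (d <= cutoff) cand[[length(cand) + 1]] <- c(s$resno[i], s$resno[j], d)
  }
  if (length(cand) == 0) return(character())
  cand <- cand[order(vapply(cand, `[`, 0, 3))]
  used <- integer(); out <- character()
  for (p in cand) {
    if (p[1] %in% used || p[2] %in% used) next
    used <- c(used, p[1], p[2])
    out <- c(out, paste(p[1], p[2]))
  }
  sort(out)
}

# independent dihedral evaluation (plain formula, no package internals)
ref_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

atom_xyz <- function(s, resno, atom, chain = NULL) {
  i <- which(s$resno == resno & s$atom == atom &
               (if (is.null(chain)) TRUE else s$chain == chain))
  c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
}

# small helper: write a variant TSV
write_variant_tsv <- function(variants, path, annotation = NULL) {
  df <- data.frame(variant = variants)
  if (!is.null(annotation)) df$annotation <- annotation
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
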