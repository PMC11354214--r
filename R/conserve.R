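#' Per-position conservation grades from an alignment
#'
#' An entropy-based stand-in for server-computed conservation grades: each
#' reference-ungapped column gets the normalized Shannon entropy
#' `h = -sum(p log p) / log(20)` over its non-gap residues, binned to a
#' 1-9 grade as `9 - floor(9 h)` clipped to `[1, 9]` (9 = fully conserved).
#' Precomputed grades (e.g. a ConSurf export) can be ingested instead via
#' [read_conservation_grades()]; the downstream "grade >= 7" rule is
#' applied identically either way.
#'
#' @param aln an `msa` from [read_alignment()] / [as_alignment()].
#' @param reference name of the reference sequence (positions are reported
#'   in its ungapped numbering).
#' @return tibble: `position`, `aa`, `grade`, `source = "computed"`.
#' @export
conservation_grades <- function(aln, reference) {
  if (length(aln$seqs) < 3) stop("at least 3 sequences required for grades")
  refmap <- alignment_map(aln, reference)
  mat <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  grades <- vapply(seq_len(nrow(refmap)), function(i) {
    col <- mat[, refmap$column[i]]
    col <- col[col != "-" & col != "."]
    p <- table(col) / length(col)
    h <- -sum(p * log(p)) / log(20)
    max(1L, min(9L, 9L - as.integer(floor(h * 9))))
  }, integer(1))
  tibble::tibble(position = refmap$position, aa = refmap$aa,
                 grade = grades, source = "computed")
}

#' Is a position highly conserved?
#'
#' TRUE when the grade is 7 or better on the 1-9 scale.
#'
#' @param profile grades tibble from [conservation_grades()] or
#'   [read_conservation_grades()].
#' @param position residue position(s).
#' @param threshold minimal grade counting as highly conserved.
#' @return logical vector.
#' @export
is_highly_conserved <- function(profile, position, threshold = 7L) {
  g <- profile$grade[match(position, profile$position)]
  if (anyNA(g)) {
    stop("no conservation grade for position(s): ",
         paste(position[is.na(g)], collapse = ", "))
  }
  g >= threshold
}
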