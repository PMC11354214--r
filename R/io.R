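#' Read a protein structure from a PDB file
#'
#' Reads ATOM records (first MODEL of multi-model files), drops HETATM,
#' waters, hydrogens and alternate locations other than A, and shifts the
#' file residue numbering by `offset` into precursor numbering. Mature-form
#' coordinate files of a precursor protein are typically shifted by the
#' signal-peptide length (e.g. `offset = 23`).
#'
#' @param path PDB file.
#' @param offset integer added to file residue numbers (default 0).
#' @param chain optional chain id(s) to keep (default: all).
#' @return a [protein_structure][new_protein_structure].
#' @export
read_pdb <- function(path, offset = 0L, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records read from ", path)
  aa <- aa_3to1(at$resid)
  if (any(is.na(aa))) {
    warning("dropping non-standard residue(s): ",
            paste(unique(at$resid[is.na(aa)]), collapse = ", "))
    at <- at[!is.na(aa), , drop = FALSE]
    aa <- aa[!is.na(aa)]
  }
  el <- at$elesy
  el[is.na(el) | !nzchar(el)] <- .element_from_name(at$elety[is.na(el) | !nzchar(el)])
  hyd <- toupper(el) == "H"
  at <- at[!hyd, , drop = FALSE]
  aa <- aa[!hyd]
  el <- toupper(el[!hyd])
  ch <- at$chain
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  new_protein_structure(
    tibble::tibble(
      chain = ch, resno = at$resno + as.integer(offset), aa = aa,
      atom = at$elety, element = el,
      x = at$x, y = at$y, z = at$z,
      occ = ifelse(is.na(at$o), 1, at$o)
    ),
    offset = offset, source = path
  )
}

#' Write a protein structure to a PDB file
#'
#' Precursor residue numbering is written as-is. Optional REMARK lines are
#' prepended (used to record variant, seed and rotamer-library version of
#' mutant models).
#'
#' @param s a [protein_structure][new_protein_structure].
#' @param path output file.
#' @param remarks character vector of REMARK payloads.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, remarks = NULL) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(.coords(s))),
    resno = s$resno, resid = aa_1to3(s$aa), elety = s$atom,
    chain = s$chain, o = s$occ, b = rep(0, nrow(s)),
    elesy = s$element
  )
  if (!is.null(remarks)) {
    body <- readLines(path)
    writeLines(c(sprintf("REMARK 250 %s", remarks), body), path)
  }
  invisible(path)
}

# --- variant notation ------------------------------------------------------

.parse_one_variant <- function(x) {
  v <- sub("^p\\.", "", trimws(x))
  m <- regmatches(v, regexec("^([A-Za-z\\*]+)([0-9]+)([A-Za-z\\*=]+)$", v))[[1]]
  if (length(m) == 0) {
    return(list(position = NA_integer_, wt = NA_character_, mut = NA_character_,
                type = "unparsable"))
  }
  dec <- function(code) {
    if (code %in% c("*", "Ter", "X")) return("*")
    if (code %in% c("=", "%3D")) return("=")
    if (nchar(code) == 1 && toupper(code) %in% names(.aa3)) return(toupper(code))
    full <- .aa_full[paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, 3)))]
    if (!is.na(full)) unname(full) else NA_character_
  }
  wt <- dec(m[2])
  pos <- as.integer(m[3])
  mut_code <- m[4]
  if (grepl("fs", mut_code, ignore.case = TRUE)) {
    return(list(position = pos, wt = wt, mut = NA_character_, type = "frameshift"))
  }
  mut <- dec(mut_code)
  type <- if (is.na(wt) || is.na(mut)) "unparsable"
  else if (mut == "*") "stop_gained"
  else if (mut == "=" || identical(wt, mut)) "synonymous"
  else "missense"
  list(position = pos, wt = wt, mut = mut, type = type)
}

#' Parse missense variant notation
#'
#' Accepts the `p.Lys78Glu`, `Lys78Glu` and `K78E` dialects. Stop
#' (`Ter`/`*`) and frameshift (`fs`) variants are typed but carry no
#' mutant residue.
#'
#' @param x character vector of variant strings.
#' @return tibble with `variant`, `position`, `wt`, `mut`, `type`.
#' @examples
#' parse_variant(c("p.Lys78Glu", "K78E", "Trp80Ter"))
#' @export
parse_variant <- function(x) {
  parsed <- purrr::map(x, .parse_one_variant)
  tibble::tibble(
    variant = as.character(x),
    position = purrr::map_int(parsed, "position"),
    wt = purrr::map_chr(parsed, "wt"),
    mut = purrr::map_chr(parsed, "mut"),
    type = purrr::map_chr(parsed, "type")
  )
}

#' Read and normalize a variant table
#'
#' Reads a TSV/CSV with a `variant` column (first column as fallback) and an
#' optional `annotation` column, normalizes the notation, skips
#' stop/frameshift/synonymous rows (count reported), collapses duplicates
#' with a warning and optionally checks the wild-type residue against a
#' reference sequence, erroring with the offending position on mismatch --
#' conflicting wild-type codes in public variant lists must surface, not be
#' silently resolved.
#'
#' @param path file path, or a data frame already holding the columns.
#' @param reference optional reference amino-acid sequence (single string,
#'   precursor numbering from 1).
#' @return tibble with `variant`, `position`, `wt`, `mut`, `annotation`.
#' @export
parse_variant_table <- function(path, reference = NULL) {
  if (is.data.frame(path)) {
    tab <- tibble::as_tibble(path)
  } else {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- tibble::as_tibble(utils::read.table(path, sep = sep, header = TRUE,
                                               stringsAsFactors = FALSE))
  }
  vcol <- if ("variant" %in% names(tab)) "variant" else names(tab)[1]
  out <- parse_variant(tab[[vcol]])
  out$annotation <- if ("annotation" %in% names(tab)) as.character(tab$annotation)
                    else NA_character_
  bad <- out$type == "unparsable"
  if (any(bad)) stop("unparsable variant(s): ", paste(out$variant[bad], collapse = ", "))
  skipped <- out$type != "missense"
  if (any(skipped)) {
    message(sum(skipped), " non-missense row(s) skipped (",
            paste(unique(out$type[skipped]), collapse = ", "), ")")
    out <- out[!skipped, , drop = FALSE]
  }
  key <- paste0(out$wt, out$position, out$mut)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate variant(s) collapsed")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(reference)) {
    ref <- strsplit(reference, "")[[1]]
    off <- out$position > length(ref)
    if (any(off)) stop("variant position(s) beyond sequence end: ",
                       paste(out$position[off], collapse = ", "))
    mism <- out$wt != ref[out$position]
    if (any(mism)) {
      stop("wild-type mismatch at position(s) ",
           paste(sprintf("%d (%s in table, %s in reference)",
                         out$position[mism], out$wt[mism], ref[out$position[mism]]),
                 collapse = "; "))
    }
  }
  dplyr::select(out, "variant", "position", "wt", "mut", "annotation")
}

# --- alignments ------------------------------------------------------------

#' Read a multiple sequence alignment (aligned FASTA)
#'
#' @param path aligned FASTA file, equal-length sequences.
#' @return an `msa` object: named character vector of aligned sequences with
#'   per-sequence column/position maps available via [alignment_map()].
#' @export
read_alignment <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  seqs <- toupper(vapply(fa, function(s) as.character(s)[1], character(1)))
  as_alignment(stats::setNames(seqs, names(fa)))
}

#' @rdname read_alignment
#' @param seqs named character vector of equal-length aligned sequences.
#' @export
as_alignment <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) stop("aligned sequences have unequal lengths")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("sequences must be named")
  structure(list(seqs = seqs, width = nchar(seqs[[1]])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$seqs), x$width))
  invisible(x)
}

#' Column/position map of one alignment sequence
#'
#' @param aln an `msa` from [read_alignment()].
#' @param id sequence name.
#' @return tibble with `column` (alignment column) and `position`
#'   (ungapped residue index); gap columns are absent.
#' @export
alignment_map <- function(aln, id) {
  if (!id %in% names(aln$seqs)) stop("sequence not in alignment: ", id)
  chars <- strsplit(aln$seqs[[id]], "")[[1]]
  resi <- chars != "-" & chars != "."
  tibble::tibble(column = which(resi), position = seq_len(sum(resi)),
                 aa = chars[resi])
}

# Map ungapped positions of `from` onto ungapped positions of `to`;
# positions landing in a gap of `to` map to NA.
.aln_transfer <- function(aln, from, to, positions) {
  mf <- alignment_map(aln, from)
  mt <- alignment_map(aln, to)
  cols <- mf$column[match(positions, mf$position)]
  mt$position[match(cols, mt$column)]
}

# --- predictor tables ------------------------------------------------------

#' Read a stability-predictor table
#'
#' One row per variant with five named predicted stability changes
#' (kcal/mol; negative = destabilizing after sign normalization) and
#' optional per-method significance cutoffs in `cutoff_<method>` columns
#' (absolute kcal/mol, default 0.5 each).
#'
#' @param path TSV file or data frame with a `variant` column and five
#'   numeric method columns.
#' @param methods optional explicit method column names.
#' @param flip_sign character vector of methods whose native convention is
#'   positive-destabilizing; their values are negated at ingestion.
#' @return tibble `variant` + five method columns, with the cutoff vector in
#'   attribute `cutoffs`.
#' @export
read_predictor_table <- function(path, methods = NULL, flip_sign = character()) {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else
    tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE))
  if (!"variant" %in% names(tab)) stop("predictor table needs a 'variant' column")
  cut_cols <- grep("^cutoff_", names(tab), value = TRUE)
  if (is.null(methods)) {
    methods <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], cut_cols)
  }
  if (length(methods) != 5) {
    stop("expected exactly 5 predictor methods, found ", length(methods))
  }
  cutoffs <- stats::setNames(rep(0.5, 5), methods)
  for (m in methods) {
    cc <- paste0("cutoff_", m)
    if (cc %in% names(tab)) cutoffs[m] <- abs(tab[[cc]][1])
  }
  if (any(cutoffs <= 0)) stop("significance cutoffs must be positive")
  for (m in intersect(flip_sign, methods)) tab[[m]] <- -tab[[m]]
  out <- dplyr::select(tab, "variant", dplyr::all_of(methods))
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Read (ingest) precomputed conservation grades
#'
#' Accepts a TSV with columns `position`, `aa`, `grade` (1-9) such as a
#' ConSurf grade export.
#'
#' @param path TSV file or data frame.
#' @return tibble `position`, `aa`, `grade`, `source = "ingested"`.
#' @export
read_conservation_grades <- function(path) {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else
    tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE))
  if (!all(c("position", "grade") %in% names(tab))) {
    stop("grades table needs 'position' and 'grade' columns")
  }
  grade <- as.integer(round(tab$grade))
  if (any(grade < 1 | grade > 9)) stop("grades must lie in 1..9")
  tibble::tibble(
    position = as.integer(tab$position),
    aa = if ("aa" %in% names(tab)) as.character(tab$aa) else NA_character_,
    grade = grade, source = "ingested"
  )
}
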