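#' Run the full variant structural-impact pipeline
#'
#' For every missense variant: builds the rigid-backbone mutant model,
#' computes wild-type and mutant structural profiles, diffs them, attaches
#' the consensus stability call, conservation flag and fold region, and
#' aggregates a cohort summary. Variants whose stated wild-type residue
#' does not match the structure are recorded as failures and skipped; the
#' pipeline continues.
#'
#' @param structure a [protein_structure][new_protein_structure] or a PDB
#'   path.
#' @param variants variant tibble (from [parse_variant_table()]), a path to
#'   a variant table, or a character vector of variant strings.
#' @param predictors optional predictor table (path or tibble, see
#'   [read_predictor_table()]).
#' @param grades optional conservation grades (path or tibble).
#' @param msa,msa_reference optional alignment (path or `msa`) and
#'   reference sequence name, used to compute grades when `grades` is
#'   absent.
#' @param region_overrides named list of region interval overrides (see
#'   [derive_regions()]).
#' @param offset numbering offset applied when `structure` is a path.
#' @param out_dir optional output directory; when given, per-variant
#'   TSV/JSON, cohort summary JSON/Markdown and a static HTML report are
#'   written, each stamped with the package version and a config hash.
#' @param seed integer seed recorded in outputs and passed to the builder.
#' @param config list of threshold overrides: `probe`, `n_points`,
#'   `salt_bridge_cutoff`, `buried_max`, `exposed_min`, `signal_len`,
#'   `conserved_min_grade`, `consensus_cutoffs`.
#' @return (invisibly, when writing) a list: `reports` (impact tibble),
#'   `summary` (`cohort_summary`), `wt_profile`, `regions`, `failures`
#'   (tibble), `config`.
#' @export
run_pipeline <- function(structure, variants, predictors = NULL,
                         grades = NULL, msa = NULL, msa_reference = NULL,
                         region_overrides = NULL, offset = 0L,
                         out_dir = NULL, seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    probe = 1.4, n_points = 960, salt_bridge_cutoff = 4.0,
    buried_max = 20, exposed_min = 50, signal_len = 23,
    conserved_min_grade = 7, consensus_cutoffs = NULL
  ), config)
  stopifnot(all(vapply(
    cfg[c("probe", "n_points", "salt_bridge_cutoff", "buried_max",
          "exposed_min")], function(v) is.numeric(v) && v > 0, logical(1))))

  if (is.character(structure)) structure <- read_pdb(structure, offset = offset)
  if (is.character(variants) && length(variants) == 1 && file.exists(variants)) {
    variants <- parse_variant_table(variants)
  } else if (is.character(variants)) {
    variants <- parse_variant(variants)
  }
  variants <- tibble::as_tibble(variants)
  if (!"annotation" %in% names(variants)) variants$annotation <- NA_character_

  profile_args <- cfg[c("probe", "n_points", "salt_bridge_cutoff",
                        "buried_max", "exposed_min")]
  wt_profile <- do.call(structural_profile, c(list(structure), profile_args))
  regions <- derive_regions(wt_profile$residues, signal_len = cfg$signal_len,
                            overrides = region_overrides)

  cons <- NULL
  if (!is.null(grades)) {
    cons <- if (is.data.frame(grades)) grades else read_conservation_grades(grades)
  } else if (!is.null(msa)) {
    aln <- if (inherits(msa, "msa")) msa else read_alignment(msa)
    cons <- conservation_grades(aln, msa_reference)
  }
  calls <- NULL
  if (!is.null(predictors)) {
    ptab <- if (is.data.frame(predictors)) predictors else
      read_predictor_table(predictors)
    calls <- consensus_stability(ptab, cutoffs = cfg$consensus_cutoffs)
  }

  seqv <- structure_sequence(structure, collapse = FALSE)
  reports <- list(); failures <- list()
  if (nrow(variants) == 0) warning("empty variant table: nothing to do")
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    fail <- function(reason) {
      failures[[length(failures) + 1]] <<- tibble::tibble(
        variant = v$variant, reason = reason)
    }
    wt_here <- unname(seqv[as.character(v$position)])
    if (is.na(wt_here)) { fail("position not in structure"); next }
    if (!identical(wt_here, v$wt)) {
      fail(sprintf("wild-type mismatch: structure has %s", wt_here)); next
    }
    rep1 <- tryCatch({
      mut <- build_mutant(structure, v, seed = seed)
      mut_profile <- do.call(structural_profile, c(list(mut), profile_args))
      diff_profiles(wt_profile, mut_profile, v)
    }, error = function(e) { fail(conditionMessage(e)); NULL })
    if (is.null(rep1)) next
    rep1$annotation <- v$annotation
    reports[[length(reports) + 1]] <- rep1
  }
  if (length(reports) == 0 && nrow(variants) > 0) {
    stop("all variants failed; see failures")
  }
  reports <- if (length(reports)) dplyr::bind_rows(reports) else
    tibble::tibble(variant = character())
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(variant = character(), reason = character())

  if (nrow(reports) > 0) {
    reports$region <- region_of(reports$position, regions)
    reports$conserved_flag <- if (!is.null(cons)) {
      g <- cons$grade[match(reports$position, cons$position)]
      !is.na(g) & g >= cfg$conserved_min_grade
    } else NA
    reports$call <- if (!is.null(calls)) {
      calls$call[match(reports$variant, calls$variant)]
    } else factor(NA, levels = levels(stability_call(0, 0)))
  }
  summary <- if (nrow(reports) > 0) cohort_summary(reports, regions) else NULL

  result <- list(reports = reports, summary = summary,
                 wt_profile = wt_profile, regions = regions,
                 failures = failures, config = cfg, seed = seed)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  if (is.null(out_dir)) result else invisible(result)
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("varstruct"))
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(result$config)
  stamp <- sprintf("# varstruct %s | config %s | seed %d",
                   .pkg_version(), hash, result$seed)
  flat <- .flatten_report(result$reports)
  tsv <- file.path(out_dir, "impact_reports.tsv")
  writeLines(stamp, tsv)
  suppressWarnings(utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  jsonlite::write_json(
    list(package_version = .pkg_version(), config_hash = hash,
         seed = result$seed, config = result$config,
         reports = flat, failures = result$failures),
    file.path(out_dir, "impact_reports.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(result$summary)) {
    jsonlite::write_json(
      list(package_version = .pkg_version(), config_hash = hash,
           seed = result$seed, counts = result$summary$counts,
           per_region = result$summary$per_region),
      file.path(out_dir, "cohort_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_summary(result$summary, md = file.path(out_dir, "cohort_summary.md"))
  }
  utils::write.table(
    tibble::as_tibble(result$regions), file.path(out_dir, "regions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  .write_html_report(result, file.path(out_dir, "report.html"), hash)
  invisible(out_dir)
}

# Minimal static HTML report: one side-by-side WT/mutant row per variant.
.write_html_report <- function(result, path, hash) {
  flat <- .flatten_report(result$reports)
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  cells <- function(row) paste(sprintf("<td>%s</td>", esc(unlist(row))),
                               collapse = "")
  header <- paste(sprintf("<th>%s</th>", names(flat)), collapse = "")
  body <- paste(vapply(seq_len(nrow(flat)), function(i) {
    sprintf("<tr>%s</tr>", cells(flat[i, ]))
  }, character(1)), collapse = "\n")
  summary_html <- if (!is.null(result$summary)) {
    td <- tidy.cohort_summary(result$summary)
    paste(sprintf("<li>%s: %s</li>", esc(td$metric), esc(td$n)), collapse = "\n")
  } else ""
  html <- sprintf(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>\n<title>Variant structural-impact report</title>\n<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font:12px sans-serif}</style>\n</head><body>\n<h1>Variant structural-impact report</h1>\n<p>varstruct %s | config hash %s | seed %d</p>\n<h2>Cohort summary</h2><ul>%s</ul>\n<h2>Per-variant wild-type vs mutant</h2>\n<table><tr>%s</tr>\n%s\n</table></body></html>",
    .pkg_version(), hash, result$seed, summary_html, header, body)
  writeLines(html, path)
  invisible(path)
}
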