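#' Generate a synthetic variant cohort with known consensus ground truth
#'
#' Draws `n` distinct random missense substitutions on `sequence` and a
#' matching five-method stability-predictor table whose values are
#' constructed so that preset fractions of variants resolve to
#' less-stable / more-stable / uncertain under the 3-of-5 consensus rule
#' (cutoff 0.5 kcal/mol per method). The intended call is recorded as
#' ground truth.
#'
#' @param n number of variants (`n <= 19 * nchar(sequence)`).
#' @param seed RNG seed; the same seed yields identical tables.
#' @param sequence reference amino-acid sequence (one-letter string).
#' @param fractions length-3 numeric (sums to 1): target fractions of
#'   `less_stable`, `more_stable`, `uncertain` calls.
#' @return list with `variants` (tibble: `variant`, `position`, `wt`,
#'   `mut`, `annotation`), `predictors` (tibble: `variant` + 5 method
#'   columns, cutoff attribute) and `truth` (tibble: `variant`,
#'   `true_call`).
#' @export
make_variant_cohort <- function(n, seed = 1L,
                                sequence = .chemokine_seq,
                                fractions = c(less_stable = 0.5,
                                              more_stable = 0.2,
                                              uncertain = 0.3)) {
  ref <- strsplit(sequence, "")[[1]]
  if (n > 19 * length(ref)) stop("n exceeds the number of possible substitutions")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  methods <- paste0("method", 1:5)
  cutoff <- 0.5
  if (n == 0) {
    return(list(
      variants = tibble::tibble(variant = character(), position = integer(),
                                wt = character(), mut = character(),
                                annotation = character()),
      predictors = structure(
        tibble::as_tibble(c(list(variant = character()),
                            stats::setNames(rep(list(numeric()), 5), methods))),
        cutoffs = stats::setNames(rep(cutoff, 5), methods)),
      truth = tibble::tibble(variant = character(), true_call = character())
    ))
  }
  all_pos <- rep(seq_along(ref), each = 19)
  all_mut <- unlist(lapply(ref, function(w) setdiff(names(.aa3), w)))
  pick <- sample(length(all_pos), n)
  pos <- all_pos[pick]; mut <- all_mut[pick]; wt <- ref[pos]
  variant <- sprintf("%s%d%s", wt, pos, mut)

  calls <- sample(rep(names(fractions), times = round(fractions * n))[
    seq_len(n) + 0], n)
  if (length(calls) < n) calls <- c(calls, rep("uncertain", n - length(calls)))

  draw_row <- function(call) {
    ddg <- numeric(5)
    if (call == "uncertain") {
      nl <- sample(0:2, 1); nm <- sample(0:2, 1)
      idx <- sample(5)
      ddg[idx[seq_len(nl)]] <- -(cutoff + stats::rexp(nl, 1.5))
      if (nm > 0) ddg[idx[nl + seq_len(nm)]] <- cutoff + stats::rexp(nm, 1.5)
      rest <- idx[-seq_len(nl + nm)]
      ddg[rest] <- stats::runif(length(rest), -0.9, 0.9) * cutoff
    } else {
      sgn <- if (call == "less_stable") -1 else 1
      nv <- sample(3:5, 1)
      idx <- sample(5)
      ddg[idx[seq_len(nv)]] <- sgn * (cutoff + stats::rexp(nv, 1.5))
      rest <- idx[-seq_len(nv)]
      # remainder abstains or votes the other way (cannot reach 3)
      for (j in rest) {
        ddg[j] <- if (stats::runif(1) < 0.5) {
          stats::runif(1, -0.9, 0.9) * cutoff
        } else -sgn * (cutoff + stats::rexp(1, 1.5))
      }
    }
    ddg
  }
  M <- t(vapply(calls, draw_row, numeric(5)))
  predictors <- tibble::as_tibble(cbind(
    tibble::tibble(variant = variant),
    stats::setNames(as.data.frame(M), methods)
  ))
  attr(predictors, "cutoffs") <- stats::setNames(rep(cutoff, 5), methods)
  list(
    variants = tibble::tibble(variant = variant, position = pos, wt = wt,
                              mut = mut, annotation = NA_character_),
    predictors = predictors,
    truth = tibble::tibble(variant = variant, true_call = calls)
  )
}
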