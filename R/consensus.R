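#' Consensus stability classification (3-of-5 rule)
#'
#' Each predictor votes "less stable" when its predicted stability change
#' is `<= -cutoff`, "more stable" when `>= +cutoff` (kcal/mol; negative =
#' destabilizing after ingestion normalization), and abstains otherwise.
#' A variant is called `less_stable` or `more_stable` when at least 3 of
#' the 5 methods agree beyond their per-method significance cutoffs, else
#' `uncertain`. Missing values abstain and are counted in `n_missing`.
#'
#' @param predictors tibble with a `variant` column and five numeric method
#'   columns (see [read_predictor_table()]), or any data frame shaped that
#'   way.
#' @param cutoffs named (or unnamed, recycled) positive cutoff vector;
#'   default the table's `cutoffs` attribute, else 0.5 kcal/mol each.
#' @return the input tibble plus `votes_less`, `votes_more`, `n_missing`
#'   and `call` (factor `less_stable`/`more_stable`/`uncertain`).
#' @examples
#' tab <- tibble::tibble(variant = "K78E", m1 = -1.2, m2 = -0.8, m3 = -1.5,
#'                       m4 = 0.1, m5 = -0.05)
#' consensus_stability(tab)
#' @export
consensus_stability <- function(predictors, cutoffs = NULL) {
  predictors <- tibble::as_tibble(predictors)
  methods <- setdiff(names(predictors)[vapply(predictors, is.numeric, logical(1))],
                     c("position", "votes_less", "votes_more", "n_missing"))
  if (length(methods) != 5) {
    stop("expected exactly 5 predictor columns, found ", length(methods))
  }
  if (is.null(cutoffs)) cutoffs <- attr(predictors, "cutoffs")
  if (is.null(cutoffs)) cutoffs <- rep(0.5, 5)
  if (length(cutoffs) == 1) cutoffs <- rep(cutoffs, 5)
  if (!is.null(names(cutoffs)) && all(methods %in% names(cutoffs))) {
    cutoffs <- cutoffs[methods]
  }
  stopifnot(length(cutoffs) == 5, all(cutoffs > 0))
  M <- as.matrix(predictors[, methods])
  less <- sweep(M, 2, -abs(cutoffs), "<=")
  more <- sweep(M, 2, abs(cutoffs), ">=")
  less[is.na(less)] <- FALSE
  more[is.na(more)] <- FALSE
  predictors$votes_less <- as.integer(rowSums(less))
  predictors$votes_more <- as.integer(rowSums(more))
  predictors$n_missing <- as.integer(rowSums(is.na(M)))
  predictors$call <- stability_call(predictors$votes_less, predictors$votes_more)
  predictors
}

#' @rdname consensus_stability
#' @param votes_less,votes_more integer vote counts.
#' @export
stability_call <- function(votes_less, votes_more) {
  factor(
    ifelse(votes_less >= 3, "less_stable",
           ifelse(votes_more >= 3, "more_stable", "uncertain")),
    levels = c("less_stable", "more_stable", "uncertain")
  )
}
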