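#' Hypergeometric subset p-value
#'
#' Probability of drawing, by chance, `k` targets out of a universe of `m`
#' such that all of them belong to the `q` targets whose correlation reaches
#' the subset's minimum: `p = C(q, k) / C(m, k)`, computed in log space for
#' stability.
#'
#' @param q Number of universe targets at or above the threshold.
#' @param m Universe size (number of targets in the network).
#' @param k Subset size, `0 <= k <= q <= m`.
#' @return The p-value in `[0, 1]`.
#' @examples
#' subset_pvalue(q = 5, m = 20, k = 3)  # 10 / 1140
#' @export
subset_pvalue <- function(q, m, k) {
  if (m < 1 || k < 0 || q < 0) dtc_abort_param("q, m, k must be non-negative, m >= 1")
  if (q > m || k > q) {
    dtc_abort(sprintf("invalid draw: need k <= q <= m, got k=%d q=%d m=%d",
                      k, q, m),
              class = "dtc_domain_error")
  }
  if (k == 0) return(1)
  exp(lchoose(q, k) - lchoose(m, k))
}

#' Minimum-p-value predicted-target subset for one drug
#'
#' Sweeps every distinct correlation value among the drug's candidate
#' predictions as a minimum-correlation threshold. For each threshold
#' `theta` the subset `M = {candidates with correlation >= theta}` has size
#' `k`, the universe count `q` is the number of network targets with
#' correlation `>= theta` (tie-inclusive; set `strict = TRUE` for a strict
#' `>` count, which can yield degenerate `q < k` subsets with p = 0), and
#' `p = C(q, k) / C(m, k)`. The subset with the minimal p-value is returned;
#' ties prefer the larger subset, then the smaller threshold. Reported
#' p-values are raw — no multiple-testing correction is applied.
#'
#' @param drug_id Drug identifier (carried through to the output).
#' @param candidates Tibble with columns `target_id`, `correlation` — the
#'   drug's ranked candidate predictions and their correlations.
#' @param universe_corrs Named numeric vector: correlation of *every* target
#'   in the network with this drug's validated targets.
#' @param strict Count `q` with a strict `>` threshold (default `FALSE`).
#' @return A one-row tibble `drug_id`, `k`, `q`, `m`, `min_correlation`,
#'   `p_value`, `members` (list column of target identifiers); zero rows if
#'   the drug has no candidates.
#' @export
best_subset <- function(drug_id, candidates, universe_corrs, strict = FALSE) {
  candidates <- as_tibble(candidates)
  m <- length(universe_corrs)
  if (nrow(candidates) == 0) {
    return(tibble(drug_id = character(), k = integer(), q = integer(),
                  m = integer(), min_correlation = double(),
                  p_value = double(), members = list()))
  }
  thresholds <- sort(unique(candidates$correlation))
  sweep <- purrr::map(thresholds, function(theta) {
    members <- candidates$target_id[candidates$correlation >= theta]
    k <- length(members)
    q <- if (strict) sum(universe_corrs > theta) else sum(universe_corrs >= theta)
    p <- if (k <= q) subset_pvalue(q, m, k) else 0
    tibble(drug_id = drug_id, k = k, q = as.integer(q), m = m,
           min_correlation = theta, p_value = p, members = list(members))
  })
  sweep <- bind_rows(sweep)
  sweep <- sweep[order(sweep$p_value, -sweep$k, sweep$min_correlation), ]
  sweep[1, ]
}

#' Score predictions with ontology correlations and subset p-values
#'
#' The full significance stage: computes, for every drug with candidate
#' predictions, the correlation of each candidate (and of every network
#' target, forming the universe) with the drug's validated targets, then
#' selects the candidate subset minimizing the hypergeometric p-value.
#'
#' @param predictions Output of [rank_predictions()].
#' @param net The [dti_network()] the predictions came from.
#' @param dag An [ontology_dag()]; augmented automatically if it is not yet.
#' @param annotations Annotation tibble (`target_id`, `term_id`).
#' @param strict Passed to [best_subset()].
#' @return A tibble `drug_id`, `target_id`, `score`, `correlation`,
#'   `in_best_subset`, `p_value`; `p_value` is the drug's minimal subset
#'   p-value, repeated on each of the drug's rows.
#' @export
score_significance <- function(predictions, net, dag, annotations,
                               strict = FALSE) {
  stopifnot(inherits(net, "dti_network"), inherits(dag, "ontology_dag"))
  predictions <- as_tibble(predictions)
  check_columns(predictions, c("drug_id", "target_id", "score"), "predictions")
  if (is.null(dag$dummy_root)) dag <- augment_dag(dag)
  corr <- correlation_matrix(net, annotations, dag)
  out <- purrr::map(unique(predictions$drug_id), function(d) {
    cand <- predictions[predictions$drug_id == d, ]
    cand$correlation <- corr[d, cand$target_id]
    best <- best_subset(d, cand[, c("target_id", "correlation")],
                        corr[d, ], strict = strict)
    if (nrow(best) == 0) {
      cand$in_best_subset <- logical(nrow(cand))
      cand$p_value <- rep(NA_real_, nrow(cand))
    } else {
      cand$in_best_subset <- cand$target_id %in% best$members[[1]]
      cand$p_value <- best$p_value
    }
    cand
  })
  bind_rows(out)[, c("drug_id", "target_id", "score", "correlation",
                     "in_best_subset", "p_value")]
}

#' Read and write prediction tables
#'
#' Predictions are TSV with columns `drug_id`, `target_id`, `score`,
#' `correlation`, `in_best_subset`, `p_value` in that order; a written file
#' re-read with [read_predictions()] reproduces the tibble. A bare
#' [rank_predictions()] table may also be written: missing significance
#' columns are filled with `NA`/`FALSE`.
#'
#' @param predictions Prediction tibble.
#' @param path File path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(predictions, path) {
  predictions <- as_tibble(predictions)
  if (!"correlation" %in% names(predictions))
    predictions$correlation <- NA_real_
  if (!"in_best_subset" %in% names(predictions))
    predictions$in_best_subset <- FALSE
  if (!"p_value" %in% names(predictions))
    predictions$p_value <- NA_real_
  cols <- c("drug_id", "target_id", "score", "correlation",
            "in_best_subset", "p_value")
  check_columns(predictions, cols, "predictions")
  readr::write_tsv(predictions[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccddld", progress = FALSE)
  check_columns(df, c("drug_id", "target_id", "score", "correlation",
                      "in_best_subset", "p_value"),
                sprintf("predictions '%s'", path))
  df
}
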