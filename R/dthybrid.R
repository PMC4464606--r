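#' Drug similarity induced by target-profile similarity
#'
#' Projects a target-target similarity matrix onto the drug side of the
#' bipartite network:
#' \deqn{\tilde S_{ij} = \frac{\sum_{l,s} a_{il} a_{js} S^T_{ls}}
#'                            {k(d_i)\,k(d_j)}}
#' where `a` is the binary adjacency and `k(d)` a drug's degree. The diagonal
#' measures a drug's own target-profile coherence and is *not* forced to 1.
#'
#' @param net A [dti_network()].
#' @param s_target Target similarity matrix indexed by `net$target_ids`.
#' @return A symmetric drug-by-drug matrix with entries in `[0, 1]`.
#' @export
target_induced_drug_similarity <- function(net, s_target) {
  a <- net$adjacency
  s_target <- s_target[net$target_ids, net$target_ids, drop = FALSE]
  kd <- rowSums(a)
  if (any(kd == 0)) {
    dtc_abort("drug with zero interactions; rebuild the network first")
  }
  s <- (a %*% s_target %*% t(a)) / outer(kd, kd)
  dimnames(s) <- list(net$drug_ids, net$drug_ids)
  s
}

#' Mix supplied and target-induced drug similarity
#'
#' Entrywise convex combination `alpha_mix * s_drug + (1 - alpha_mix) *
#' s_induced`. With `alpha_mix = 1` only the supplied chemical similarity is
#' used; with `alpha_mix = 0` only the similarity induced by shared/similar
#' targets.
#'
#' @param s_drug Supplied drug similarity matrix.
#' @param s_induced Output of [target_induced_drug_similarity()].
#' @param alpha_mix Mixing weight in `[0, 1]`.
#' @return Combined drug similarity matrix.
#' @export
combined_drug_similarity <- function(s_drug, s_induced, alpha_mix) {
  if (!is.numeric(alpha_mix) || alpha_mix < 0 || alpha_mix > 1) {
    dtc_abort_param("alpha_mix must be in [0, 1]")
  }
  if (!identical(dim(s_drug), dim(s_induced))) {
    dtc_abort_param("similarity matrices have mismatched dimensions")
  }
  alpha_mix * s_drug + (1 - alpha_mix) * s_induced
}

#' DT-Hybrid resource-transfer matrix
#'
#' The drug-by-drug transfer matrix of the similarity-weighted hybrid
#' two-step resource spreading:
#' \deqn{W_{ij} = \frac{S_{ij}}{k(d_i)^{1-\lambda}\,k(d_j)^{\lambda}}
#'       \sum_l \frac{a_{il} a_{jl}}{k(t_l)}}
#' `lambda_hybrid = 1` recovers the mass-conserving ProbS normalization
#' (columns of `W` sum to 1 when `S` is all ones); `lambda_hybrid = 0` the
#' heat-spreading HeatS normalization; intermediate values interpolate.
#'
#' @param net A [dti_network()].
#' @param s_combined Drug similarity matrix (all-ones for the pure hybrid).
#' @param lambda_hybrid Degree-normalization exponent in `[0, 1]`.
#' @return A drug-by-drug transfer matrix `W`.
#' @export
transfer_matrix <- function(net, s_combined, lambda_hybrid) {
  if (!is.numeric(lambda_hybrid) || lambda_hybrid < 0 || lambda_hybrid > 1) {
    dtc_abort_param("lambda_hybrid must be in [0, 1]")
  }
  a <- net$adjacency
  kd <- rowSums(a)
  kt <- colSums(a)
  if (any(kd == 0) || any(kt == 0)) {
    dtc_abort("network has zero-degree drugs or targets")
  }
  shared <- a %*% (t(a) / kt)           # sum_l a_il a_jl / k(t_l)
  w <- s_combined * shared /
    outer(kd^(1 - lambda_hybrid), kd^lambda_hybrid)
  dimnames(w) <- list(net$drug_ids, net$drug_ids)
  w
}

#' DT-Hybrid recommendation scores
#'
#' Runs the full similarity-weighted two-step resource transfer: resources
#' start on each drug's validated targets, spread to drugs, are re-weighted
#' by the combined drug similarity, and return to targets. Omitted similarity
#' matrices default to all-ones, which reduces the method to the plain
#' hybrid network-based inference recommender.
#'
#' @param net A [dti_network()], or a data frame of `drug_id`/`target_id`
#'   edges which is passed through [dti_network()].
#' @param s_drug Optional drug similarity matrix over `net$drug_ids`.
#' @param s_target Optional target similarity matrix over `net$target_ids`.
#' @param lambda_hybrid Degree-normalization exponent, default `0.5`.
#' @param alpha_mix Weight of the supplied drug similarity against the
#'   target-induced one, default `0.4`.
#' @return A `dthybrid_fit` object holding the score matrix (`scores`), the
#'   transfer matrix (`w`), the network and the parameters. Use [tidy()] for
#'   a long tibble of scores and [rank_predictions()] for ranked novel
#'   predictions.
#' @examples
#' net <- dti_network(tibble::tibble(
#'   drug_id = c("d1", "d2", "d2"), target_id = c("t1", "t1", "t2")
#' ))
#' fit <- dthybrid(net, lambda_hybrid = 1)
#' fit$scores
#' @export
dthybrid <- function(net, s_drug = NULL, s_target = NULL,
                     lambda_hybrid = 0.5, alpha_mix = 0.4) {
  if (is.data.frame(net)) net <- dti_network(net)
  stopifnot(inherits(net, "dti_network"))
  nd <- length(net$drug_ids)
  nt <- length(net$target_ids)
  ones_d <- matrix(1, nd, nd, dimnames = list(net$drug_ids, net$drug_ids))
  ones_t <- matrix(1, nt, nt, dimnames = list(net$target_ids, net$target_ids))
  s_drug <- s_drug %||% ones_d
  s_target <- s_target %||% ones_t
  s_induced <- target_induced_drug_similarity(net, s_target)
  s_combined <- combined_drug_similarity(s_drug, s_induced, alpha_mix)
  w <- transfer_matrix(net, s_combined, lambda_hybrid)
  scores <- w %*% net$adjacency
  if (any(!is.finite(scores)) || any(scores < 0)) {
    dtc_abort("non-finite or negative recommendation scores")
  }
  structure(
    list(scores = scores, w = w, net = net,
         params = list(lambda_hybrid = lambda_hybrid, alpha_mix = alpha_mix)),
    class = "dthybrid_fit"
  )
}

#' @export
print.dthybrid_fit <- function(x, ...) {
  cat(sprintf(
    "<dthybrid_fit> %d drugs x %d targets (lambda = %g, alpha = %g)\n",
    nrow(x$scores), ncol(x$scores),
    x$params$lambda_hybrid, x$params$alpha_mix
  ))
  invisible(x)
}

#' @rdname dthybrid
#' @param x A `dthybrid_fit`.
#' @param ... Unused.
#' @export
tidy.dthybrid_fit <- function(x, ...) {
  tibble(
    drug_id = rep(rownames(x$scores), times = ncol(x$scores)),
    target_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores),
    known = as.vector(x$net$adjacency) == 1L
  )
}

#' @rdname dthybrid
#' @export
glance.dthybrid_fit <- function(x, ...) {
  tibble(
    n_drugs = nrow(x$scores),
    n_targets = ncol(x$scores),
    n_interactions = sum(x$net$adjacency),
    lambda_hybrid = x$params$lambda_hybrid,
    alpha_mix = x$params$alpha_mix,
    total_score = sum(x$scores)
  )
}

#' Rank novel predictions per drug
#'
#' Validated interactions are excluded (they are not predictions); the
#' remaining targets are sorted by score descending with ties broken by
#' target identifier, and the list truncated to `top_n` per drug.
#'
#' @param fit A `dthybrid_fit` from [dthybrid()].
#' @param top_n Maximum number of candidate predictions kept per drug
#'   (default 20).
#' @return A tibble `drug_id`, `target_id`, `score`, `rank`, ordered by drug
#'   (network order) then rank.
#' @export
rank_predictions <- function(fit, top_n = 20) {
  stopifnot(inherits(fit, "dthybrid_fit"))
  if (!is.numeric(top_n) || top_n < 1) {
    dtc_abort_param("top_n must be a positive integer")
  }
  scores <- fit$scores
  a <- fit$net$adjacency
  out <- purrr::map(rownames(scores), function(d) {
    novel <- colnames(scores)[a[d, ] == 0L]
    if (length(novel) == 0) {
      return(tibble(drug_id = character(), target_id = character(),
                    score = double(), rank = integer()))
    }
    s <- scores[d, novel]
    ord <- order(-s, novel)
    keep <- head(ord, top_n)
    tibble(drug_id = d, target_id = novel[keep], score = unname(s[keep]),
           rank = seq_along(keep))
  })
  bind_rows(out)
}
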