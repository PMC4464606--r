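test_that("target-induced drug similarity matches the hand-evaluated double sum", {
  net <- tiny_net()
  st <- named_matrix(c(1, 0.5, 0.5, 1), c("t1", "t2"))
  s <- target_induced_drug_similarity(net, st)
  expect_equal(unname(s), matrix(c(1, 0.75, 0.75, 0.75), 2), tolerance = 1e-12)
})

test_that("induced similarity endpoints: disjoint profiles and all-ones", {
  # each drug its own target, identity target similarity: no off-diagonal
  net <- dti_network(tibble::tibble(drug_id = c("d1", "d2"),
                                    target_id = c("t1", "t2")))
  st_id <- named_matrix(c(1, 0, 0, 1), c("t1", "t2"))
  s <- target_induced_drug_similarity(net, st_id)
  expect_equal(s["d1", "d2"], 0)
  # all-ones target similarity induces all-ones drug similarity
  net2 <- tiny_net()
  ones <- named_matrix(rep(1, 4), c("t1", "t2"))
  expect_equal(unname(target_induced_drug_similarity(net2, ones)),
               matrix(1, 2, 2))
})

test_that("alpha mixing interpolates between the two similarity sources", {
  sd <- named_matrix(c(1, 0.2, 0.2, 1), c("d1", "d2"))
  si <- named_matrix(c(1, 0.75, 0.75, 0.75), c("d1", "d2"))
  expect_equal(combined_drug_similarity(sd, si, 1), sd)
  expect_equal(combined_drug_similarity(sd, si, 0), si)
  expect_equal(unname(combined_drug_similarity(sd, si, 0.5)),
               matrix(c(1, 0.475, 0.475, 0.875), 2))
  expect_error(combined_drug_similarity(sd, si, 1.2),
               class = "dtc_parameter_error")
})

test_that("transfer matrix reproduces the ProbS limit and its dual", {
  net <- tiny_net()
  ones <- named_matrix(rep(1, 4), c("d1", "d2"))
  w1 <- transfer_matrix(net, ones, 1)
  expect_equal(unname(w1), matrix(c(0.5, 0.5, 0.25, 0.75), 2),
               tolerance = 1e-12)
  expect_equal(colSums(w1), c(d1 = 1, d2 = 1), tolerance = 1e-12)
  w0 <- transfer_matrix(net, ones, 0)
  expect_equal(w0, t(w1), tolerance = 1e-12)
  # degenerate single-interaction network
  net1 <- dti_network(tibble::tibble(drug_id = "d", target_id = "t"))
  expect_equal(unname(transfer_matrix(net1, matrix(1, 1, 1), 0.3)),
               matrix(1))
  expect_error(transfer_matrix(net, ones, 1.5),
               class = "dtc_parameter_error")
})

test_that("recommendation scores conserve resources in the ProbS limit", {
  net <- tiny_net()
  fit <- dthybrid(net, lambda_hybrid = 1)
  expect_equal(unname(fit$scores), matrix(c(0.75, 1.25, 0.25, 0.75), 2),
               tolerance = 1e-12)
  expect_equal(sum(fit$scores), 3, tolerance = 1e-12)
  # validated pairs always keep strictly positive score
  expect_true(all(fit$scores[fit$net$adjacency == 1L] > 0))
})

test_that("ranking masks known interactions and breaks ties by target id", {
  net <- tiny_net()
  fit <- dthybrid(net, lambda_hybrid = 1)
  preds <- rank_predictions(fit, top_n = 5)
  expect_equal(preds$drug_id, "d1")
  expect_equal(preds$target_id, "t2")
  expect_equal(preds$score, 0.25, tolerance = 1e-12)
  expect_error(rank_predictions(fit, top_n = 0),
               class = "dtc_parameter_error")

  # equal scores order by target id: symmetric 2-drug, 3-target network
  net2 <- dti_network(tibble::tibble(
    drug_id = c("d1", "d2", "d2", "d2"),
    target_id = c("t1", "t1", "t2", "t3")
  ))
  fit2 <- dthybrid(net2, lambda_hybrid = 0.5)
  p2 <- rank_predictions(fit2, top_n = 5)
  d1 <- p2[p2$drug_id == "d1", ]
  expect_equal(d1$target_id, sort(d1$target_id))
  expect_equal(d1$score[1], d1$score[2])
})

test_that("recommend() matches the naive triple-loop oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n_d <- sample(3:15, 1)
    n_t <- sample(3:15, 1)
    a <- random_adjacency(n_d, n_t, runif(1, 0.2, 0.6))
    sd <- random_similarity(rownames(a))
    st <- random_similarity(colnames(a))
    lambda <- runif(1)
    alpha <- runif(1)
    fit <- dthybrid(net_from_adjacency(a), sd, st,
                    lambda_hybrid = lambda, alpha_mix = alpha)
    oracle <- naive_recommend(a, sd, st, lambda, alpha)
    expect_lt(max(abs(align_scores(fit$scores, oracle) - oracle)), 1e-10)
  }
})

test_that("increasing one similarity entry never lowers a linked score", {
  set.seed(77)
  a <- random_adjacency(6, 8, 0.4)
  net <- net_from_adjacency(a)
  sd <- random_similarity(rownames(a))
  st <- random_similarity(colnames(a))
  base <- dthybrid(net, sd, st, lambda_hybrid = 0.5, alpha_mix = 0.6)$scores
  sd2 <- sd
  bump <- min(1, sd["d01", "d02"] + 0.2)
  sd2["d01", "d02"] <- sd2["d02", "d01"] <- bump
  bumped <- dthybrid(net, sd2, st, lambda_hybrid = 0.5, alpha_mix = 0.6)$scores
  linked <- which(a["d02", ] == 1L)
  expect_true(all(bumped["d01", linked] >= base["d01", linked] - 1e-12))
})

test_that("relabeling drugs and targets permutes scores identically", {
  set.seed(5)
  a <- random_adjacency(5, 6, 0.4)
  net <- net_from_adjacency(a)
  sd <- random_similarity(rownames(a))
  st <- random_similarity(colnames(a))
  fit <- dthybrid(net, sd, st, lambda_hybrid = 0.3, alpha_mix = 0.5)
  pd <- sample(rownames(a))
  pt <- sample(colnames(a))
  a2 <- a[pd, pt]
  fit2 <- dthybrid(net_from_adjacency(a2), sd[pd, pd], st[pt, pt],
                   lambda_hybrid = 0.3, alpha_mix = 0.5)
  expect_equal(align_scores(fit2$scores, fit$scores), fit$scores,
               tolerance = 1e-12)
})

test_that("tidy and glance summarize a fit", {
  fit <- dthybrid(tiny_net(), lambda_hybrid = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$known), 3)
  gl <- glance(fit)
  expect_equal(gl$n_interactions, 3)
  expect_equal(gl$total_score, 3, tolerance = 1e-12)
})
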