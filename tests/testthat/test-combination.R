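toy_index <- function() {
  # T1 -> M -> G1, T2 -> G2, T1--T2 complex link, G3 unreachable
  g <- pathway_graph(tibble::tibble(
    source = c("T1", "M", "T2", "T1"),
    target = c("M", "G1", "G2", "T2"),
    interaction_type = c("activates", "activates", "activates",
                         "complex-membership"),
    directed = c(TRUE, TRUE, TRUE, FALSE),
    pathway_ids = as.list(c("p1", "p1", "p2", "p1"))
  ))
  build_path_index(g)
}

toy_drug_map <- function() {
  tibble::tibble(
    target_id = c("T1", "T2"),
    drug_id = c("DB1", "DB2"),
    status = c("validated", "predicted"),
    score = c(NA_real_, 0.7)
  )
}

test_that("gene mapping canonicalizes and partitions", {
  idx <- toy_index()
  m <- map_genes(c("g1", "G2", "NOSUCH"), idx)
  expect_setequal(m$known, c("G1", "G2"))
  expect_equal(m$unknown, "NOSUCH")
  expect_equal(map_genes("zz", idx)$known, character())
})

test_that("candidates require a drug and a gene within the range", {
  idx <- toy_index()
  cands <- find_candidate_targets(idx, c("G1", "G2"), c(1, 9), toy_drug_map())
  expect_setequal(cands$target_id, c("T1", "T2"))
  t1 <- cands$covered[[which(cands$target_id == "T1")]]
  # the undirected complex link lets T1 reach G2 through T2 as well
  expect_setequal(t1$gene, c("G1", "G2"))
  expect_equal(t1$distance[t1$gene == "G1"], 2L)
  # range [0,0]: only genes that are themselves druggable targets qualify
  none <- find_candidate_targets(idx, c("G1", "G2"), c(0, 0), toy_drug_map())
  expect_equal(nrow(none), 0)
  dm <- dplyr::bind_rows(toy_drug_map(), tibble::tibble(
    target_id = "G1", drug_id = "DB3", status = "validated", score = NA_real_
  ))
  self <- find_candidate_targets(idx, c("G1", "G2"), c(0, 0), dm)
  expect_equal(self$target_id, "G1")
  expect_equal(self$covered[[1]]$distance, 0L)
  expect_error(find_candidate_targets(idx, "G1", c(3, 1), toy_drug_map()),
               class = "dtc_parameter_error")
})

test_that("the pair filter keeps partnered targets and lone singletons", {
  idx <- toy_index()
  cands <- find_candidate_targets(idx, c("G1", "G2"), c(1, 9), toy_drug_map())
  kept <- apply_pair_filter(cands, idx, c(1, 5))
  expect_setequal(kept$candidates$target_id, c("T1", "T2"))
  expect_equal(nrow(kept$pairs), 1)
  expect_equal(kept$pairs$distance, 1)  # the undirected complex link
  # a single candidate survives regardless of the pair range
  solo <- cands[cands$target_id == "T1", ]
  expect_equal(apply_pair_filter(solo, idx, c(5, 9))$candidates$target_id,
               "T1")
  # mutually unreachable candidates are all removed, with a warning
  far <- pathway_graph(tibble::tibble(
    source = c("T1", "T2"), target = c("G1", "G2"),
    interaction_type = "activates", directed = TRUE,
    pathway_ids = as.list(c("p1", "p1"))
  ))
  far_idx <- build_path_index(far)
  far_cands <- find_candidate_targets(far_idx, c("G1", "G2"), c(1, 9),
                                      toy_drug_map())
  expect_warning(res <- apply_pair_filter(far_cands, far_idx, c(1, 5)),
                 "pair range")
  expect_equal(nrow(res$candidates), 0)
})

test_that("greedy set cover matches the worked examples and stays bounded", {
  # T1={g1,g2}, T2={g2,g3}, T3={g3}: greedy = {T1, T2}, optimum 2
  cands <- make_candidates(list(T1 = c("g1", "g2"), T2 = c("g2", "g3"),
                                T3 = "g3"))
  expect_equal(greedy_min_target_set(cands), c("T1", "T2"))

  # single target covering everything
  expect_equal(greedy_min_target_set(make_candidates(list(T9 = c("a", "b")))),
               "T9")
  expect_equal(greedy_min_target_set(cands[0, ]), character())

  # classic greedy-suboptimal instance stays within the harmonic bound
  sets <- list(S1 = c("1", "2", "3", "4"), S2 = c("1", "2", "5"),
               S3 = c("3", "4", "6"), S4 = "5", S5 = "6")
  greedy <- greedy_min_target_set(make_candidates(sets))
  expect_equal(greedy[1], "S1")
  opt <- brute_min_cover(sets)
  h <- sum(1 / seq_len(max(lengths(sets))))
  expect_gte(length(greedy), opt)
  expect_lte(length(greedy), h * opt)
  # the union of the greedy selection covers everything coverable
  expect_setequal(unique(unlist(sets[greedy])), unique(unlist(sets)))
})

test_that("greedy ties prefer smaller covering distance then smaller id", {
  sets <- list(B = c("g1", "g2"), A = c("g1", "g2"))
  near <- make_candidates(sets, distances = list(c(5L, 5L), c(1L, 1L)))
  expect_equal(greedy_min_target_set(near), "A")
  even <- make_candidates(sets, distances = list(c(1L, 1L), c(1L, 1L)))
  expect_equal(greedy_min_target_set(even), "A")
})

test_that("greedy stays within the harmonic bound on random set systems", {
  set.seed(808)
  for (rep in 1:25) {
    n_sets <- sample(3:8, 1)
    universe <- sprintf("g%d", seq_len(sample(4:8, 1)))
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(seq_along(universe), 1))
    })
    names(sets) <- sprintf("S%02d", seq_len(n_sets))
    greedy <- greedy_min_target_set(make_candidates(sets))
    coverable <- unique(unlist(sets))
    expect_setequal(unique(unlist(sets[greedy])), coverable)
    opt <- brute_min_cover(sets)
    h <- sum(1 / seq_len(max(lengths(sets))))
    expect_lte(length(greedy), h * opt)
  }
})

test_that("a full query composes the stages and reports unreachable genes", {
  idx <- toy_index()
  res <- run_combination_query(c("g1", "G2", "G3", "NOPE"), idx,
                               toy_drug_map())
  expect_s3_class(res, "combination_result")
  expect_setequal(res$candidates$target_id, c("T1", "T2"))
  # both candidates cover both genes (distance sums tie), so the greedy
  # cover is the lexicographically first single target
  expect_equal(res$minimal_set, "T1")
  expect_setequal(res$unreachable_genes, c("NOPE", "G3"))
  expect_equal(res$status, "ok")
  td <- tidy(res)
  expect_true(all(c("target_id", "gene", "distance", "drug_id", "status",
                    "score", "in_minimal_set") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_candidates, 2)

  # all genes unknown
  none <- run_combination_query(c("x", "y"), idx, toy_drug_map())
  expect_equal(nrow(none$candidates), 0)
  expect_setequal(none$unreachable_genes, c("x", "y"))
  expect_match(none$status, "no input gene")
})

test_that("query results match the independent brute-force companion", {
  for (seed in c(7, 13, 29)) {
    case <- gen_pathway_case(seed = seed)
    raw <- read_pathway_edges(write_pathway_case_tsv(case))
    idx <- build_path_index(build_collapsed_graph(raw, case$entity_map))
    res <- run_combination_query(case$genes, idx, case$drug_map)
    got <- tidy(res) |>
      dplyr::distinct(.data$target_id, .data$gene, .data$distance) |>
      dplyr::arrange(.data$target_id, .data$gene)
    want <- dplyr::arrange(case$expected$candidates, .data$target_id,
                           .data$gene)
    expect_equal(as.data.frame(got), as.data.frame(want))
    opt <- case$expected$optimal_cover_size
    expect_gte(length(res$minimal_set), opt)
    if (nrow(res$candidates) > 0) {
      h <- sum(1 / seq_len(max(res$candidates$n_covered)))
      expect_lte(length(res$minimal_set), h * opt)
    }
  }
})

test_that("widening the direct-indirect range never removes a candidate", {
  case <- gen_pathway_case(seed = 21)
  raw <- read_pathway_edges(write_pathway_case_tsv(case))
  idx <- build_path_index(build_collapsed_graph(raw, case$entity_map))
  genes <- canonical_entity(case$genes)
  narrow <- find_candidate_targets(idx, genes, c(1, 2), case$drug_map)
  wide <- find_candidate_targets(idx, genes, c(0, 9), case$drug_map)
  expect_true(all(narrow$target_id %in% wide$target_id))
})

test_that("combination results round-trip their flat table", {
  idx <- toy_index()
  res <- run_combination_query(c("G1", "G2", "G3"), idx, toy_drug_map())
  p <- tempfile(fileext = ".tsv")
  write_combination(res, p)
  back <- read_combination(p)
  expect_equal(back$minimal_set, res$minimal_set)
  expect_setequal(back$unreachable_genes, res$unreachable_genes)
  expect_equal(back$table$target_id, res$candidates$target_id)
  expect_equal(back$table$in_minimal_set,
               res$candidates$target_id %in% res$minimal_set)
})
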