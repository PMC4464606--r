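chain_graph <- function(n, prefix = "N") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  pathway_graph(tibble::tibble(
    source = ids[-n], target = ids[-1], interaction_type = "activates",
    directed = TRUE, pathway_ids = as.list(rep("p1", n - 1))
  ))
}

test_that("entity collapsing merges compartment variants and case folds", {
  g <- pathway_graph(tibble::tibble(
    source = c("BRCA1_nucleus", "BRCA1_cytosol", "Tp53"),
    target = c("X", "Y", "TP53BP"),
    interaction_type = "activates", directed = TRUE,
    pathway_ids = as.list(c("p1", "p2", "p1"))
  ))
  map <- tibble::tibble(id = c("BRCA1_nucleus", "BRCA1_cytosol"),
                        canonical = c("BRCA1", "BRCA1"))
  cg <- build_collapsed_graph(g, map)
  expect_true("BRCA1" %in% cg$nodes)
  expect_false(any(grepl("NUCLEUS|CYTOSOL", cg$nodes)))
  expect_equal(sum(cg$edges$source == "BRCA1"), 2)

  # case-insensitive node dedup without a map
  g2 <- pathway_graph(tibble::tibble(
    source = c("Tp53", "TP53"), target = c("A", "B"),
    interaction_type = "activates", directed = TRUE,
    pathway_ids = as.list(c("p1", "p2"))
  ))
  cg2 <- build_collapsed_graph(g2)
  expect_equal(sum(cg2$nodes == "TP53"), 1)
})

test_that("collapse drops newly created self-loops and is idempotent", {
  g <- pathway_graph(tibble::tibble(
    source = c("A", "A"), target = c("B", "C"),
    interaction_type = "activates", directed = TRUE,
    pathway_ids = as.list(c("p1", "p2"))
  ))
  map <- tibble::tibble(id = "B", canonical = "A")
  cg <- build_collapsed_graph(g, map)
  expect_equal(nrow(cg$edges), 1)  # A->B became a self-loop and was dropped
  twice <- build_collapsed_graph(cg, map)
  expect_equal(twice$edges, cg$edges)

  bad_map <- tibble::tibble(id = c("B", "B"), canonical = c("A", "C"))
  expect_error(build_collapsed_graph(g, bad_map),
               class = "dtc_conflict_error")
})

test_that("path index respects the 9-edge bound on a 12-node chain", {
  idx <- build_path_index(chain_graph(12))
  expect_equal(query_distance(idx, "N01", "N10")$distance, 9)
  expect_null(query_distance(idx, "N01", "N11"))  # distance 10, absent
  expect_null(query_distance(idx, "N02", "N01"))  # direction respected
  expect_equal(query_distance(idx, "N05", "N05"),
               list(distance = 0L, path = "N05", edge_pathways = list()))
  expect_true(all(idx$entries$distance <= idx$max_len))
  expect_error(build_path_index(chain_graph(3), max_len = 0),
               class = "dtc_parameter_error")
})

test_that("undirected complex edges index both directions", {
  g <- pathway_graph(tibble::tibble(
    source = "C", target = "D", interaction_type = "complex-membership",
    directed = FALSE, pathway_ids = list("p1")
  ))
  idx <- build_path_index(g)
  expect_equal(query_distance(idx, "C", "D")$distance, 1)
  expect_equal(query_distance(idx, "D", "C")$distance, 1)
  expect_equal(query_distance(idx, "C", "D")$edge_pathways[[1]], "p1")
})

test_that("indexed distances match a plain BFS oracle on random graphs", {
  set.seed(404)
  for (rep in 1:8) {
    n <- sample(8:40, 1)
    ids <- sprintf("V%03d", seq_len(n))
    m <- 2 * n
    e <- tibble::tibble(
      source = sample(ids, m, replace = TRUE),
      target = sample(ids, m, replace = TRUE),
      interaction_type = sample(c("activates", "complex-membership"), m,
                                replace = TRUE, prob = c(0.8, 0.2)),
      directed = NA, pathway_ids = as.list(sprintf("p%d", sample(3, m, TRUE)))
    )
    e$directed <- e$interaction_type != "complex-membership"
    e <- e[e$source != e$target, ]
    g <- pathway_graph(e)
    idx <- build_path_index(g, max_len = 9)
    arcs <- graph_arcs(g)
    for (src in sample(g$nodes, min(5, length(g$nodes)))) {
      dist <- plain_bfs(arcs, g$nodes, src)
      stored <- idx$entries[idx$entries$source == src, ]
      for (v in g$nodes) {
        hit <- stored[stored$destination == v, ]
        if (nrow(hit) == 1) {
          expect_equal(hit$distance, as.integer(dist[v]))
          # stored path is a genuine path of the stated length
          expect_equal(length(hit$path[[1]]) - 1L, hit$distance)
        } else {
          expect_gt(dist[v], 9)
        }
      }
    }
  }
})

test_that("stored paths walk real edges and break ties lexicographically", {
  # two shortest A->D paths: A-B-D and A-C-D; A-B-D is lexicographically first
  g <- pathway_graph(tibble::tibble(
    source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
    interaction_type = "activates", directed = TRUE,
    pathway_ids = as.list(c("p1", "p2", "p1", "p2"))
  ))
  idx <- build_path_index(g)
  q <- query_distance(idx, "A", "D")
  expect_equal(q$path, c("A", "B", "D"))
  expect_equal(q$edge_pathways, list("p1", "p1"))
})

test_that("a path index round-trips through its TSV serialization", {
  case <- gen_pathway_case(seed = 13)
  raw <- read_pathway_edges(write_pathway_case_tsv(case))
  g <- build_collapsed_graph(raw, case$entity_map)
  idx <- build_path_index(g)
  p <- tempfile(fileext = ".tsv")
  write_path_index(idx, p)
  idx2 <- read_path_index(p)
  expect_equal(idx2$max_len, idx$max_len)
  expect_equal(as.data.frame(idx2$entries), as.data.frame(idx$entries))
})
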