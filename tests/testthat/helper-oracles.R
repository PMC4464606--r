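# Independent oracles and tiny fixture builders shared across tests.
# These deliberately avoid the package's own linear-algebra / igraph paths:
# explicit loops and queue-based breadth-first search only.

tiny_net <- function() {
  dti_network(tibble::tibble(
    drug_id = c("d1", "d2", "d2"),
    target_id = c("t1", "t1", "t2")
  ))
}

named_matrix <- function(values, ids) {
  m <- matrix(values, length(ids), length(ids), byrow = TRUE,
              dimnames = list(ids, ids))
  m
}

# random bipartite adjacency with no zero-degree rows/columns
random_adjacency <- function(n_d, n_t, density) {
  repeat {
    a <- matrix(as.integer(runif(n_d * n_t) < density), n_d, n_t)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) break
  }
  dimnames(a) <- list(sprintf("d%02d", seq_len(n_d)),
                      sprintf("t%02d", seq_len(n_t)))
  a
}

net_from_adjacency <- function(a) {
  idx <- which(t(a) == 1L, arr.ind = TRUE)  # row-major edge order
  dti_network(tibble::tibble(drug_id = rownames(a)[idx[, 2]],
                             target_id = colnames(a)[idx[, 1]]))
}

# align a fit's score matrix to the dimnames of a reference matrix
align_scores <- function(scores, ref) {
  scores[rownames(ref), colnames(ref), drop = FALSE]
}

random_similarity <- function(ids) {
  n <- length(ids)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# naive two-step similarity-weighted resource spreading, explicit summation
naive_recommend <- function(a, s_drug, s_target, lambda, alpha) {
  n_d <- nrow(a)
  n_t <- ncol(a)
  kd <- rowSums(a)
  kt <- colSums(a)
  s_ind <- matrix(0, n_d, n_d)
  for (i in seq_len(n_d)) for (j in seq_len(n_d)) {
    acc <- 0
    for (l in seq_len(n_t)) for (s in seq_len(n_t)) {
      acc <- acc + a[i, l] * a[j, s] * s_target[l, s]
    }
    s_ind[i, j] <- acc / (kd[i] * kd[j])
  }
  s_comb <- alpha * s_drug + (1 - alpha) * s_ind
  w <- matrix(0, n_d, n_d)
  for (i in seq_len(n_d)) for (j in seq_len(n_d)) {
    acc <- 0
    for (l in seq_len(n_t)) acc <- acc + a[i, l] * a[j, l] / kt[l]
    w[i, j] <- s_comb[i, j] * acc / (kd[i]^(1 - lambda) * kd[j]^lambda)
  }
  r <- matrix(0, n_d, n_t)
  for (i in seq_len(n_d)) for (l in seq_len(n_t)) {
    acc <- 0
    for (j in seq_len(n_d)) acc <- acc + w[i, j] * a[j, l]
    r[i, l] <- acc
  }
  dimnames(r) <- dimnames(a)
  r
}

# plain queue-based BFS distances over a directed arc matrix (2 columns)
plain_bfs <- function(arcs, nodes, src) {
  adj <- split(arcs[, 2], factor(arcs[, 1], levels = nodes))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# arcs (from, to) for a pathway_graph, undirected edges in both directions
graph_arcs <- function(graph) {
  e <- graph$edges
  rbind(cbind(e$source, e$target),
        cbind(e$target[!e$directed], e$source[!e$directed]))
}

# exhaustive minimum set cover size; sets is a named list of element vectors
brute_min_cover <- function(sets) {
  universe <- unique(unlist(sets))
  ids <- names(sets)
  for (size in seq_along(ids)) {
    for (cc in utils::combn(ids, size, simplify = FALSE)) {
      if (setequal(intersect(unique(unlist(sets[cc])), universe), universe)) {
        return(size)
      }
    }
  }
  0L
}

# build candidate tibble in the shape find_candidate_targets() returns
make_candidates <- function(sets, distances = NULL) {
  tibble::tibble(
    target_id = names(sets),
    n_covered = vapply(sets, length, integer(1)),
    covered = lapply(seq_along(sets), function(i) {
      g <- sets[[i]]
      d <- if (is.null(distances)) rep(1L, length(g)) else distances[[i]]
      tibble::tibble(gene = g, distance = d, path = vector("list", length(g)))
    }),
    drugs = rep(list(tibble::tibble(drug_id = "DB1", status = "validated",
                                    score = NA_real_)), length(sets))
  )
}

# serialize a gen_pathway_case() raw edge tibble to the SIF-like TSV format
write_pathway_case_tsv <- function(case) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(case$raw_edges, path, progress = FALSE)
  path
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
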