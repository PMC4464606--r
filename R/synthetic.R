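#' Generate a planted-block drug-target interaction case
#'
#' Drugs and targets are partitioned into `n_blocks` co-modules; a drug
#' interacts with targets of its own block with probability `density` and
#' with other blocks' targets with probability `noise * density`. Drug and
#' target similarity matrices mirror the same block structure (0.9 within a
#' block, 0.1 across, plus a small symmetric jitter, unit diagonal). This
#' plants the premise of similarity-weighted network inference — similar
#' drugs act on similar targets — so held-out within-block interactions are
#' recoverable. Ten percent of the planted within-block interactions are
#' removed from the adjacency and returned as ground truth, never removing a
#' drug's or target's last interaction. Deterministic given `seed`.
#'
#' @param n_drugs,n_targets Entity counts.
#' @param n_blocks Number of planted co-modules, at most
#'   `min(n_drugs, n_targets)`.
#' @param density Within-block interaction probability in `(0, 1)`.
#' @param noise Cross-block rate as a fraction of `density` (default 0.1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list: `net` ([dti_network()]), `drug_sim`, `target_sim`
#'   (similarity matrices), `held_out` (tibble `drug_id`, `target_id`),
#'   `drug_block`, `target_block` (named block assignments).
#' @export
gen_dti_case <- function(n_drugs = 60, n_targets = 80, n_blocks = 4,
                         density = 0.35, noise = 0.1, seed = 42) {
  if (n_blocks > min(n_drugs, n_targets) || n_blocks < 1) {
    dtc_abort_param("n_blocks must be in [1, min(n_drugs, n_targets)]")
  }
  if (density <= 0 || density >= 1) {
    dtc_abort_param("density must be in (0, 1)")
  }
  withr_seed(seed, {
    drug_ids <- sprintf("D%03d", seq_len(n_drugs))
    target_ids <- sprintf("T%03d", seq_len(n_targets))
    drug_block <- setNames(rep_len(seq_len(n_blocks), n_drugs), drug_ids)
    target_block <- setNames(rep_len(seq_len(n_blocks), n_targets), target_ids)
    same <- outer(drug_block, target_block, "==")
    prob <- ifelse(same, density, noise * density)
    a <- matrix(runif(n_drugs * n_targets) < prob, n_drugs, n_targets,
                dimnames = list(drug_ids, target_ids)) + 0L
    # guarantee every drug and target at least one within-block interaction
    for (i in seq_len(n_drugs)) {
      if (sum(a[i, ]) == 0) {
        pick <- sample(which(target_block == drug_block[i]), 1)
        a[i, pick] <- 1L
      }
    }
    for (j in seq_len(n_targets)) {
      if (sum(a[, j]) == 0) {
        pick <- sample(which(drug_block == target_block[j]), 1)
        a[pick, j] <- 1L
      }
    }
    planted <- which(a == 1L & same, arr.ind = TRUE)
    n_hold <- floor(0.1 * nrow(planted))
    held <- matrix(integer(), 0, 2)
    if (n_hold > 0) {
      cand <- planted[sample(nrow(planted)), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (sum(a[i, ]) > 1 && sum(a[, j]) > 1) {
          a[i, j] <- 0L
          held <- rbind(held, cand[r, , drop = FALSE])
          if (nrow(held) == n_hold) break
        }
      }
    }
    block_sim <- function(blocks) {
      n <- length(blocks)
      s <- ifelse(outer(blocks, blocks, "=="), 0.9, 0.1)
      jit <- matrix(runif(n * n, -0.05, 0.05), n, n)
      jit <- (jit + t(jit)) / 2
      s <- pmin(pmax(s + jit, 0), 1)
      diag(s) <- 1
      dimnames(s) <- list(names(blocks), names(blocks))
      s
    }
    drug_sim <- block_sim(drug_block)
    target_sim <- block_sim(target_block)
    edges <- which(a == 1L, arr.ind = TRUE)
    net <- dti_network(tibble(drug_id = drug_ids[edges[, 1]],
                              target_id = target_ids[edges[, 2]]) |>
                         arrange(.data$drug_id, .data$target_id))
    # reindex similarities to the network's (first-appearance) id order
    drug_sim <- drug_sim[net$drug_ids, net$drug_ids]
    target_sim <- target_sim[net$target_ids, net$target_ids]
    list(
      net = net,
      drug_sim = drug_sim,
      target_sim = target_sim,
      held_out = tibble(drug_id = drug_ids[held[, 1]],
                        target_id = target_ids[held[, 2]]),
      drug_block = drug_block,
      target_block = target_block
    )
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a complete-tree ontology with leaf annotations
#'
#' Builds a complete rooted tree of the given depth and branching factor
#' (depth 2, branching 2 gives 7 terms), then annotates each of `n_targets`
#' synthetic targets with `terms_per_target` random leaves. On a tree the
#' node distance between two terms has a closed form (steps up to the lowest
#' common ancestor plus steps down), which serves as an independent oracle
#' for the node-distance similarity.
#'
#' @param depth Tree depth (root is depth 0).
#' @param branching Children per internal node.
#' @param n_targets Number of annotated targets.
#' @param terms_per_target Leaf terms drawn per target (without replacement).
#' @param seed Integer seed.
#' @return A list: `dag` (un-augmented [ontology_dag()]), `annotations`
#'   (tibble), `leaves`, and `depth_of` (named integer vector of term
#'   depths).
#' @export
gen_ontology_case <- function(depth = 3, branching = 2, n_targets = 10,
                              terms_per_target = 2, seed = 1) {
  if (depth < 1 || branching < 1) {
    dtc_abort_param("depth and branching must be >= 1")
  }
  withr_seed(seed, {
    ids <- list("GO:0000001")
    parent <- character()
    child <- character()
    depth_of <- c(`GO:0000001` = 0L)
    counter <- 1L
    frontier <- "GO:0000001"
    for (lvl in seq_len(depth)) {
      nxt <- character()
      for (p in frontier) {
        for (b in seq_len(branching)) {
          counter <- counter + 1L
          id <- sprintf("GO:%07d", counter)
          child <- c(child, id)
          parent <- c(parent, p)
          depth_of[id] <- lvl
          nxt <- c(nxt, id)
        }
      }
      frontier <- nxt
    }
    term_ids <- names(depth_of)
    leaves <- frontier
    dag <- ontology_dag(term_ids, tibble(child = child, parent = parent))
    k <- min(terms_per_target, length(leaves))
    annotations <- bind_rows(lapply(seq_len(n_targets), function(i) {
      tibble(target_id = sprintf("T%03d", i),
             term_id = sort(sample(leaves, k)))
    }))
    list(dag = dag, annotations = annotations, leaves = leaves,
         depth_of = depth_of)
  })
}

#' Tree distance oracle for generated ontologies
#'
#' Closed-form node distance between two terms of a [gen_ontology_case()]
#' tree: number of steps from each term up to their lowest common ancestor.
#' Independent of the graph-based distance used by [term_similarity()].
#'
#' @param case A list returned by [gen_ontology_case()].
#' @param t1,t2 Term identifiers.
#' @return Integer distance.
#' @export
tree_distance <- function(case, t1, t2) {
  parents <- setNames(case$dag$parent_edges$parent,
                      case$dag$parent_edges$child)
  lineage <- function(t) {
    path <- t
    while (t %in% names(parents)) {
      t <- parents[[t]]
      path <- c(path, t)
    }
    path
  }
  l1 <- lineage(t1)
  l2 <- lineage(t2)
  common <- intersect(l1, l2)
  lca <- common[1]
  (match(lca, l1) - 1L) + (match(lca, l2) - 1L)
}

#' Generate a layered pathway fixture with a known combination answer
#'
#' Builds a three-layer directed network — druggable targets feed
#' intermediates which feed genes — plus pathway assignments, a drug map, a
#' compartment-suffixed duplicate of some nodes (with the entity map
#' collapsing them back), and a user gene list. The expected candidate set
#' and the exact minimum cover size are computed by an independent
#' brute-force companion (plain queue-based breadth-first search and
#' exhaustive subset enumeration) so end-to-end results can be checked
#' against it.
#'
#' @param n_nodes Total node count, split across the three layers.
#' @param n_pathways Number of pathway labels assigned to edges.
#' @param frac_druggable Fraction of first-layer nodes carrying a drug.
#' @param seed Integer seed.
#' @return A list: `raw_edges` (SIF-like tibble, one row per edge/pathway),
#'   `entity_map`, `drug_map`, `genes`, and `expected` (list with
#'   `candidates` tibble of target/gene/distance and `optimal_cover_size`).
#' @export
gen_pathway_case <- function(n_nodes = 18, n_pathways = 3,
                             frac_druggable = 0.8, seed = 7) {
  if (n_nodes < 6) dtc_abort_param("n_nodes must be >= 6")
  withr_seed(seed, {
    n1 <- max(2, round(n_nodes / 4))
    n3 <- max(2, round(n_nodes / 3))
    n2 <- max(2, n_nodes - n1 - n3)
    targets <- sprintf("TGT%02d", seq_len(n1))
    mids <- sprintf("MID%02d", seq_len(n2))
    genes <- sprintf("GEN%02d", seq_len(n3))
    edge <- function(from, to) tibble(
      source = from, interaction_type = "activates", target = to,
      directed = "1",
      pathway_id = sprintf("path%d", sample.int(n_pathways, length(from),
                                                replace = TRUE))
    )
    e1 <- edge(sample(targets, n2, replace = TRUE), mids)
    e2 <- edge(mids, sample(genes, n2, replace = TRUE))
    extra1 <- edge(sample(targets, n2, replace = TRUE), sample(mids, n2, replace = TRUE))
    extra2 <- edge(sample(mids, n3, replace = TRUE), sample(genes, n3, replace = TRUE))
    # undirected complex-membership links among first-layer targets keep
    # candidate pairs mutually reachable (as protein complexes do in vivo)
    cx <- tibble(
      source = targets[-length(targets)],
      interaction_type = "complex-membership",
      target = targets[-1],
      directed = "0",
      pathway_id = sprintf("path%d", sample.int(n_pathways, n1 - 1,
                                                replace = TRUE))
    )
    raw <- bind_rows(e1, e2, extra1, extra2, cx) |> dplyr::distinct()
    # duplicate one intermediate with a compartment suffix to exercise collapse
    dup <- mids[1]
    dup_name <- paste0(dup, "_nucleus")
    raw_dup <- raw[raw$source == dup | raw$target == dup, ][1, ]
    if (raw_dup$source == dup) raw_dup$source <- dup_name else raw_dup$target <- dup_name
    raw <- bind_rows(raw, raw_dup)
    entity_map <- tibble(id = dup_name, canonical = dup)
    druggable <- sort(sample(targets, max(1, round(frac_druggable * n1))))
    drug_map <- bind_rows(lapply(druggable, function(t) {
      predicted <- runif(1) < 0.4
      tibble(target_id = t,
             drug_id = sprintf("DB%05d", sample.int(99999, 1)),
             status = if (predicted) "predicted" else "validated",
             score = if (predicted) round(runif(1, 0.1, 1), 3) else NA_real_)
    }))
    expected <- brute_force_combination(raw, entity_map, drug_map, genes,
                                        max_len = 9)
    list(raw_edges = raw, entity_map = entity_map, drug_map = drug_map,
         genes = genes, expected = expected)
  })
}

# Independent oracle: collapses names, runs a plain queue BFS from each
# druggable target, and enumerates all candidate subsets for the exact
# minimum cover. Shares no code with pathway_index / combination.
brute_force_combination <- function(raw, entity_map, drug_map, genes,
                                    max_len = 9, di_range = c(0, max_len)) {
  rename <- function(x) {
    hit <- match(x, entity_map$id)
    x[!is.na(hit)] <- entity_map$canonical[hit[!is.na(hit)]]
    toupper(trimws(x))
  }
  from <- rename(raw$source)
  to <- rename(raw$target)
  und <- raw$directed == "0" | raw$interaction_type == "complex-membership"
  keep <- from != to
  arcs <- rbind(cbind(from[keep], to[keep]),
                cbind(to[keep & und], from[keep & und]))
  nodes <- unique(c(arcs[, 1], arcs[, 2]))
  adj <- split(arcs[, 2], factor(arcs[, 1], levels = nodes))
  bfs <- function(src) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      if (dist[cur] >= max_len) next
      for (nb in adj[[cur]]) {
        if (is.infinite(dist[nb])) {
          dist[nb] <- dist[cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
    dist
  }
  genes_c <- toupper(genes)
  genes_c <- intersect(genes_c, nodes)
  druggable <- intersect(toupper(unique(drug_map$target_id)), nodes)
  cand <- list()
  for (t in druggable) {
    dist <- bfs(t)
    hit <- genes_c[dist[genes_c] >= di_range[1] & dist[genes_c] <= di_range[2]]
    if (length(hit) > 0) {
      cand[[t]] <- tibble(target_id = t, gene = hit,
                          distance = as.integer(dist[hit]))
    }
  }
  candidates <- bind_rows(cand)
  # pair filter, same semantics as the pipeline: with >= 2 candidates, a
  # target needs at least one partner at min-orientation distance in range
  if (nrow(candidates) > 0) {
    ids <- unique(candidates$target_id)
    if (length(ids) > 1) {
      dists <- lapply(setNames(ids, ids), bfs)
      has_partner <- vapply(ids, function(a) {
        any(vapply(setdiff(ids, a), function(b) {
          dd <- min(dists[[a]][b], dists[[b]][a])
          dd >= 0 && dd <= max_len
        }, logical(1)))
      }, logical(1))
      candidates <- candidates[candidates$target_id %in% ids[has_partner], ]
    }
  }
  optimal <- 0L
  if (nrow(candidates) > 0) {
    sets <- split(candidates$gene, candidates$target_id)
    coverable <- unique(candidates$gene)
    ids <- names(sets)
    optimal <- length(ids)
    for (size in seq_along(ids)) {
      combos <- utils::combn(ids, size, simplify = FALSE)
      ok <- vapply(combos, function(cc) {
        setequal(intersect(unique(unlist(sets[cc])), coverable), coverable)
      }, logical(1))
      if (any(ok)) {
        optimal <- size
        break
      }
    }
  }
  list(candidates = candidates, optimal_cover_size = optimal)
}

#' Write an ontology DAG as a minimal OBO file
#'
#' Emits `[Term]` stanzas with `id:` and `is_a:` lines, parseable by
#' [read_ontology()].
#'
#' @param dag An [ontology_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  parents <- split(dag$parent_edges$parent, dag$parent_edges$child)
  lines <- c("format-version: 1.2", "")
  for (t in dag$term_ids) {
    lines <- c(lines, "[Term]", paste0("id: ", t))
    for (p in parents[[t]]) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_obo
#' @param annotations Annotation tibble (`target_id`, `term_id`).
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[, c("target_id", "term_id")], path,
                   progress = FALSE)
  invisible(path)
}
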