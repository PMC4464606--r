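#' Construct a pathway graph from an edge tibble
#'
#' @param edges Tibble with columns `source`, `target`, `interaction_type`,
#'   `directed` (logical) and `pathway_ids` (list column of character
#'   vectors). Parallel edges with identical `(source, target,
#'   interaction_type)` are merged and their pathway sets unioned.
#' @return A `pathway_graph` object.
#' @export
pathway_graph <- function(edges) {
  edges <- as_tibble(edges)
  check_columns(edges, c("source", "target", "interaction_type",
                         "directed", "pathway_ids"), "pathway edges")
  edges <- merge_parallel_edges(edges)
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$source, edges$target)))),
    class = "pathway_graph"
  )
}

merge_parallel_edges <- function(edges) {
  edges |>
    group_by(.data$source, .data$target, .data$interaction_type) |>
    summarise(
      # an edge that is undirected in any merged record stays undirected
      directed = all(.data$directed),
      pathway_ids = list(sort(unique(unlist(.data$pathway_ids)))),
      .groups = "drop"
    ) |>
    arrange(.data$source, .data$target, .data$interaction_type)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d nodes, %d edges (%d undirected)\n",
              length(x$nodes), nrow(x$edges), sum(!x$edges$directed)))
  invisible(x)
}

#' @rdname pathway_graph
#' @param x A `pathway_graph`.
#' @param ... Unused.
#' @export
tidy.pathway_graph <- function(x, ...) x$edges

#' Read a pathway network from a SIF-like TSV edge table
#'
#' Columns: `source`, `interaction_type`, `target`, `directed` (0/1),
#' `pathway_id`. Rows sharing `(source, target, interaction_type)` merge
#' into one edge whose pathway set is the union of their `pathway_id`
#' values. Complex-to-constituent edges (`interaction_type ==
#' "complex-membership"`) are always undirected, whatever the input flag;
#' all other directions are kept as given. Self-loop rows are dropped with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return A raw (pre-collapse) [pathway_graph()].
#' @export
read_pathway_edges <- function(path) {
  df <- read_tsv_quiet(path, col_types = "ccccc")
  check_columns(df, c("source", "interaction_type", "target", "directed",
                      "pathway_id"), sprintf("pathway file '%s'", path))
  loops <- df$source == df$target
  if (any(loops)) {
    warn(sprintf("pathway file '%s': dropping %d self-loop row(s)",
                 path, sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  directed <- df$directed %in% c("1", "true", "TRUE")
  directed[df$interaction_type == "complex-membership"] <- FALSE
  pathway_graph(tibble(
    source = df$source, target = df$target,
    interaction_type = df$interaction_type,
    directed = directed,
    pathway_ids = as.list(df$pathway_id)
  ))
}

#' Write a pathway graph back to the SIF-like TSV format
#'
#' One row per (edge, pathway) combination, the inverse of
#' [read_pathway_edges()] up to row order.
#'
#' @param graph A [pathway_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_edges <- function(graph, path) {
  df <- graph$edges |>
    tidyr::unnest_longer(col = "pathway_ids", values_to = "pathway_id") |>
    mutate(directed = as.integer(.data$directed)) |>
    select("source", "interaction_type", "target", "directed", "pathway_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an entity-name mapping table
#'
#' TSV with columns `id`, `canonical`: each variant node identifier (protein
#' sub-unit, compartment-suffixed copy, ...) maps to its canonical entity
#' name. An identifier mapped to two different canonical names is a fatal
#' error.
#'
#' @param path Path to the TSV file.
#' @return A tibble `id`, `canonical`.
#' @export
read_entity_map <- function(path) {
  df <- dplyr::distinct(read_tsv_quiet(path, col_types = "cc"))
  check_columns(df, c("id", "canonical"), sprintf("entity map '%s'", path))
  check_entity_map(df)
  df
}

check_entity_map <- function(entity_map) {
  dup <- unique(entity_map$id[duplicated(entity_map$id)])
  conflicting <- dup[vapply(dup, function(i) {
    length(unique(entity_map$canonical[entity_map$id == i])) > 1
  }, logical(1))]
  if (length(conflicting) > 0) {
    dtc_abort(sprintf(
      "entity map assigns conflicting canonical names to '%s'",
      conflicting[[1]]
    ), class = "dtc_conflict_error")
  }
  invisible(entity_map)
}

#' Collapse pathway nodes to canonical biological entities
#'
#' Nodes are renamed through the optional entity map (sub-units and
#' compartment-specific copies of the same protein become one node), then
#' deduplicated case-insensitively (canonical form is upper case). Edges
#' re-attach to the canonical nodes; self-loops created by the collapse are
#' dropped and parallel edges are merged with their pathway sets unioned.
#' Collapsing is idempotent.
#'
#' @param graph A raw [pathway_graph()] from [read_pathway_edges()].
#' @param entity_map Optional tibble `id`, `canonical` (see
#'   [read_entity_map()]).
#' @return The collapsed [pathway_graph()].
#' @export
build_collapsed_graph <- function(graph, entity_map = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  rename <- function(x) {
    if (!is.null(entity_map)) {
      check_entity_map(entity_map)
      hit <- match(x, entity_map$id)
      x[!is.na(hit)] <- entity_map$canonical[hit[!is.na(hit)]]
    }
    canonical_entity(x)
  }
  edges <- graph$edges
  edges$source <- rename(edges$source)
  edges$target <- rename(edges$target)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  pathway_graph(edges)
}

# ---- bounded directed shortest-path index ----------------------------------

#' Build the bounded directed shortest-path index
#'
#' Stores, for every ordered node pair at directed distance at most
#' `max_len` edges, the distance and one shortest path (the
#' lexicographically smallest node sequence among shortest paths, so output
#' is reproducible). Undirected edges are traversable both ways; directed
#' edges forward only. Each stored path edge carries the set of pathways it
#' appears in. Pairs farther apart than `max_len` are absent from the index.
#'
#' @param graph A collapsed [pathway_graph()].
#' @param max_len Maximum stored distance in edges (default 9).
#' @return A `path_index` object; `$entries` is a tibble `source`,
#'   `destination`, `distance`, `path` (list of node sequences),
#'   `edge_pathways` (list of per-edge pathway-id vectors).
#' @export
build_path_index <- function(graph, max_len = 9) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!is.numeric(max_len) || max_len < 1) {
    dtc_abort_param("max_len must be >= 1")
  }
  arcs <- expand_arcs(graph)
  nodes <- graph$nodes
  g <- igraph::graph_from_data_frame(arcs[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = tibble(name = nodes))
  d <- igraph::distances(g, mode = "out")   # unweighted BFS distances
  d <- d[nodes, nodes, drop = FALSE]
  # sorted out-neighbour lists for the lexicographic path walk
  adj <- split(arcs$to, factor(arcs$from, levels = nodes))
  adj <- lapply(adj, function(x) sort(unique(x)))
  arc_paths <- split(arcs$pathway_ids, paste(arcs$from, arcs$to, sep = "\r"))
  arc_paths <- lapply(arc_paths, function(x) sort(unique(unlist(x))))
  rows <- list()
  for (v in nodes) {
    dv <- d[, v]
    reach <- nodes[is.finite(dv) & dv <= max_len]
    for (u in reach) {
      if (u == v) {
        rows[[length(rows) + 1L]] <-
          list(source = u, destination = v, distance = 0L,
               path = u, edge_pathways = list())
        next
      }
      path <- walk_lexicographic(u, v, dv, adj)
      ep <- lapply(seq_len(length(path) - 1L), function(i) {
        arc_paths[[paste(path[i], path[i + 1L], sep = "\r")]]
      })
      rows[[length(rows) + 1L]] <-
        list(source = u, destination = v, distance = as.integer(dv[u]),
             path = path, edge_pathways = ep)
    }
  }
  entries <- tibble(
    source = map_chr(rows, "source"),
    destination = map_chr(rows, "destination"),
    distance = map_int(rows, "distance"),
    path = map(rows, "path"),
    edge_pathways = map(rows, "edge_pathways")
  ) |>
    arrange(.data$source, .data$destination)
  structure(list(entries = entries, max_len = as.integer(max_len),
                 nodes = nodes),
            class = "path_index")
}

# one traversable arc per direction; undirected edges expand to both
expand_arcs <- function(graph) {
  e <- graph$edges
  fwd <- tibble(from = e$source, to = e$target, pathway_ids = e$pathway_ids)
  rev <- tibble(from = e$target[!e$directed], to = e$source[!e$directed],
                pathway_ids = e$pathway_ids[!e$directed])
  bind_rows(fwd, rev)
}

# greedy walk from u to v: always step to the alphabetically first
# out-neighbour that stays on a shortest path (dv = distance-to-v vector)
walk_lexicographic <- function(u, v, dv, adj) {
  path <- u
  cur <- u
  while (cur != v) {
    nb <- adj[[cur]]
    nxt <- nb[dv[nb] == dv[cur] - 1][1]
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' @export
print.path_index <- function(x, ...) {
  cat(sprintf("<path_index> %d nodes, %d stored pairs (max_len = %d)\n",
              length(x$nodes), nrow(x$entries), x$max_len))
  invisible(x)
}

#' @rdname build_path_index
#' @param x A `path_index`.
#' @param ... Unused.
#' @export
tidy.path_index <- function(x, ...) x$entries

#' Look up a bounded shortest path
#'
#' @param index A `path_index` from [build_path_index()].
#' @param u,v Node names (canonicalized with [canonical_entity()] before
#'   lookup).
#' @return A list `distance`, `path`, `edge_pathways`, or `NULL` when the
#'   pair is farther apart than the index bound or a node is unknown.
#' @export
query_distance <- function(index, u, v) {
  stopifnot(inherits(index, "path_index"))
  u <- canonical_entity(u)
  v <- canonical_entity(v)
  hit <- which(index$entries$source == u & index$entries$destination == v)
  if (length(hit) == 0) return(NULL)
  e <- index$entries[hit[1], ]
  list(distance = e$distance, path = e$path[[1]],
       edge_pathways = e$edge_pathways[[1]])
}

#' Serialize and restore a path index
#'
#' TSV columns: `source`, `destination`, `distance`, `path` (nodes joined
#' with `;`), `edge_pathways` (per-edge pathway sets joined with `,`, edges
#' joined with `|`), plus a `max_len` header comment line. Round-trips
#' losslessly through [read_path_index()].
#'
#' @param index A `path_index`.
#' @param path File path.
#' @return `write_path_index()` returns `path` invisibly.
#' @export
write_path_index <- function(index, path) {
  df <- tibble(
    source = index$entries$source,
    destination = index$entries$destination,
    distance = index$entries$distance,
    path = map_chr(index$entries$path, paste, collapse = ";"),
    edge_pathways = map_chr(index$entries$edge_pathways, function(ep) {
      if (length(ep) == 0) return("")
      paste(map_chr(ep, paste, collapse = ","), collapse = "|")
    })
  )
  body <- readr::format_tsv(df)
  writeLines(c(sprintf("# max_len=%d", index$max_len),
               sub("\n$", "", body)), path, sep = "\n")
  invisible(path)
}

#' @rdname write_path_index
#' @export
read_path_index <- function(path) {
  first <- readLines(path, n = 1L)
  max_len <- 9L
  skip <- 0L
  if (grepl("^# max_len=", first)) {
    max_len <- as.integer(sub("^# max_len=", "", first))
    skip <- 1L
  }
  df <- readr::read_tsv(path, skip = skip, col_types = "ccicc",
                        na = character(), progress = FALSE)
  check_columns(df, c("source", "destination", "distance", "path",
                      "edge_pathways"), sprintf("path index '%s'", path))
  entries <- tibble(
    source = df$source,
    destination = df$destination,
    distance = df$distance,
    path = strsplit(df$path, ";", fixed = TRUE),
    edge_pathways = map(df$edge_pathways, function(s) {
      if (s == "") return(list())
      lapply(strsplit(s, "|", fixed = TRUE)[[1]],
             function(e) strsplit(e, ",", fixed = TRUE)[[1]])
    })
  ) |>
    arrange(.data$source, .data$destination)
  structure(list(entries = entries, max_len = max_len,
                 nodes = sort(unique(c(df$source, df$destination)))),
            class = "path_index")
}
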