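#' Construct an ontology DAG from a parent-edge table
#'
#' Terms are related by `is_a` edges pointing from child to parent. The graph
#' must be acyclic; term identifiers are opaque strings.
#'
#' @param term_ids Character vector of term identifiers.
#' @param parent_edges Data frame with columns `child`, `parent`.
#' @param dummy_root Identifier of the dummy root once the DAG has been
#'   augmented with [augment_dag()], or `NULL` before augmentation.
#' @return An `ontology_dag` object.
#' @export
ontology_dag <- function(term_ids, parent_edges, dummy_root = NULL) {
  term_ids <- unique(as.character(term_ids))
  parent_edges <- as_tibble(parent_edges)
  if (nrow(parent_edges) > 0) {
    check_columns(parent_edges, c("child", "parent"), "ontology edges")
    parent_edges <- dplyr::distinct(parent_edges[, c("child", "parent")])
    unknown <- setdiff(c(parent_edges$child, parent_edges$parent), term_ids)
    if (length(unknown) > 0) {
      dtc_abort_format(sprintf(
        "ontology edge references unknown term '%s'", unknown[[1]]
      ))
    }
    check_acyclic(parent_edges)
  } else {
    parent_edges <- tibble(child = character(), parent = character())
  }
  structure(
    list(term_ids = term_ids, parent_edges = parent_edges,
         dummy_root = dummy_root),
    class = "ontology_dag"
  )
}

check_acyclic <- function(parent_edges) {
  g <- igraph::graph_from_data_frame(parent_edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    in_cycle <- parent_edges$child %in% cyc & parent_edges$parent %in% cyc
    e <- parent_edges[in_cycle, ][1, ]
    dtc_abort(sprintf(
      "ontology contains an is_a cycle through edge %s -> %s",
      e$child, e$parent
    ), class = "dtc_cycle_error")
  }
  invisible(TRUE)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d is_a edges%s\n",
              length(x$term_ids), nrow(x$parent_edges),
              if (!is.null(x$dummy_root))
                sprintf(", augmented (root '%s')", x$dummy_root) else ""))
  invisible(x)
}

#' Read an ontology (OBO subset) and a target annotation table
#'
#' Parses a minimal OBO 1.2 dialect: `[Term]` stanzas with `id:`, `name:`,
#' `is_a:` and `is_obsolete:` lines; everything else is ignored. Obsolete
#' terms are dropped together with their annotations. The annotation file is
#' TSV with columns `target_id`, `term_id`; annotations referencing unknown
#' terms are reported and dropped.
#'
#' @param path_obo Path to the OBO file.
#' @param path_annotations Path to the annotation TSV.
#' @return A list with elements `dag` (an [ontology_dag()], not yet
#'   augmented) and `annotations` (a tibble `target_id`, `term_id`).
#' @export
read_ontology <- function(path_obo, path_annotations) {
  dag <- parse_obo(path_obo)
  ann <- read_tsv_quiet(path_annotations, col_types = "cc")
  check_columns(ann, c("target_id", "term_id"),
                sprintf("annotations '%s'", path_annotations))
  unknown <- !(ann$term_id %in% dag$term_ids)
  if (any(unknown)) {
    inform(sprintf(
      "annotations '%s': dropping %d row(s) referencing unknown terms",
      path_annotations, sum(unknown)
    ))
    ann <- ann[!unknown, , drop = FALSE]
  }
  list(dag = dag, annotations = as_tibble(ann))
}

parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  terms <- character()
  obsolete <- character()
  edges_child <- character()
  edges_parent <- character()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt) > 0) nxt[1] - 1L else length(lines)
    block <- lines[(s + 1L):end]
    id_line <- grep("^id:", block, value = TRUE)
    if (length(id_line) == 0) next
    id <- trimws(sub("^id:", "", id_line[[1]]))
    if (any(grepl("^is_obsolete:\\s*true", block))) {
      obsolete <- c(obsolete, id)
      next
    }
    terms <- c(terms, id)
    parents <- sub("^is_a:", "", grep("^is_a:", block, value = TRUE))
    parents <- trimws(sub("!.*$", "", parents))
    parents <- parents[parents != ""]
    edges_child <- c(edges_child, rep(id, length(parents)))
    edges_parent <- c(edges_parent, parents)
  }
  # edges to obsolete or never-defined parents are dropped
  defined <- edges_parent %in% terms
  if (any(!defined)) {
    inform(sprintf("OBO '%s': dropping %d is_a edge(s) to undefined or obsolete terms",
                   path, sum(!defined)))
  }
  ontology_dag(
    terms,
    tibble(child = edges_child[defined], parent = edges_parent[defined])
  )
}

#' Attach a dummy root below all roots of an ontology DAG
#'
#' Every original root (term with no parent) gains exactly one `is_a` edge to
#' a new dummy root term, so that any two terms are connected when edge
#' direction is ignored and all pairwise node distances are finite. This is
#' required before [term_similarity()] can compare terms from disconnected
#' branches (or different GO namespaces, which are merged under the single
#' dummy root).
#'
#' @param dag An [ontology_dag()].
#' @param dummy_root_id Identifier for the new root; must not collide with an
#'   existing term.
#' @return The augmented `ontology_dag`.
#' @export
augment_dag <- function(dag, dummy_root_id = "DTC:ROOT") {
  stopifnot(inherits(dag, "ontology_dag"))
  if (dummy_root_id %in% dag$term_ids) {
    dtc_abort(sprintf(
      "dummy root id '%s' collides with an existing term", dummy_root_id
    ), class = "dtc_collision_error")
  }
  roots <- setdiff(dag$term_ids, dag$parent_edges$child)
  new_edges <- bind_rows(
    dag$parent_edges,
    tibble(child = roots, parent = rep(dummy_root_id, length(roots)))
  )
  ontology_dag(c(dag$term_ids, dummy_root_id), new_edges,
               dummy_root = dummy_root_id)
}

dag_igraph <- function(dag, directed = FALSE) {
  igraph::graph_from_data_frame(
    dag$parent_edges, directed = directed,
    vertices = tibble(name = dag$term_ids)
  )
}

#' Node-distance similarity between ontology terms
#'
#' The similarity between two terms is `1 / (1 + d)` where `d` is the length
#' of the shortest path between them in the augmented DAG, ignoring edge
#' direction. It is 1 exactly for identical terms, symmetric, and strictly
#' decreasing in the distance. The DAG must have been augmented with
#' [augment_dag()] so all distances are finite.
#'
#' @param dag An augmented [ontology_dag()].
#' @param t1,t2 Term identifiers.
#' @return Similarity in `(0, 1]`.
#' @export
term_similarity <- function(dag, t1, t2) {
  unknown <- setdiff(c(t1, t2), dag$term_ids)
  if (length(unknown) > 0) {
    dtc_abort(sprintf("unknown ontology term '%s'", unknown[[1]]),
              class = "dtc_lookup_error")
  }
  if (t1 == t2) return(1)
  g <- dag_igraph(dag)
  d <- igraph::distances(g, v = t1, to = t2)[1, 1]
  1 / (1 + d)
}

#' Pairwise node-distance similarities for a set of terms
#'
#' @param dag An augmented [ontology_dag()].
#' @param terms Character vector of term identifiers.
#' @return A symmetric matrix of `1 / (1 + d)` similarities.
#' @export
term_similarity_matrix <- function(dag, terms) {
  terms <- unique(terms)
  unknown <- setdiff(terms, dag$term_ids)
  if (length(unknown) > 0) {
    dtc_abort(sprintf("unknown ontology term '%s'", unknown[[1]]),
              class = "dtc_lookup_error")
  }
  g <- dag_igraph(dag)
  d <- igraph::distances(g, v = terms, to = terms)
  1 / (1 + d)
}

#' Correlation of a predicted target with a drug's validated targets
#'
#' The correlation is the maximum ontology-term similarity between any term
#' annotating the candidate target and any term annotating any validated
#' target of the drug. Unannotated candidates (or drugs whose validated
#' targets are all unannotated) get correlation 0.
#'
#' @param drug_id Drug identifier, present in `net`.
#' @param candidate_target Target identifier to score.
#' @param net A [dti_network()].
#' @param annotations Annotation tibble (`target_id`, `term_id`).
#' @param dag An augmented [ontology_dag()].
#' @return Correlation in `[0, 1]`.
#' @export
drug_target_correlation <- function(drug_id, candidate_target, net,
                                    annotations, dag) {
  if (!drug_id %in% net$drug_ids) {
    dtc_abort(sprintf("drug '%s' absent from network", drug_id),
              class = "dtc_lookup_error")
  }
  validated <- net$target_ids[net$adjacency[drug_id, ] == 1L]
  cand_terms <- annotations$term_id[annotations$target_id == candidate_target]
  val_terms <- unique(annotations$term_id[annotations$target_id %in% validated])
  if (length(cand_terms) == 0 || length(val_terms) == 0) return(0)
  sims <- term_similarity_matrix(dag, unique(c(cand_terms, val_terms)))
  max(sims[unique(cand_terms), val_terms])
}

# All-drug x all-target correlation matrix, computed once per analysis:
# a target-vs-target max-term-similarity matrix is built first, then each
# drug's row is the columnwise max over its validated targets.
correlation_matrix <- function(net, annotations, dag) {
  ann_split <- split(annotations$term_id, annotations$target_id)
  ann_split <- lapply(ann_split, unique)
  annotated <- intersect(net$target_ids, names(ann_split))
  corr <- matrix(0, length(net$drug_ids), length(net$target_ids),
                 dimnames = list(net$drug_ids, net$target_ids))
  if (length(annotated) == 0) return(corr)
  terms <- unique(unlist(ann_split[annotated], use.names = FALSE))
  sims <- term_similarity_matrix(dag, terms)
  tt <- matrix(0, length(annotated), length(annotated),
               dimnames = list(annotated, annotated))
  for (i in seq_along(annotated)) {
    ti <- ann_split[[annotated[i]]]
    for (j in i:length(annotated)) {
      tj <- ann_split[[annotated[j]]]
      v <- max(sims[ti, tj, drop = FALSE])
      tt[i, j] <- v
      tt[j, i] <- v
    }
  }
  for (d in net$drug_ids) {
    validated <- intersect(net$target_ids[net$adjacency[d, ] == 1L], annotated)
    if (length(validated) == 0) next
    corr[d, annotated] <-
      apply(tt[, validated, drop = FALSE], 1, max)
  }
  corr
}
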