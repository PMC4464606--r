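#' Partition a user gene list by presence in the path index
#'
#' Genes are canonicalized the same way as pathway nodes (trimmed,
#' upper-cased) before matching; identifiers are otherwise opaque.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param index A `path_index` from [build_path_index()].
#' @return A list with `known` (canonical names present in the index) and
#'   `unknown` (input identifiers with no match).
#' @export
map_genes <- function(gene_ids, index) {
  canon <- canonical_entity(gene_ids)
  present <- canon %in% index$nodes
  list(known = unique(canon[present]), unknown = unique(gene_ids[!present]))
}

#' Find druggable candidate targets within the direct-indirect range
#'
#' A protein is a candidate if (a) it is targeted by at least one drug
#' (validated or predicted) and (b) at least one user gene lies downstream
#' of it at a directed distance within `di_range` (orientation target to
#' gene: a drug perturbs its target and the effect propagates towards the
#' genes; distance 0 means the gene is itself the drug target).
#'
#' @param index A `path_index`.
#' @param genes Canonical gene names (the `known` part of [map_genes()]).
#' @param di_range Length-2 integer vector `c(lo, hi)`, the direct-indirect
#'   range, `0 <= lo <= hi <= max_len`.
#' @param drug_map Tibble `target_id`, `drug_id`, `status`
#'   (`"validated"`/`"predicted"`), `score` (NA for validated pairs).
#' @return A tibble `target_id`, `n_covered`, `covered` (list column: tibble
#'   `gene`, `distance`, `path`), `drugs` (list column of drug rows).
#' @export
find_candidate_targets <- function(index, genes, di_range, drug_map) {
  check_range(di_range, index$max_len, "direct-indirect range")
  drug_map <- as_tibble(drug_map)
  check_columns(drug_map, c("target_id", "drug_id", "status", "score"),
                "drug map")
  drug_map$target_id <- canonical_entity(drug_map$target_id)
  druggable <- unique(drug_map$target_id)
  e <- index$entries
  hits <- e[e$source %in% druggable &
              e$destination %in% genes &
              e$distance >= di_range[1] & e$distance <= di_range[2], ]
  if (nrow(hits) == 0) {
    return(tibble(target_id = character(), n_covered = integer(),
                  covered = list(), drugs = list()))
  }
  hits |>
    group_by(target_id = .data$source) |>
    summarise(
      n_covered = dplyr::n(),
      covered = list({
        rows <- dplyr::pick("destination", "distance", "path")
        tibble(gene = rows$destination, distance = rows$distance,
               path = rows$path)
      }),
      .groups = "drop"
    ) |>
    mutate(drugs = map(.data$target_id, function(t)
      drug_map[drug_map$target_id == t,
               c("drug_id", "status", "score")])) |>
    arrange(desc(.data$n_covered), .data$target_id)
}

check_range <- function(range, max_len, what) {
  if (!is.numeric(range) || length(range) != 2 ||
      range[1] < 0 || range[1] > range[2] || range[2] > max_len) {
    dtc_abort_param(sprintf(
      "%s must be c(lo, hi) with 0 <= lo <= hi <= %d", what, max_len
    ))
  }
  invisible(range)
}

#' Filter candidates by pairwise target-to-target distance
#'
#' Two candidate targets are compatible when the smaller of their two
#' directed distances (either orientation; unreachable counts as infinite)
#' falls within `pair_range`. When two or more candidates exist, candidates
#' participating in no compatible pair are removed — a combination needs
#' partners — while a single candidate is always kept (a one-target answer
#' has no pair constraint).
#'
#' @param candidates Output of [find_candidate_targets()].
#' @param index A `path_index`.
#' @param pair_range Length-2 integer vector `c(lo, hi)`.
#' @return A list with `candidates` (filtered tibble) and `pairs` (tibble
#'   `target_a`, `target_b`, `distance` of compatible pairs).
#' @export
apply_pair_filter <- function(candidates, index, pair_range) {
  check_range(pair_range, index$max_len, "pair range")
  n <- nrow(candidates)
  empty_pairs <- tibble(target_a = character(), target_b = character(),
                        distance = double())
  if (n <= 1) return(list(candidates = candidates, pairs = empty_pairs))
  ids <- candidates$target_id
  e <- index$entries[index$entries$source %in% ids &
                       index$entries$destination %in% ids, ]
  dmat <- matrix(Inf, n, n, dimnames = list(ids, ids))
  if (nrow(e) > 0) dmat[cbind(e$source, e$destination)] <- e$distance
  pairs <- empty_pairs
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- min(dmat[ids[i], ids[j]], dmat[ids[j], ids[i]])
      if (dd >= pair_range[1] && dd <= pair_range[2]) {
        pairs <- bind_rows(pairs, tibble(
          target_a = min(ids[i], ids[j]),
          target_b = max(ids[i], ids[j]),
          distance = dd
        ))
      }
    }
  }
  keep <- candidates$target_id %in% c(pairs$target_a, pairs$target_b)
  if (!any(keep)) {
    warn("no candidate pair falls within the pair range; all candidates removed")
  }
  list(candidates = candidates[keep, ], pairs = pairs)
}

#' Greedy approximation of the minimum covering target set
#'
#' Classic Chvatal greedy set cover over the candidates' covered-gene sets:
#' repeatedly pick the target covering the most still-uncovered genes, until
#' every coverable gene is covered. Ties prefer the target whose newly
#' covered genes have the smaller total distance, then the lexicographically
#' smaller target identifier. The greedy cover is within a factor
#' `H(max set size)` of the optimum.
#'
#' @param candidates Output of [find_candidate_targets()] (possibly
#'   pair-filtered).
#' @return Character vector of target identifiers in selection order.
#' @export
greedy_min_target_set <- function(candidates) {
  if (nrow(candidates) == 0) return(character())
  sets <- setNames(
    map(candidates$covered, function(cv) setNames(cv$distance, cv$gene)),
    candidates$target_id
  )
  uncovered <- unique(unlist(lapply(sets, names)))
  chosen <- character()
  while (length(uncovered) > 0) {
    gain <- vapply(sets, function(s) sum(names(s) %in% uncovered), integer(1))
    best <- max(gain)
    if (best == 0) break
    tied <- names(sets)[gain == best]
    if (length(tied) > 1) {
      dist_sum <- vapply(tied, function(t) {
        s <- sets[[t]]
        sum(s[names(s) %in% uncovered])
      }, double(1))
      tied <- tied[dist_sum == min(dist_sum)]
    }
    pick <- sort(tied)[1]
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, names(sets[[pick]]))
    sets[[pick]] <- NULL
  }
  chosen
}

#' Run a full drug-combination query
#'
#' Composes the real-time pipeline: map the gene list onto the pathway
#' index, collect druggable candidate targets within the direct-indirect
#' range, filter by the pair range, and compute the greedy near-minimal
#' target set covering the reachable genes.
#'
#' @param gene_ids User gene identifiers (matched case-insensitively
#'   against index nodes).
#' @param index A `path_index`.
#' @param drug_map Tibble `target_id`, `drug_id`, `status`, `score`.
#' @param di_range,pair_range Length-2 ranges, default `c(0, 9)`.
#' @return A `combination_result`: `candidates` (ordered by genes covered,
#'   then identifier), `minimal_set`, `pairs`, `unreachable_genes`,
#'   `known_genes` and a `status` string.
#' @export
run_combination_query <- function(gene_ids, index, drug_map,
                                  di_range = c(0, 9), pair_range = c(0, 9)) {
  mapped <- map_genes(gene_ids, index)
  if (length(mapped$known) == 0) {
    return(new_combination_result(
      candidates = tibble(target_id = character(), n_covered = integer(),
                          covered = list(), drugs = list()),
      minimal_set = character(),
      pairs = tibble(target_a = character(), target_b = character(),
                     distance = double()),
      unreachable_genes = unique(gene_ids),
      known_genes = character(),
      status = "no input gene found in the pathway index"
    ))
  }
  cands <- find_candidate_targets(index, mapped$known, di_range, drug_map)
  filtered <- apply_pair_filter(cands, index, pair_range)
  minimal <- greedy_min_target_set(filtered$candidates)
  covered <- unique(unlist(map(filtered$candidates$covered, "gene")))
  unreachable <- c(mapped$unknown, setdiff(mapped$known, covered))
  status <- if (nrow(filtered$candidates) == 0) {
    "no druggable target reaches the gene list under the given ranges"
  } else "ok"
  new_combination_result(
    candidates = filtered$candidates, minimal_set = minimal,
    pairs = filtered$pairs, unreachable_genes = unreachable,
    known_genes = mapped$known, status = status
  )
}

new_combination_result <- function(candidates, minimal_set, pairs,
                                   unreachable_genes, known_genes, status) {
  structure(
    list(candidates = candidates, minimal_set = minimal_set, pairs = pairs,
         unreachable_genes = unreachable_genes, known_genes = known_genes,
         status = status),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf(
    "<combination_result> %d candidate target(s), minimal set of %d, %d unreachable gene(s) [%s]\n",
    nrow(x$candidates), length(x$minimal_set), length(x$unreachable_genes),
    x$status
  ))
  invisible(x)
}

#' @rdname run_combination_query
#' @param x A `combination_result`.
#' @param ... Unused.
#' @export
tidy.combination_result <- function(x, ...) {
  if (nrow(x$candidates) == 0) {
    return(tibble(target_id = character(), gene = character(),
                  distance = integer(), drug_id = character(),
                  status = character(), score = double(),
                  in_minimal_set = logical()))
  }
  x$candidates |>
    select("target_id", "covered", "drugs") |>
    tidyr::unnest(cols = "covered") |>
    select(-dplyr::any_of("path")) |>
    tidyr::unnest(cols = "drugs") |>
    mutate(in_minimal_set = .data$target_id %in% x$minimal_set)
}

#' @rdname run_combination_query
#' @export
glance.combination_result <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_minimal = length(x$minimal_set),
    n_known_genes = length(x$known_genes),
    n_unreachable = length(x$unreachable_genes),
    n_compatible_pairs = nrow(x$pairs),
    status = x$status
  )
}

#' Write / read a combination result summary table
#'
#' One row per candidate target: covered genes and their distances (comma
#' joined, aligned), associated drugs as `drug:status[:score]` entries
#' (semicolon joined) and a flag marking membership in the greedy minimal
#' set. Unreachable genes are stored on `# unreachable=` and the minimal set
#' order on `# minimal_set=` header comment lines, so a written file
#' re-reads into an equivalent flat table.
#'
#' @param result A `combination_result`.
#' @param path File path.
#' @return `write_combination()` returns `path` invisibly;
#'   `read_combination()` a list `table`, `minimal_set`, `unreachable_genes`.
#' @export
write_combination <- function(result, path) {
  df <- tibble(
    target_id = result$candidates$target_id,
    covered_genes = map_chr(result$candidates$covered,
                            function(cv) paste(cv$gene, collapse = ",")),
    distances = map_chr(result$candidates$covered,
                        function(cv) paste(cv$distance, collapse = ",")),
    drugs = map_chr(result$candidates$drugs, function(dr) {
      paste(ifelse(dr$status == "predicted",
                   sprintf("%s:predicted:%g", dr$drug_id, dr$score),
                   paste0(dr$drug_id, ":validated")),
            collapse = ";")
    }),
    in_minimal_set = result$candidates$target_id %in% result$minimal_set
  )
  body <- readr::format_tsv(df)
  writeLines(c(
    sprintf("# minimal_set=%s", paste(result$minimal_set, collapse = ",")),
    sprintf("# unreachable=%s", paste(result$unreachable_genes, collapse = ",")),
    sub("\n$", "", body)
  ), path, sep = "\n")
  invisible(path)
}

#' @rdname write_combination
#' @export
read_combination <- function(path) {
  header <- readLines(path, n = 2L)
  split_csv <- function(x) {
    x <- sub("^# [a-z_]+=", "", x)
    if (x == "") character() else strsplit(x, ",", fixed = TRUE)[[1]]
  }
  df <- readr::read_tsv(path, skip = 2L, col_types = "ccccl",
                        na = character(), progress = FALSE)
  list(table = df,
       minimal_set = split_csv(header[1]),
       unreachable_genes = split_csv(header[2]))
}

#' Read a drug map table
#'
#' TSV columns `target_id`, `drug_id`, `status` (`validated` or
#' `predicted`), `score` (empty for validated pairs).
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_drug_map <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccd", na = c("", "NA"),
                        progress = FALSE)
  check_columns(df, c("target_id", "drug_id", "status", "score"),
                sprintf("drug map '%s'", path))
  bad <- !df$status %in% c("validated", "predicted")
  if (any(bad)) {
    dtc_abort_format(sprintf(
      "drug map '%s': status must be 'validated' or 'predicted' (row %d)",
      path, which(bad)[1]
    ))
  }
  df
}

#' @rdname read_drug_map
#' @param drug_map The tibble to write.
#' @export
write_drug_map <- function(drug_map, path) {
  readr::write_tsv(drug_map, path, progress = FALSE)
  invisible(path)
}
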