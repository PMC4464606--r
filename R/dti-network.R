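#' Build a drug-target interaction network from an edge table
#'
#' Constructs the binary bipartite adjacency used by the DT-Hybrid
#' recommender. Duplicate edges collapse to a single interaction; drug and
#' target identifiers keep their first-appearance order. Because the network
#' is built from an edge list, every drug and target participates in at least
#' one interaction by construction.
#'
#' @param edges A data frame with character columns `drug_id` and `target_id`,
#'   one row per validated interaction.
#' @return A `dti_network` object: a list with `drug_ids`, `target_ids` and a
#'   binary `adjacency` matrix (rows = drugs, columns = targets).
#' @examples
#' net <- dti_network(tibble::tibble(
#'   drug_id = c("d1", "d2", "d2"), target_id = c("t1", "t1", "t2")
#' ))
#' net$adjacency
#' @export
dti_network <- function(edges) {
  edges <- as_tibble(edges)
  check_columns(edges, c("drug_id", "target_id"), "DTI network")
  edges <- dplyr::distinct(edges[, c("drug_id", "target_id")])
  if (nrow(edges) == 0) {
    dtc_abort("DTI network is empty: no interactions provided",
              class = "dtc_empty_input_error")
  }
  bad <- edges$drug_id == "" | edges$target_id == "" |
    is.na(edges$drug_id) | is.na(edges$target_id)
  if (any(bad)) {
    dtc_abort_format(sprintf(
      "DTI network: %d row(s) with a missing drug_id or target_id value",
      sum(bad)
    ))
  }
  drug_ids <- unique(edges$drug_id)
  target_ids <- unique(edges$target_id)
  if (anyDuplicated(drug_ids) || anyDuplicated(target_ids)) {
    dtc_abort_format("duplicate identifiers within an axis")
  }
  adjacency <- matrix(
    0L, nrow = length(drug_ids), ncol = length(target_ids),
    dimnames = list(drug_ids, target_ids)
  )
  adjacency[cbind(match(edges$drug_id, drug_ids),
                  match(edges$target_id, target_ids))] <- 1L
  structure(
    list(drug_ids = drug_ids, target_ids = target_ids, adjacency = adjacency),
    class = "dti_network"
  )
}

#' @export
print.dti_network <- function(x, ...) {
  cat(sprintf(
    "<dti_network> %d drugs x %d targets, %d interactions\n",
    length(x$drug_ids), length(x$target_ids), sum(x$adjacency)
  ))
  invisible(x)
}

#' @rdname dti_network
#' @param x A `dti_network`.
#' @param ... Unused.
#' @export
tidy.dti_network <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  tibble(
    drug_id = x$drug_ids[idx[, 1]],
    target_id = x$target_ids[idx[, 2]]
  ) |>
    arrange(match(.data$drug_id, x$drug_ids),
            match(.data$target_id, x$target_ids))
}

#' @rdname dti_network
#' @export
glance.dti_network <- function(x, ...) {
  tibble(
    n_drugs = length(x$drug_ids),
    n_targets = length(x$target_ids),
    n_interactions = sum(x$adjacency),
    density = mean(x$adjacency)
  )
}

#' Read a drug-target interaction network from a TSV edge list
#'
#' The file must be UTF-8 tab-separated with a header containing `drug_id`
#' and `target_id`. Duplicate rows collapse to one interaction and identifier
#' order is first appearance in the file.
#'
#' @param path Path to the TSV file.
#' @return A [dti_network()] object.
#' @export
read_dti_network <- function(path) {
  df <- tryCatch(
    read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character())),
    error = function(e) dtc_abort_format(sprintf(
      "cannot parse DTI network file '%s': %s", path, conditionMessage(e)
    ))
  )
  if (nrow(df) == 0) {
    dtc_abort(sprintf("DTI network file '%s' has no data rows", path),
              class = "dtc_empty_input_error")
  }
  check_columns(df, c("drug_id", "target_id"), sprintf("DTI network '%s'", path))
  dti_network(df)
}

#' Write a drug-target network as a TSV edge list
#'
#' @param net A [dti_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dti_network <- function(net, path) {
  readr::write_tsv(tidy(net), path, progress = FALSE)
  invisible(path)
}

# ---- similarity matrices ---------------------------------------------------

new_similarity_matrix <- function(values, entity_ids) {
  dimnames(values) <- list(entity_ids, entity_ids)
  validate_similarity_matrix(values)
  values
}

#' Validate a similarity matrix
#'
#' A valid similarity matrix is square, symmetric within `1e-9`, has a unit
#' diagonal and all entries in `[0, 1]`.
#'
#' @param values A square numeric matrix with identical row/column names.
#' @return `values`, invisibly, or an error describing the violated property.
#' @export
validate_similarity_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    dtc_abort_format("similarity matrix must be square")
  }
  if (any(values < 0 | values > 1)) {
    dtc_abort("similarity values outside [0, 1]", class = "dtc_range_error")
  }
  if (any(abs(values - t(values)) > 1e-9)) {
    dtc_abort_format("similarity matrix is not symmetric within 1e-9")
  }
  if (any(abs(diag(values) - 1) > 1e-9)) {
    dtc_abort_format("similarity matrix diagonal must be 1")
  }
  invisible(values)
}

#' Read a similarity matrix from TSV
#'
#' Accepts either a square matrix with row and column headers, or a sparse
#' long form with columns `id_a`, `id_b`, `value`. The result is reordered to
#' `expected_ids`; absent off-diagonal pairs default to similarity 0 and the
#' diagonal to 1. Asymmetric inputs are symmetrized with the entrywise
#' maximum (a warning is issued when the two directions differ by more than
#' `1e-6`). Identifiers not in `expected_ids` are reported and dropped;
#' values outside `[0, 1]` raise a range error.
#'
#' @param path Path to the TSV file.
#' @param expected_ids Ordered character vector of entity identifiers the
#'   matrix must be indexed by (typically `net$drug_ids` or `net$target_ids`).
#' @return A named square numeric matrix over `expected_ids`.
#' @export
read_similarity_matrix <- function(path, expected_ids) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) == 3 && identical(header, c("id_a", "id_b", "value"))) {
    df <- read_tsv_quiet(path, col_types = "ccd")
    return(similarity_from_long(df, expected_ids, path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "double"
  if (!identical(sort(ids), sort(colnames(m)))) {
    dtc_abort_format(sprintf(
      "square similarity '%s': row and column identifiers differ", path
    ))
  }
  rownames(m) <- ids
  m <- m[ids, ids, drop = FALSE]
  if (any(is.na(m))) {
    dtc_abort_format(sprintf("square similarity '%s': non-numeric entries", path))
  }
  if (any(m < 0 | m > 1)) {
    dtc_abort(sprintf("similarity '%s': value outside [0, 1]", path),
              class = "dtc_range_error")
  }
  unknown <- setdiff(ids, expected_ids)
  if (length(unknown) > 0) {
    inform(sprintf("similarity '%s': dropping %d unknown identifier(s): %s",
                   path, length(unknown),
                   paste(head(unknown, 5), collapse = ", ")))
    keep <- setdiff(ids, unknown)
    m <- m[keep, keep, drop = FALSE]
  }
  if (any(abs(m - t(m)) > 1e-6)) {
    warn(sprintf("similarity '%s': asymmetric entries symmetrized with max", path))
  }
  m <- pmax(m, t(m))
  out <- diag(1, length(expected_ids))
  dimnames(out) <- list(expected_ids, expected_ids)
  present <- intersect(expected_ids, rownames(m))
  out[present, present] <- m[present, present]
  diag(out) <- 1
  new_similarity_matrix(out, expected_ids)
}

similarity_from_long <- function(df, expected_ids, path) {
  if (nrow(df) > 0 && any(df$value < 0 | df$value > 1)) {
    dtc_abort(sprintf("similarity '%s': value outside [0, 1]", path),
              class = "dtc_range_error")
  }
  known <- df$id_a %in% expected_ids & df$id_b %in% expected_ids
  if (any(!known)) {
    bad <- unique(c(df$id_a[!known], df$id_b[!known]))
    bad <- setdiff(bad, expected_ids)
    inform(sprintf("similarity '%s': dropping %d unknown identifier(s): %s",
                   path, length(bad), paste(head(bad, 5), collapse = ", ")))
    df <- df[known, , drop = FALSE]
  }
  n <- length(expected_ids)
  out <- diag(1, n)
  dimnames(out) <- list(expected_ids, expected_ids)
  asym <- FALSE
  if (nrow(df) > 0) {
    ia <- match(df$id_a, expected_ids)
    ib <- match(df$id_b, expected_ids)
    filled <- matrix(NA_real_, n, n)
    for (r in seq_len(nrow(df))) {
      prev <- filled[ib[r], ia[r]]
      if (!is.na(prev) && abs(prev - df$value[r]) > 1e-6) asym <- TRUE
      filled[ia[r], ib[r]] <- max(df$value[r], filled[ia[r], ib[r]], na.rm = TRUE)
    }
    filled[is.na(filled)] <- 0
    filled <- pmax(filled, t(filled))
    off <- row(out) != col(out)
    out[off] <- filled[off]
  }
  if (asym) {
    warn(sprintf("similarity '%s': asymmetric entries symmetrized with max", path))
  }
  new_similarity_matrix(out, expected_ids)
}

#' Write a similarity matrix in sparse long form
#'
#' Emits one `id_a, id_b, value` row per unordered pair with non-zero
#' similarity (upper triangle). The unit diagonal is implicit.
#'
#' @param values A similarity matrix as returned by [read_similarity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(values, path) {
  validate_similarity_matrix(values)
  ids <- rownames(values)
  idx <- which(upper.tri(values) & values > 0, arr.ind = TRUE)
  df <- tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    value = values[idx]
  ) |>
    arrange(.data$id_a, .data$id_b)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
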