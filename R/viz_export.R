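#' Force-directed network document from mechanism chains
#'
#' Builds a renderer-agnostic node-link graph: the two article sets are large
#' anchor nodes, every distinct subject / shared / object concept a node, and
#' links run set A -> subject -> shared -> object -> set B. Parallel
#' relationships between the same node pair are collapsed into one link with
#' summed weight and the distinct predicate labels sorted and joined with
#' `|`; link weight is the supporting-publication count, so arc thickness in
#' a renderer reflects evidence volume.
#'
#' @param chains Tibble from [overlap_triples()] (provenance optional).
#' @param set_a,set_b Display names of the two article sets.
#' @return A list with `nodes` and `links` tibbles (class `network_doc`).
#' @export
to_network <- function(chains, set_a = "set A", set_b = "set B") {
  set_a_id <- paste0("set:", set_a)
  set_b_id <- paste0("set:", set_b)
  if (nrow(chains) == 0) {
    nodes <- tibble::tibble(id = character(), label = character(),
                            role = character(), semtype = character())
    links <- tibble::tibble(source = character(), target = character(),
                            predicates = character(), weight = integer())
    return(structure(list(nodes = nodes, links = links), class = "network_doc"))
  }
  node_rows <- rbind(
    data.frame(id = set_a_id, label = set_a, role = "article_set", semtype = ""),
    data.frame(id = set_b_id, label = set_b, role = "article_set", semtype = ""),
    data.frame(id = chains$subject_a_id, label = chains$subject_a_name,
               role = "subject", semtype = chains$subject_a_semtype),
    data.frame(id = chains$shared_id, label = chains$shared_name,
               role = "shared", semtype = chains$shared_semtype),
    data.frame(id = chains$object_b_id, label = chains$object_b_name,
               role = "object", semtype = chains$object_b_semtype)
  )
  node_rows <- node_rows[!duplicated(node_rows$id), ]
  nodes <- tibble::as_tibble(node_rows[order(node_rows$role, node_rows$id), ])

  link_rows <- rbind(
    data.frame(source = set_a_id, target = chains$subject_a_id,
               predicate = "", weight = chains$uniq_a),
    data.frame(source = chains$subject_a_id, target = chains$shared_id,
               predicate = chains$predicate_1, weight = chains$uniq_a),
    data.frame(source = chains$shared_id, target = chains$object_b_id,
               predicate = chains$predicate_2, weight = chains$uniq_b),
    data.frame(source = chains$object_b_id, target = set_b_id,
               predicate = "", weight = chains$uniq_b)
  )
  # one evidence bundle per distinct (source, target, predicate); collapse
  # parallel predicates into a single arc
  link_rows <- link_rows[!duplicated(link_rows[c("source", "target", "predicate")]), ]
  links <- link_rows |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      predicates = paste(sort(unique(.data$predicate[nzchar(.data$predicate)])),
                         collapse = "|"),
      weight = as.integer(sum(.data$weight)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source, .data$target)
  structure(list(nodes = nodes, links = links), class = "network_doc")
}

#' Sankey document from mechanism chains
#'
#' Left-to-right staged flows: set A (stage 0) -> subjects (1) -> shared
#' terms (2) -> objects (3) -> set B (4). Band value is the supporting
#' publication count of that side of the chain, and predicate labels are
#' rendered in square brackets on the band. Bands represent independent
#' evidence counts, so per-node flow is deliberately NOT conserved.
#'
#' @inheritParams to_network
#' @return A list with `nodes` (id, label, stage, semtype) and `links`
#'   (source, target, label, value) tibbles (class `sankey_doc`).
#' @export
to_sankey <- function(chains, set_a = "set A", set_b = "set B") {
  set_a_id <- paste0("set:", set_a)
  set_b_id <- paste0("set:", set_b)
  if (nrow(chains) == 0) {
    nodes <- tibble::tibble(id = character(), label = character(),
                            stage = integer(), semtype = character())
    links <- tibble::tibble(source = character(), target = character(),
                            label = character(), value = integer())
    return(structure(list(nodes = nodes, links = links), class = "sankey_doc"))
  }
  node_rows <- rbind(
    data.frame(id = set_a_id, label = set_a, stage = 0L, semtype = ""),
    data.frame(id = paste0("subj:", chains$subject_a_id),
               label = chains$subject_a_name, stage = 1L,
               semtype = chains$subject_a_semtype),
    data.frame(id = paste0("shared:", chains$shared_id),
               label = chains$shared_name, stage = 2L,
               semtype = chains$shared_semtype),
    data.frame(id = paste0("obj:", chains$object_b_id),
               label = chains$object_b_name, stage = 3L,
               semtype = chains$object_b_semtype),
    data.frame(id = set_b_id, label = set_b, stage = 4L, semtype = "")
  )
  node_rows <- node_rows[!duplicated(node_rows$id), ]
  nodes <- tibble::as_tibble(node_rows[order(node_rows$stage, node_rows$id), ])

  link_rows <- rbind(
    data.frame(source = set_a_id, target = paste0("subj:", chains$subject_a_id),
               label = "", value = chains$uniq_a),
    data.frame(source = paste0("subj:", chains$subject_a_id),
               target = paste0("shared:", chains$shared_id),
               label = paste0("[", chains$predicate_1, "]"),
               value = chains$uniq_a),
    data.frame(source = paste0("shared:", chains$shared_id),
               target = paste0("obj:", chains$object_b_id),
               label = paste0("[", chains$predicate_2, "]"),
               value = chains$uniq_b),
    data.frame(source = paste0("obj:", chains$object_b_id), target = set_b_id,
               label = "", value = chains$uniq_b)
  )
  link_rows <- link_rows[!duplicated(link_rows[c("source", "target", "label")]), ]
  links <- link_rows |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      label = paste(sort(unique(.data$label[nzchar(.data$label)])), collapse = "|"),
      value = as.integer(sum(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source, .data$target)
  structure(list(nodes = nodes, links = links), class = "sankey_doc")
}

#' Write a network or Sankey document as JSON
#'
#' Standard node-link JSON (`nodes` and `links` arrays of objects). Output is
#' byte-stable across runs on identical input.
#'
#' @param doc A `network_doc` or `sankey_doc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_doc <- function(doc, path) {
  payload <- list(
    type = if (inherits(doc, "sankey_doc")) "sankey" else "network",
    nodes = doc$nodes,
    links = doc$links
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a network/Sankey JSON document back
#' @param path Path written by [write_doc()].
#' @return The document object.
#' @export
read_doc <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- if (identical(raw$type, "sankey")) "sankey_doc" else "network_doc"
  nodes <- tibble::as_tibble(raw$nodes)
  links <- tibble::as_tibble(raw$links)
  if (cls == "network_doc" && nrow(links) > 0) links$weight <- as.integer(links$weight)
  if (cls == "sankey_doc" && nrow(links) > 0) links$value <- as.integer(links$value)
  if ("stage" %in% names(nodes)) nodes$stage <- as.integer(nodes$stage)
  structure(list(nodes = nodes, links = links), class = cls)
}

#' Write results as a TSV table
#'
#' All chain/term fields are written, with provenance article-ID list-columns
#' flattened to comma-separated strings.
#'
#' @param results Overlap results tibble (optionally with provenance).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(results, path) {
  flat <- results
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], function(x) paste(x, collapse = ","),
                            character(1))
    }
  }
  if ("triple_a" %in% names(flat)) {
    flat$triple_a <- gsub("\u001f", "|", flat$triple_a, fixed = TRUE)
    flat$triple_b <- gsub("\u001f", "|", flat$triple_b, fixed = TRUE)
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
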