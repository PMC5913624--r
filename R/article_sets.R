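#' Create a named article set
#'
#' An article set is a named collection of article IDs representing one
#' biomedical concept (e.g. "pancreatic cancer"). Requested IDs are
#' intersected with the store's article universe: only covered articles count
#' towards set size, so contingency denominators are computable from the
#' supplied corpus. The number of requested IDs absent from the store is
#' retained for reporting.
#'
#' @param store A `knowledge_store`.
#' @param name Set name (used in result labels and cache keys).
#' @param ids Integer vector of article IDs (e.g. from [read_pmid_list()]).
#' @return An object of class `article_set`.
#' @export
create_article_set <- function(store, name, ids) {
  if (length(ids) == 0) stop("article set '", name, "' has no requested IDs",
                             call. = FALSE)
  ids <- unique(as.integer(ids))
  members <- sort(intersect(ids, store$articles))
  if (length(members) == 0) {
    stop("article set '", name, "' has no coverage: none of the ",
         length(ids), " requested articles are in the store", call. = FALSE)
  }
  structure(list(
    name = name,
    requested_ids = ids,
    member_ids = members,
    n_members = length(members),
    n_absent = length(ids) - length(members)
  ), class = "article_set")
}

#' @export
print.article_set <- function(x, ...) {
  cat("<article_set> '", x$name, "': ", x$n_members, " member article(s)",
      if (x$n_absent > 0) paste0(" (", x$n_absent, " requested ID(s) not in store)"),
      "\n", sep = "")
  invisible(x)
}

#' Per-set occurrence counts
#'
#' Counts, for every key of the chosen method, the number of DISTINCT member
#' articles containing it. Distinct-article counting (rather than mention
#' counting) is deliberate: enrichment must not reward repeated mentions of a
#' term within a single abstract. The `mesh` method uses major-topic
#' annotations only; the `concept` method counts an article once even when
#' the concept appears as both subject and object in it.
#'
#' @param store A `knowledge_store`.
#' @param set An `article_set`.
#' @param method One of `"mesh"`, `"concept"`, `"triple"`.
#' @return Tibble with columns `key` and `uniq`, sorted by key.
#' @export
occurrences <- function(store, set, method = c("mesh", "concept", "triple")) {
  method <- match.arg(method)
  members <- set$member_ids
  tab <- switch(method,
    triple = {
      p <- store$predications
      p <- p[p$article_id %in% members, c("article_id", "triple")]
      data.frame(key = p$triple, article_id = p$article_id)
    },
    concept = {
      p <- store$predications
      p <- p[p$article_id %in% members, ]
      data.frame(
        key = c(p$subject_id, p$object_id),
        article_id = c(p$article_id, p$article_id)
      )
    },
    mesh = {
      m <- store$mesh_major
      m <- m[m$article_id %in% members, ]
      data.frame(key = m$descriptor_id, article_id = m$article_id)
    }
  )
  if (nrow(tab) == 0) return(tibble::tibble(key = character(), uniq = integer()))
  tab <- unique(tab)
  cnt <- c(table(tab$key))
  tibble::tibble(key = names(cnt), uniq = as.integer(cnt)) |>
    dplyr::arrange(.data$key)
}
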