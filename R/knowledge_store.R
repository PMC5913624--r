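#' Build an indexed literature corpus
#'
#' Constructs the in-memory knowledge store over a predication table and a
#' MeSH annotation table: article-to-annotation maps, inverted indexes from
#' triples / concepts / major MeSH descriptors back to articles, and the
#' global background frequencies the enrichment step tests against. The unit
#' of evidence is the (article, triple) pair: duplicate mentions of a triple
#' within one article collapse to a single link.
#'
#' The article universe is the union of article IDs seen in either table;
#' articles absent from both inputs are invisible to all background totals.
#'
#' Concepts carry two global frequencies. `concept_articles` counts distinct
#' articles containing the concept as subject or object; `concept_occurrences`
#' counts (article, slot) pairs, so one article contributes once for the
#' concept-as-subject and once for concept-as-object. Published linking-term
#' frequency caps are expressed on the occurrence scale, while enrichment
#' contingency tables are built on the article scale.
#'
#' @param predications Tibble from [read_predications()].
#' @param mesh_annotations Tibble from [read_mesh_annotations()], or `NULL`.
#' @param mesh_tree A `mesh_tree` from [read_mesh_tree()], or `NULL`.
#' @return An object of class `knowledge_store`.
#' @export
build_store <- function(predications, mesh_annotations = NULL, mesh_tree = NULL) {
  n_pred <- if (is.null(predications)) 0L else nrow(predications)
  n_mesh <- if (is.null(mesh_annotations)) 0L else nrow(mesh_annotations)
  if (n_pred == 0 && n_mesh == 0) stop("empty corpus", call. = FALSE)

  if (n_pred > 0) {
    p <- predications[order(predications$article_id, predications$subject_id,
                            predications$predicate, predications$object_id), ]
    p$triple <- triple_key(p$subject_id, p$predicate, p$object_id)
    # evidence unit is the (article, triple) pair
    p <- p[!duplicated(p[c("article_id", "triple")]), ]
  } else {
    p <- predications
  }

  major <- NULL
  if (n_mesh > 0) {
    m <- mesh_annotations[order(mesh_annotations$article_id,
                                mesh_annotations$descriptor_id), ]
    m <- m[!duplicated(m[c("article_id", "descriptor_id", "is_major")]), ]
    major <- m[m$is_major, , drop = FALSE]
  } else {
    m <- mesh_annotations
  }

  universe <- sort(unique(c(
    if (n_pred > 0) p$article_id else integer(),
    if (n_mesh > 0) m$article_id else integer()
  )))

  triple_index <- concept_index <- list()
  concept_occurrences <- integer()
  triple_meta <- NULL
  if (n_pred > 0) {
    triple_index <- lapply(split(p$article_id, p$triple), function(x) sort(unique(x)))
    slot <- rbind(
      data.frame(concept = p$subject_id, article_id = p$article_id),
      data.frame(concept = p$object_id, article_id = p$article_id)
    )
    concept_index <- lapply(split(slot$article_id, slot$concept),
                            function(x) sort(unique(x)))
    # (article, slot) occurrences: subject and object slots count separately
    subj <- unique(p[c("article_id", "subject_id")])
    obj <- unique(p[c("article_id", "object_id")])
    occ <- c(table(subj$subject_id)) ; occ2 <- c(table(obj$object_id))
    all_c <- sort(unique(c(names(occ), names(occ2))))
    concept_occurrences <- stats::setNames(
      ifelse(is.na(occ[all_c]), 0L, occ[all_c]) +
        ifelse(is.na(occ2[all_c]), 0L, occ2[all_c]),
      all_c
    )
    triple_meta <- p[!duplicated(p$triple),
                     c("triple", "subject_id", "subject_name", "subject_semtype",
                       "predicate", "object_id", "object_name", "object_semtype")]
    triple_meta <- triple_meta[order(triple_meta$triple), ]
  }

  mesh_index <- list()
  if (!is.null(major) && nrow(major) > 0) {
    mesh_index <- lapply(split(major$article_id, major$descriptor_id),
                         function(x) sort(unique(x)))
  }

  predicate_counts <- if (n_pred > 0) {
    cnt <- c(table(p$predicate))
    cnt[order(-cnt, names(cnt))]
  } else integer()

  structure(list(
    n_articles = length(universe),
    articles = universe,
    predications = if (n_pred > 0) tibble::as_tibble(p) else tibble::tibble(),
    mesh_major = if (!is.null(major)) tibble::as_tibble(major) else tibble::tibble(),
    triple_index = triple_index,
    concept_index = concept_index,
    mesh_index = mesh_index,
    triple_freq = vapply(triple_index, length, integer(1)),
    concept_article_freq = vapply(concept_index, length, integer(1)),
    concept_occurrence_freq = concept_occurrences,
    mesh_freq = vapply(mesh_index, length, integer(1)),
    predicate_counts = predicate_counts,
    triple_meta = triple_meta,
    mesh_tree = mesh_tree
  ), class = "knowledge_store")
}

#' @export
print.knowledge_store <- function(x, ...) {
  cat("<knowledge_store>\n")
  cat("  articles:           ", x$n_articles, "\n")
  cat("  distinct triples:   ", length(x$triple_index), "\n")
  cat("  distinct concepts:  ", length(x$concept_index), "\n")
  cat("  major descriptors:  ", length(x$mesh_index), "\n")
  cat("  predicates:         ", length(x$predicate_counts), "\n")
  invisible(x)
}

#' Directed triple key
#'
#' Canonical string key for a subject-PREDICATE-object triple. Keys are
#' direction-preserving: `(x, P, y)` and `(y, P, x)` are distinct triples.
#'
#' @param subject_id,predicate,object_id Character vectors (recycled).
#' @return Character vector of keys.
#' @export
triple_key <- function(subject_id, predicate, object_id) {
  paste(subject_id, predicate, object_id, sep = "\u001f")
}

#' Split triple keys back into components
#' @param key Character vector of keys from [triple_key()].
#' @return Tibble with columns `subject_id`, `predicate`, `object_id`.
#' @export
triple_key_parts <- function(key) {
  parts <- strsplit(key, "\u001f", fixed = TRUE)
  tibble::tibble(
    subject_id = vapply(parts, `[`, character(1), 1),
    predicate = vapply(parts, `[`, character(1), 2),
    object_id = vapply(parts, `[`, character(1), 3)
  )
}

#' Predicate frequency ranks
#'
#' Ranks predicates by global occurrence count, rank 1 being the most
#' frequent; rarer (higher-ranked) predicates are treated as more
#' informative. Ties are broken by predicate string, ascending, so the
#' ranking is deterministic.
#'
#' @param store A `knowledge_store`.
#' @return Tibble with columns `predicate`, `count`, `rank`.
#' @export
predicate_ranks <- function(store) {
  cnt <- store$predicate_counts
  if (length(cnt) == 0) {
    return(tibble::tibble(predicate = character(), count = integer(),
                          rank = integer()))
  }
  ord <- order(-cnt, names(cnt))
  tibble::tibble(
    predicate = names(cnt)[ord],
    count = as.integer(cnt[ord]),
    rank = seq_along(cnt)
  )
}

#' Inverted-index lookups
#'
#' Retrieve the distinct article IDs containing a concept (as subject or
#' object), a directed triple, or a major MeSH descriptor. Unknown keys
#' return an empty integer vector.
#'
#' @param store A `knowledge_store`.
#' @param concept_id,key,descriptor_id Single lookup key.
#' @return Sorted integer vector of article IDs.
#' @export
articles_with_concept <- function(store, concept_id) {
  out <- store$concept_index[[concept_id]]
  if (is.null(out)) integer() else out
}

#' @rdname articles_with_concept
#' @export
articles_with_triple <- function(store, key) {
  out <- store$triple_index[[key]]
  if (is.null(out)) integer() else out
}

#' @rdname articles_with_concept
#' @export
articles_with_descriptor <- function(store, descriptor_id) {
  out <- store$mesh_index[[descriptor_id]]
  if (is.null(out)) integer() else out
}

#' Fingerprint of a store's contents
#'
#' MD5 over a canonical serialization of the store's indexes; used to key the
#' enrichment cache so stale results are never silently reused.
#'
#' @param store A `knowledge_store`.
#' @return Character MD5 hex digest.
#' @export
store_fingerprint <- function(store) {
  payload <- list(
    n = store$n_articles, a = store$articles,
    t = store$triple_index, c = store$concept_index, m = store$mesh_index
  )
  md5_of(payload)
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Save / load a knowledge store cache file
#'
#' Single-file serialized cache so a corpus need not be re-indexed on every
#' run; no server process is involved.
#'
#' @param store A `knowledge_store`.
#' @param path Cache file path.
#' @return `save_store` returns `path` invisibly; `load_store` the store.
#' @export
save_store <- function(store, path) {
  saveRDS(store, path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  store <- readRDS(path)
  if (!inherits(store, "knowledge_store")) {
    stop("not a knowledge store cache: ", path, call. = FALSE)
  }
  store
}
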