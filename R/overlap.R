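#' Shared enriched single terms between two article sets
#'
#' Intersects the surviving enrichment lists of two article sets analysed
#' with the same single-term method (`mesh` or `concept`). Each shared term
#' carries both sides' statistics, the balance score of [eq1_score()], and
#' the arithmetic mean of the two corrected p-values. For the `mesh` method,
#' the MeSH hierarchy depth of each descriptor is attached when the store
#' carries a tree.
#'
#' @param result_a,result_b `enrichment_result` objects for sets A and B,
#'   same method.
#' @param store Optional `knowledge_store`, used to annotate MeSH depth.
#' @return Tibble of shared terms, one row per key, sorted by key.
#' @export
overlap_single <- function(result_a, result_b, store = NULL) {
  if (!identical(result_a$method, result_b$method)) {
    stop("both enrichment results must use the same method (got '",
         result_a$method, "' and '", result_b$method, "')", call. = FALSE)
  }
  if (result_a$method == "triple") {
    stop("overlap_single() is for single-term methods; use overlap_triples()",
         call. = FALSE)
  }
  keys <- sort(intersect(result_a$enriched$key, result_b$enriched$key))
  ea <- result_a$enriched[match(keys, result_a$enriched$key), ]
  eb <- result_b$enriched[match(keys, result_b$enriched$key), ]
  out <- tibble::tibble(
    key = keys,
    uniq_a = ea$uniq, uniq_b = eb$uniq,
    p_corrected_a = ea$p_corrected, p_corrected_b = eb$p_corrected,
    odds_ratio_a = ea$odds_ratio, odds_ratio_b = eb$odds_ratio,
    score = eq1_score(ea$uniq, eb$uniq),
    mean_p_corrected = (ea$p_corrected + eb$p_corrected) / 2
  )
  if (result_a$method == "mesh" && !is.null(store) && !is.null(store$mesh_tree)) {
    out$mesh_depth <- mesh_depth(store$mesh_tree, out$key)
  }
  attr(out, "method") <- result_a$method
  out
}

#' Chain enriched triples across two article sets
#'
#' Builds candidate mechanism chains subjectA—predicate1—shared—predicate2—
#' objectB: for every triple `(s1, P1, x)` enriched in set A and every triple
#' `(x, P2, o2)` enriched in set B sharing the linking term `x`, one chain is
#' emitted. The direction is strictly from A-object to B-subject; reversed
#' matches never appear. The linking term must fall below the global
#' occurrence threshold (applied to the linking position only), which removes
#' ubiquitous concepts such as "Patients" or "Cells" that would otherwise
#' flood the results. All predicates are retained deliberately: rows with
#' common predicates can still be informative and are handled downstream by
#' the predicate-frequency-rank filter.
#'
#' @param store A `knowledge_store`.
#' @param result_a,result_b `enrichment_result` objects from
#'   `method = "triple"` for sets A and B.
#' @param linking_threshold Global concept OCCURRENCE count cap on the
#'   linking term (the published full-corpus value is 150,000; synthetic or
#'   reduced corpora need a rescaled value). `Inf` disables the filter.
#' @return Tibble of mechanism chains with per-side statistics, the
#'   [eq1_score()] value, predicate frequency ranks `pfr_1` / `pfr_2`, and
#'   deterministic row order.
#' @export
overlap_triples <- function(store, result_a, result_b,
                            linking_threshold = 150000) {
  if (!identical(result_a$method, "triple") || !identical(result_b$method, "triple")) {
    stop("overlap_triples() requires enrichment results from method 'triple'",
         call. = FALSE)
  }
  if (!(is.numeric(linking_threshold) && linking_threshold > 0)) {
    stop("linking_threshold must be positive", call. = FALSE)
  }
  empty <- mechanism_chain_tibble()
  if (nrow(result_a$enriched) == 0 || nrow(result_b$enriched) == 0) return(empty)

  pa <- triple_key_parts(result_a$enriched$key)
  pb <- triple_key_parts(result_b$enriched$key)
  ta <- tibble::tibble(
    subject_a_id = pa$subject_id, predicate_1 = pa$predicate,
    link = pa$object_id, triple_a = result_a$enriched$key,
    uniq_a = result_a$enriched$uniq,
    p_corrected_a = result_a$enriched$p_corrected,
    odds_ratio_a = result_a$enriched$odds_ratio
  )
  tb <- tibble::tibble(
    link = pb$subject_id, predicate_2 = pb$predicate,
    object_b_id = pb$object_id, triple_b = result_b$enriched$key,
    uniq_b = result_b$enriched$uniq,
    p_corrected_b = result_b$enriched$p_corrected,
    odds_ratio_b = result_b$enriched$odds_ratio
  )
  joined <- dplyr::inner_join(ta, tb, by = "link", relationship = "many-to-many")
  if (nrow(joined) == 0) return(empty)

  occ <- store$concept_occurrence_freq[joined$link]
  occ[is.na(occ)] <- 0L
  joined <- joined[occ < linking_threshold, , drop = FALSE]
  if (nrow(joined) == 0) return(empty)

  meta <- store$triple_meta
  meta_a <- meta[match(joined$triple_a, meta$triple), ]
  meta_b <- meta[match(joined$triple_b, meta$triple), ]
  ranks <- predicate_ranks(store)
  pfr <- stats::setNames(ranks$rank, ranks$predicate)

  out <- tibble::tibble(
    subject_a_id = joined$subject_a_id,
    subject_a_name = meta_a$subject_name,
    subject_a_semtype = meta_a$subject_semtype,
    predicate_1 = joined$predicate_1,
    shared_id = joined$link,
    shared_name = meta_a$object_name,
    shared_semtype = meta_a$object_semtype,
    predicate_2 = joined$predicate_2,
    object_b_id = joined$object_b_id,
    object_b_name = meta_b$object_name,
    object_b_semtype = meta_b$object_semtype,
    triple_a = joined$triple_a,
    triple_b = joined$triple_b,
    uniq_a = joined$uniq_a,
    uniq_b = joined$uniq_b,
    p_corrected_a = joined$p_corrected_a,
    p_corrected_b = joined$p_corrected_b,
    odds_ratio_a = joined$odds_ratio_a,
    odds_ratio_b = joined$odds_ratio_b,
    score = eq1_score(joined$uniq_a, joined$uniq_b),
    mean_p_corrected = (joined$p_corrected_a + joined$p_corrected_b) / 2,
    pfr_1 = as.integer(pfr[joined$predicate_1]),
    pfr_2 = as.integer(pfr[joined$predicate_2])
  )
  out <- out[order(out$triple_a, out$triple_b), , drop = FALSE]
  attr(out, "method") <- "triple"
  out
}

mechanism_chain_tibble <- function() {
  out <- tibble::tibble(
    subject_a_id = character(), subject_a_name = character(),
    subject_a_semtype = character(), predicate_1 = character(),
    shared_id = character(), shared_name = character(),
    shared_semtype = character(), predicate_2 = character(),
    object_b_id = character(), object_b_name = character(),
    object_b_semtype = character(), triple_a = character(),
    triple_b = character(), uniq_a = integer(), uniq_b = integer(),
    p_corrected_a = numeric(), p_corrected_b = numeric(),
    odds_ratio_a = numeric(), odds_ratio_b = numeric(),
    score = numeric(), mean_p_corrected = numeric(),
    pfr_1 = integer(), pfr_2 = integer()
  )
  attr(out, "method") <- "triple"
  out
}

#' Attach per-side publication provenance to mechanism chains
#'
#' For every chain, records the article IDs supporting each side: set-A
#' member articles containing triple 1 and set-B member articles containing
#' triple 2. The list lengths equal the chains' `uniq_a` / `uniq_b` counts by
#' construction; an empty support list indicates an internal inconsistency
#' and raises an error.
#'
#' @param store A `knowledge_store`.
#' @param chains Tibble from [overlap_triples()].
#' @param result_a,result_b The enrichment results the chains came from
#'   (source of set membership).
#' @return `chains` with list-columns `articles_a`, `articles_b`.
#' @export
attach_provenance <- function(store, chains, result_a, result_b) {
  if (nrow(chains) == 0) {
    chains$articles_a <- list()
    chains$articles_b <- list()
    return(chains)
  }
  prov_side <- function(keys, members) {
    lapply(keys, function(k) intersect(articles_with_triple(store, k), members))
  }
  chains$articles_a <- prov_side(chains$triple_a, result_a$member_ids)
  chains$articles_b <- prov_side(chains$triple_b, result_b$member_ids)
  if (any(lengths(chains$articles_a) == 0) || any(lengths(chains$articles_b) == 0)) {
    stop("internal consistency error: enriched chain with empty support",
         call. = FALSE)
  }
  stopifnot(identical(lengths(chains$articles_a), chains$uniq_a),
            identical(lengths(chains$articles_b), chains$uniq_b))
  chains
}
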