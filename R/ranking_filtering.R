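#' Balance score for an overlapping element
#'
#' `min(uniq_a, uniq_b) / max(uniq_a, uniq_b) * (uniq_a + uniq_b)`, where
#' `uniq_a` and `uniq_b` are the numbers of unique articles from each set
#' containing the overlapping element. The score favours elements with many
#' AND balanced supporting articles on both sides: (5, 5) scores 10 while
#' (1, 100) scores only 1.01, so one-sided support is down-weighted even when
#' the total is large.
#'
#' @param uniq_a,uniq_b Positive integer article counts (vectorized).
#' @return Numeric score vector.
#' @export
eq1_score <- function(uniq_a, uniq_b) {
  if (any(uniq_a < 1) || any(uniq_b < 1)) {
    stop("uniq counts must be >= 1", call. = FALSE)
  }
  pmin(uniq_a, uniq_b) / pmax(uniq_a, uniq_b) * (uniq_a + uniq_b)
}

#' Filter specification for overlap results
#'
#' Bundles the filter panel: corrected-p and odds-ratio thresholds, top-N
#' truncation, predicate-frequency-rank floor (exclude rows whose rarer
#' predicate rank is below `min_pfr`, i.e. whose predicates are globally too
#' common), minimum MeSH hierarchy depth (mesh method only), and per-position
#' keyword include/exclude lists over the five chain elements
#' (`subject_a`, `predicate_1`, `shared`, `predicate_2`, `object_b`; single
#' terms use position `shared`).
#'
#' @param max_mean_p_corrected Keep rows with mean corrected p at or below
#'   this value (`Inf` disables).
#' @param min_odds_ratio Keep rows whose odds ratios on both sides are at or
#'   above this value (0 disables).
#' @param top_n Keep at most this many rows after ordering by score
#'   (`Inf` disables).
#' @param min_pfr Keep rows with `min(pfr_1, pfr_2) >= min_pfr` (0 disables);
#'   rank 1 is the most frequent predicate, so `min_pfr = 6` drops rows whose
#'   rarer predicate is among the 5 most frequent.
#' @param min_mesh_depth Keep terms at or below this depth in the MeSH
#'   hierarchy, i.e. `mesh_depth >= min_mesh_depth` (0 disables).
#' @param include_keywords,exclude_keywords Named lists of character vectors
#'   keyed by position; include lists keep only rows matching at least one
#'   keyword at that position, exclude lists drop matching rows.
#' @param exact Use exact (case-insensitive) matching instead of substring
#'   matching for keywords.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(max_mean_p_corrected = Inf, min_odds_ratio = 0,
                        top_n = Inf, min_pfr = 0, min_mesh_depth = 0,
                        include_keywords = list(), exclude_keywords = list(),
                        exact = FALSE) {
  positions <- c("subject_a", "predicate_1", "shared", "predicate_2", "object_b")
  check_kw <- function(kw, what) {
    if (length(kw) > 0 && (is.null(names(kw)) || !all(names(kw) %in% positions))) {
      stop(what, " keyword lists must be named by position (",
           paste(positions, collapse = ", "), ")", call. = FALSE)
    }
  }
  check_kw(include_keywords, "include")
  check_kw(exclude_keywords, "exclude")
  for (pos in intersect(names(include_keywords), names(exclude_keywords))) {
    clash <- intersect(tolower(include_keywords[[pos]]),
                       tolower(exclude_keywords[[pos]]))
    if (length(clash) > 0) {
      stop("keyword(s) both included and excluded at position '", pos, "': ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
  }
  if (max_mean_p_corrected < 0 || min_odds_ratio < 0 || top_n < 1 ||
      min_pfr < 0 || min_mesh_depth < 0) {
    stop("filter thresholds out of range", call. = FALSE)
  }
  structure(list(
    max_mean_p_corrected = max_mean_p_corrected,
    min_odds_ratio = min_odds_ratio,
    top_n = top_n,
    min_pfr = min_pfr,
    min_mesh_depth = min_mesh_depth,
    include_keywords = include_keywords,
    exclude_keywords = exclude_keywords,
    exact = exact
  ), class = "filter_spec")
}

#' Order overlap results
#'
#' Deterministic total ordering of shared terms or mechanism chains:
#' `score` descending (balanced well-supported elements first),
#' `mean_p_corrected` ascending (strongest enrichment first), `pfr`
#' descending on `min(pfr_1, pfr_2)` (rarer, more informative predicates
#' first; triple method only), or `mesh_depth` descending (more specific MeSH
#' topics first; mesh method only). Ties are broken by total support
#' `uniq_a + uniq_b` descending, then lexicographically on the element
#' identity, so the order is fully reproducible.
#'
#' @param results Tibble from [overlap_single()] or [overlap_triples()].
#' @param key One of `"score"`, `"mean_p_corrected"`, `"pfr"`, `"mesh_depth"`.
#' @return The reordered tibble, with the ordering key recorded in attribute
#'   `"order_key"`.
#' @export
order_results <- function(results,
                          key = c("score", "mean_p_corrected", "pfr", "mesh_depth")) {
  key <- match.arg(key)
  is_chain <- "triple_a" %in% names(results)
  if (key == "pfr" && !is_chain) {
    stop("pfr ordering applies to triple-method results only", call. = FALSE)
  }
  if (key == "mesh_depth" && !("mesh_depth" %in% names(results))) {
    stop("mesh_depth ordering applies to mesh-method results only", call. = FALSE)
  }
  if (nrow(results) == 0) {
    attr(results, "order_key") <- key
    return(results)
  }
  primary <- switch(key,
    score = -results$score,
    mean_p_corrected = results$mean_p_corrected,
    pfr = -pmin(results$pfr_1, results$pfr_2),
    mesh_depth = -results$mesh_depth
  )
  ident <- if (is_chain) paste(results$triple_a, results$triple_b) else results$key
  ord <- order(primary, -(results$uniq_a + results$uniq_b), ident)
  out <- results[ord, , drop = FALSE]
  attr(out, "method") <- attr(results, "method")
  attr(out, "order_key") <- key
  out
}

#' Apply a filter specification to overlap results
#'
#' Filters are applied in a fixed stage order — corrected p, odds ratio,
#' predicate frequency rank / MeSH depth, keywords, then top-N — and the
#' survivor count after each stage is recorded in attribute
#' `"stage_counts"`. Keyword matching is case-insensitive substring matching
#' on the named chain position (names for concepts/descriptors, labels for
#' predicates); include lists keep only rows matching at least one keyword at
#' that position. Top-N is taken after ordering by score so truncation is
#' deterministic. An empty result is a valid outcome, never an error.
#'
#' @param results Tibble from [overlap_single()] or [overlap_triples()].
#' @param spec A [filter_spec()].
#' @return Filtered (and score-ordered, when top-N applies) tibble with
#'   attributes `"stage_counts"` and `"filter_spec"`.
#' @export
apply_filters <- function(results, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  is_chain <- "triple_a" %in% names(results)
  counts <- c(input = nrow(results))
  out <- results

  if (is.finite(spec$max_mean_p_corrected)) {
    out <- out[out$mean_p_corrected <= spec$max_mean_p_corrected, , drop = FALSE]
  }
  counts <- c(counts, p = nrow(out))

  if (spec$min_odds_ratio > 0) {
    out <- out[out$odds_ratio_a >= spec$min_odds_ratio &
               out$odds_ratio_b >= spec$min_odds_ratio, , drop = FALSE]
  }
  counts <- c(counts, odds_ratio = nrow(out))

  if (spec$min_pfr > 0 && is_chain) {
    out <- out[pmin(out$pfr_1, out$pfr_2) >= spec$min_pfr, , drop = FALSE]
  }
  if (spec$min_mesh_depth > 0 && "mesh_depth" %in% names(out)) {
    depth <- out$mesh_depth
    keep <- !is.na(depth) & depth >= spec$min_mesh_depth
    out <- out[keep, , drop = FALSE]
  }
  counts <- c(counts, rank_depth = nrow(out))

  out <- filter_keywords(out, spec, is_chain)
  counts <- c(counts, keywords = nrow(out))

  if (is.finite(spec$top_n) && nrow(out) > spec$top_n) {
    out <- order_results(out, "score")
    out <- out[seq_len(spec$top_n), , drop = FALSE]
  }
  counts <- c(counts, top_n = nrow(out))

  attr(out, "method") <- attr(results, "method")
  attr(out, "stage_counts") <- counts
  attr(out, "filter_spec") <- spec
  out
}

position_text <- function(results, pos, is_chain) {
  if (is_chain) {
    switch(pos,
      subject_a = paste(results$subject_a_id, results$subject_a_name),
      predicate_1 = results$predicate_1,
      shared = paste(results$shared_id, results$shared_name),
      predicate_2 = results$predicate_2,
      object_b = paste(results$object_b_id, results$object_b_name)
    )
  } else {
    # single-term results expose only the shared position
    if (pos != "shared") return(NULL)
    results$key
  }
}

filter_keywords <- function(out, spec, is_chain) {
  if (nrow(out) == 0) return(out)
  match_any <- function(text, kws, exact) {
    hit <- rep(FALSE, length(text))
    for (kw in kws) {
      hit <- hit | if (exact) {
        tolower(text) == tolower(kw)
      } else {
        grepl(kw, text, ignore.case = TRUE, fixed = FALSE)
      }
    }
    hit
  }
  for (pos in names(spec$exclude_keywords)) {
    text <- position_text(out, pos, is_chain)
    if (is.null(text)) next
    out <- out[!match_any(text, spec$exclude_keywords[[pos]], spec$exact), , drop = FALSE]
    if (nrow(out) == 0) return(out)
  }
  for (pos in names(spec$include_keywords)) {
    text <- position_text(out, pos, is_chain)
    if (is.null(text)) next
    out <- out[match_any(text, spec$include_keywords[[pos]], spec$exact), , drop = FALSE]
    if (nrow(out) == 0) return(out)
  }
  out
}

#' First-pass dynamic filter defaults
#'
#' Result sets of very different sizes need different first-view filtering:
#' small sets are shown in full, moderate sets are truncated to the top 100
#' by score, and large sets additionally drop rows whose rarer predicate is
#' among the most frequent globally. The size breakpoints and parameters are
#' package configuration, not fixed constants of the method.
#'
#' @param results Overlap results tibble.
#' @param small_max Largest result count shown unfiltered.
#' @param large_min Result count beyond which the predicate-rank cut engages.
#' @param top_n Truncation used above `small_max`.
#' @param n_common_predicates Number of globally most frequent predicates
#'   excluded above `large_min` (triple method only).
#' @return A [filter_spec()].
#' @export
dynamic_defaults <- function(results, small_max = 50, large_min = 1000,
                             top_n = 100, n_common_predicates = 5) {
  n <- nrow(results)
  if (n <= small_max) return(filter_spec())
  if (n <= large_min) return(filter_spec(top_n = top_n))
  filter_spec(top_n = top_n, min_pfr = n_common_predicates + 1)
}
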