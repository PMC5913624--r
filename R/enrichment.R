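#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-sided test of association in the table
#' \preformatted{
#'            with key   without key
#'   in set        a          b
#'   outside       c          d
#' }
#' The p-value is the sum, over all tables with the observed margins, of the
#' hypergeometric probabilities not exceeding that of the observed table
#' (the conventional two-sided exact test, with a 1e-7 relative tolerance for
#' ties in the comparison). The odds ratio is the sample estimate
#' `(a*d)/(b*c)`, with `Inf` as the sentinel whenever `b*c == 0`.
#'
#' Inputs are vectorized: all four cells are recycled to a common length and
#' one test is performed per element.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list with numeric vectors `p` and `odds_ratio`.
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop("contingency cells must be non-negative", call. = FALSE)
  }
  p <- vapply(seq_len(n), function(i) {
    fet_p_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
  or <- ifelse(b * c == 0, Inf, (a * d) / (b * c))
  list(p = p, odds_ratio = or)
}

# Two-sided exact p for one table: hypergeometric mass over the support of a
# given fixed margins, summing masses <= observed * (1 + 1e-7).
fet_p_one <- function(a, b, c, d) {
  m <- a + c          # total with key
  nn <- b + d         # total without key
  k <- a + b          # set size
  if (m + nn == 0 || k == 0 || k == m + nn || m == 0 || nn == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  dens <- stats::dhyper(support, m, nn, k)
  obs <- stats::dhyper(a, m, nn, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction: with m tests sorted ascending,
#' `adj_i = min over j >= i of (m * p_j / j)`, clipped to 1 and mapped back
#' to input order. Adjusted values are never below the raw values and their
#' sorted order matches the raw sorted order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, in input order.
#' @export
bh_correct <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, m * p[ord] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Term / triple enrichment of an article set against the corpus
#'
#' For every key the set's members contain (MeSH descriptor, concept, or
#' directed triple depending on `method`), tests over-representation in the
#' set against the rest of the corpus with a two-tailed Fisher's exact test,
#' corrects across all tested keys of this (set, method) family with
#' Benjamini-Hochberg, and retains keys with corrected p below `alpha`
#' (default 1e-5). The 2x2 table is disjoint: set articles are excluded from
#' the background side, with `a` = distinct member articles containing the
#' key, `b = n_members - a`, `c = global - a`, `d = (N - n_members) - c`
#' where `global` is the key's distinct-article corpus frequency and `N` the
#' corpus article count.
#'
#' Results are cached on disk keyed by (store fingerprint, member hash,
#' method, alpha): a repeat call with an identical key reloads the cached
#' table byte-identically; a fingerprint mismatch triggers recomputation with
#' a warning, never silent reuse.
#'
#' @param store A `knowledge_store`.
#' @param set An `article_set`.
#' @param method One of `"mesh"`, `"concept"`, `"triple"`.
#' @param alpha Corrected-p cutoff for the surviving list.
#' @param cache_dir Directory for cached results, or `NULL` to disable
#'   caching.
#' @return An object of class `enrichment_result` with components `table`
#'   (all tested keys: `key`, `uniq`, `global`, `p`, `p_corrected`,
#'   `odds_ratio`), `enriched` (the surviving subset), plus run metadata.
#' @export
enrich <- function(store, set, method = c("mesh", "concept", "triple"),
                   alpha = 1e-5, cache_dir = NULL) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  fp <- store_fingerprint(store)
  member_hash <- md5_of(set$member_ids)
  cache_hit <- FALSE

  if (!is.null(cache_dir)) {
    cached <- cache_load(cache_dir, set$name, method, fp, member_hash, alpha)
    if (!is.null(cached)) {
      tab <- cached
      cache_hit <- TRUE
    }
  }

  if (!cache_hit) {
    occ <- occurrences(store, set, method)
    global <- switch(method,
      triple = store$triple_freq,
      concept = store$concept_article_freq,
      mesh = store$mesh_freq
    )
    n_set <- set$n_members
    n_all <- store$n_articles
    if (nrow(occ) > 0) {
      g <- as.integer(global[occ$key])
      a <- occ$uniq
      b <- n_set - a
      cc <- g - a
      dd <- (n_all - n_set) - cc
      fet <- fisher_two_tailed(a, b, cc, dd)
      tab <- tibble::tibble(
        key = occ$key, uniq = a, global = g,
        p = fet$p, p_corrected = bh_correct(fet$p), odds_ratio = fet$odds_ratio
      )
    } else {
      tab <- tibble::tibble(key = character(), uniq = integer(),
                            global = integer(), p = numeric(),
                            p_corrected = numeric(), odds_ratio = numeric())
    }
    if (!is.null(cache_dir)) {
      cache_save(cache_dir, set$name, method, fp, member_hash, alpha, tab)
    }
  }

  structure(list(
    set_name = set$name,
    member_ids = set$member_ids,
    n_members = set$n_members,
    method = method,
    alpha = alpha,
    table = tab,
    enriched = tab[tab$p_corrected < alpha, , drop = FALSE],
    store_fingerprint = fp,
    cache_hit = cache_hit,
    counting = list(set_side = "distinct_articles", background_side = "distinct_articles",
                    background = "disjoint")
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> set '", x$set_name, "', method ", x$method,
      ": ", nrow(x$enriched), " of ", nrow(x$table),
      " tested key(s) enriched at corrected p < ", format(x$alpha),
      if (x$cache_hit) " [cache hit]", "\n", sep = "")
  invisible(x)
}

# --- cache ------------------------------------------------------------------

cache_paths <- function(cache_dir, set_name, method) {
  slug <- gsub("[^A-Za-z0-9._-]", "_", set_name)
  base <- file.path(cache_dir, paste0("enrich_", slug, "_", method))
  list(tsv = paste0(base, ".tsv"), manifest = paste0(base, ".json"))
}

cache_save <- function(cache_dir, set_name, method, fp, member_hash, alpha, tab) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- cache_paths(cache_dir, set_name, method)
  out <- tab
  for (col in c("p", "p_corrected", "odds_ratio")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_tsv(out, paths$tsv, progress = FALSE)
  manifest <- list(
    store_fingerprint = fp, member_hash = member_hash, method = method,
    alpha = alpha, n_keys = nrow(tab),
    package_version = as.character(utils::packageVersion("litmech"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

cache_load <- function(cache_dir, set_name, method, fp, member_hash, alpha) {
  paths <- cache_paths(cache_dir, set_name, method)
  if (!file.exists(paths$tsv) || !file.exists(paths$manifest)) return(NULL)
  manifest <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  if (!identical(manifest$store_fingerprint, fp) ||
      !identical(manifest$member_hash, member_hash) ||
      !isTRUE(all.equal(manifest$alpha, alpha))) {
    warning("enrichment cache for set '", set_name, "' (", method,
            ") does not match the current store/set; recomputing",
            call. = FALSE)
    return(NULL)
  }
  tab <- readr::read_tsv(
    paths$tsv, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      key = readr::col_character(), uniq = readr::col_integer(),
      global = readr::col_integer(), p = readr::col_double(),
      p_corrected = readr::col_double(), odds_ratio = readr::col_double()
    )
  )
  tibble::as_tibble(tab)
}
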