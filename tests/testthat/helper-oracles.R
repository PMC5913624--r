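# Independent oracles, kept deliberately naive: they recompute quantities by
# enumeration / brute force and must never call the code paths they check.

# Two-sided exact p by exhaustive enumeration of all tables with the observed
# margins; pmf computed from log-binomial coefficients, not dhyper.
fet_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  logpmf <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  pmf <- exp(logpmf)
  obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

# Hand-coded BH step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- pmin(1, m * sorted / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force chaining over two enriched triple-key lists.
overlap_oracle <- function(store, keys_a, keys_b, linking_threshold) {
  out <- list()
  for (ka in keys_a) {
    pa <- strsplit(ka, "\u001f", fixed = TRUE)[[1]]
    for (kb in keys_b) {
      pb <- strsplit(kb, "\u001f", fixed = TRUE)[[1]]
      if (pa[3] != pb[1]) next
      occ <- store$concept_occurrence_freq[pa[3]]
      if (is.na(occ)) occ <- 0
      if (occ >= linking_threshold) next
      out[[length(out) + 1L]] <- c(triple_a = ka, triple_b = kb)
    }
  }
  if (length(out) == 0) {
    return(data.frame(triple_a = character(), triple_b = character()))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$triple_a, df$triple_b), , drop = FALSE]
}

# Naive recount of supporting articles straight from the raw predication rows.
provenance_oracle <- function(predications, key, members) {
  parts <- strsplit(key, "\u001f", fixed = TRUE)[[1]]
  hit <- predications$subject_id == parts[1] &
    predications$predicate == parts[2] &
    predications$object_id == parts[3]
  sort(intersect(unique(predications$article_id[hit]), members))
}

# Small random corpus of raw tables (not via the synthetic generator) used
# for store/overlap equivalence checks.
random_toy_corpus <- function(n_articles = 30, n_concepts = 12, n_rows = 120) {
  concepts <- sprintf("C%03d", seq_len(n_concepts))
  preds <- c("AFFECTS", "CAUSES", "INHIBITS", "TREATS")
  ids <- seq_len(n_articles)
  tibble::tibble(
    article_id = sample(ids, n_rows, replace = TRUE),
    subject_id = sample(concepts, n_rows, replace = TRUE),
    subject_name = "s",
    subject_semtype = "gngm",
    predicate = sample(preds, n_rows, replace = TRUE),
    object_id = sample(concepts, n_rows, replace = TRUE),
    object_name = "o",
    object_semtype = "dsyn"
  )
}

random_toy_mesh <- function(n_articles = 30, n_desc = 8, n_rows = 60) {
  tibble::tibble(
    article_id = sample(seq_len(n_articles), n_rows, replace = TRUE),
    descriptor_id = sprintf("D%06d", sample(n_desc, n_rows, replace = TRUE)),
    descriptor_name = "d",
    is_major = sample(c(TRUE, FALSE), n_rows, replace = TRUE, prob = c(0.7, 0.3))
  )
}

# Hand-built deterministic demo corpus with one obvious planted chain
# (G1 -INHIBITS-> LINK in set A, LINK -CAUSES-> DIS in set B).
demo_corpus <- function() {
  row <- function(aid, s, p, o) {
    tibble::tibble(article_id = aid, subject_id = s, subject_name = tolower(s),
                   subject_semtype = "gngm", predicate = p, object_id = o,
                   object_name = tolower(o), object_semtype = "dsyn")
  }
  a_ids <- 1:10; b_ids <- 11:20; bg_ids <- 21:120
  preds <- dplyr::bind_rows(
    lapply(a_ids, function(i) row(i, "G1", "INHIBITS", "LINK")),
    lapply(b_ids, function(i) row(i, "LINK", "CAUSES", "DIS")),
    lapply(bg_ids, function(i) row(i, sprintf("BG%02d", (i %% 7) + 1),
                                   "AFFECTS", sprintf("BG%02d", (i %% 5) + 10)))
  )
  mesh <- tibble::tibble(
    article_id = c(a_ids, b_ids),
    descriptor_id = rep(c("D000100", "D000200"), c(10, 10)),
    descriptor_name = rep(c("exposure topic", "disease topic"), c(10, 10)),
    is_major = TRUE
  )
  tree <- structure(list(D000100 = "C01.100", D000200 = c("C04", "C04.200.300")),
                    class = "mesh_tree")
  list(predications = preds, mesh = mesh, tree = tree,
       a_ids = a_ids, b_ids = b_ids)
}
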