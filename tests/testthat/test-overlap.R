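demo_pipeline <- function(linking_threshold = 1000) {
  cp <- demo_corpus()
  store <- build_store(cp$predications, cp$mesh, cp$tree)
  sa <- create_article_set(store, "A", cp$a_ids)
  sb <- create_article_set(store, "B", cp$b_ids)
  list(cp = cp, store = store,
       ra = enrich(store, sa, "triple"), rb = enrich(store, sb, "triple"),
       ma = enrich(store, sa, "mesh"), mb = enrich(store, sb, "mesh"))
}

test_that("single-term overlap is the intersection of surviving lists", {
  d <- demo_pipeline()
  shared <- overlap_single(d$ma, d$mb, store = d$store)
  expect_equal(shared$key,
               sort(intersect(d$ma$enriched$key, d$mb$enriched$key)))
  expect_true(all(shared$uniq_a >= 1 & shared$uniq_b >= 1))
  expect_equal(shared$score, eq1_score(shared$uniq_a, shared$uniq_b))
  expect_equal(shared$mean_p_corrected,
               (shared$p_corrected_a + shared$p_corrected_b) / 2)
  expect_error(overlap_single(d$ma, d$rb), "same method")
})

test_that("triple chaining links A-objects to B-subjects below the threshold", {
  d <- demo_pipeline()
  ch <- overlap_triples(d$store, d$ra, d$rb, linking_threshold = 1000)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$subject_a_id, "G1")
  expect_equal(ch$predicate_1, "INHIBITS")
  expect_equal(ch$shared_id, "LINK")
  expect_equal(ch$predicate_2, "CAUSES")
  expect_equal(ch$object_b_id, "DIS")
  expect_equal(ch$uniq_a, 10L)
  expect_equal(ch$score, 20)

  # LINK occurs in 20 (article, slot) units; a threshold at/below that blocks it
  occ <- unname(d$store$concept_occurrence_freq["LINK"])
  expect_equal(
    nrow(overlap_triples(d$store, d$ra, d$rb, linking_threshold = occ)), 0)
  expect_error(overlap_triples(d$store, d$ra, d$rb, linking_threshold = 0),
               "positive")
  expect_error(overlap_triples(d$store, d$ma, d$rb), "triple")
})

test_that("chaining is strictly directional: reversed evidence yields no chains", {
  cp <- demo_corpus()
  # reverse the mechanism: B-articles' triples point INTO the A-side subject
  rev_preds <- cp$predications
  in_a <- rev_preds$article_id %in% cp$a_ids
  in_b <- rev_preds$article_id %in% cp$b_ids
  rev_preds$subject_id[in_a] <- "LINK"; rev_preds$object_id[in_a] <- "G1"
  rev_preds$subject_id[in_b] <- "DIS";  rev_preds$object_id[in_b] <- "LINK"
  store <- build_store(rev_preds, cp$mesh, cp$tree)
  sa <- create_article_set(store, "A", cp$a_ids)
  sb <- create_article_set(store, "B", cp$b_ids)
  ra <- enrich(store, sa, "triple")
  rb <- enrich(store, sb, "triple")
  expect_gt(nrow(ra$enriched), 0)
  expect_gt(nrow(rb$enriched), 0)
  expect_equal(nrow(overlap_triples(store, ra, rb, linking_threshold = 1e6)), 0)
})

test_that("chain sets equal a brute-force double loop on random toy corpora", {
  for (s in 1:10) {
    set.seed(400 + s)
    preds <- random_toy_corpus(n_articles = 40, n_concepts = 8, n_rows = 200)
    store <- build_store(preds)
    sa <- create_article_set(store, "A", 1:15)
    sb <- create_article_set(store, "B", 16:30)
    # relaxed alpha so toy corpora actually produce enriched triples
    ra <- enrich(store, sa, "triple", alpha = 0.5)
    rb <- enrich(store, sb, "triple", alpha = 0.5)
    thr <- sample(c(3, 10, Inf), 1)
    ch <- overlap_triples(store, ra, rb, linking_threshold = thr)
    oracle <- overlap_oracle(store, ra$enriched$key, rb$enriched$key, thr)
    expect_equal(nrow(ch), nrow(oracle))
    if (nrow(ch) > 0) {
      expect_equal(ch$triple_a, oracle$triple_a)
      expect_equal(ch$triple_b, oracle$triple_b)
    }
    # monotonicity: removing the threshold never shrinks the chain set
    ch_all <- overlap_triples(store, ra, rb, linking_threshold = Inf)
    expect_true(all(paste(ch$triple_a, ch$triple_b) %in%
                    paste(ch_all$triple_a, ch_all$triple_b)))

    # cartesian expansion around each shared term
    if (nrow(ch_all) > 0) {
      pa <- triple_key_parts(ra$enriched$key)
      pb <- triple_key_parts(rb$enriched$key)
      n_expected <- sum(vapply(unique(pa$object_id), function(x) {
        sum(pa$object_id == x) * sum(pb$subject_id == x)
      }, numeric(1)))
      expect_equal(nrow(ch_all), n_expected)
    }
  }
})

test_that("provenance lists match naive recounts of the raw rows", {
  for (s in 1:5) {
    set.seed(500 + s)
    preds <- random_toy_corpus(n_articles = 30, n_concepts = 8, n_rows = 150)
    # guarantee at least one chainable signal on top of the random background
    planted <- tibble::tibble(
      article_id = c(1:6, 13:18),
      subject_id = rep(c("GX", "LX"), c(6, 6)), subject_name = "s",
      subject_semtype = "gngm",
      predicate = rep(c("INHIBITS", "CAUSES"), c(6, 6)),
      object_id = rep(c("LX", "DX"), c(6, 6)), object_name = "o",
      object_semtype = "dsyn")
    preds <- dplyr::bind_rows(preds, planted)
    store <- build_store(preds)
    sa <- create_article_set(store, "A", 1:12)
    sb <- create_article_set(store, "B", 13:24)
    ra <- enrich(store, sa, "triple", alpha = 0.5)
    rb <- enrich(store, sb, "triple", alpha = 0.5)
    ch <- overlap_triples(store, ra, rb, linking_threshold = Inf)
    ch <- attach_provenance(store, ch, ra, rb)
    if (nrow(ch) == 0) next
    expect_equal(lengths(ch$articles_a), ch$uniq_a)
    expect_equal(lengths(ch$articles_b), ch$uniq_b)
    for (i in seq_len(nrow(ch))) {
      expect_equal(ch$articles_a[[i]],
                   provenance_oracle(preds, ch$triple_a[i], ra$member_ids))
      expect_equal(ch$articles_b[[i]],
                   provenance_oracle(preds, ch$triple_b[i], rb$member_ids))
    }
  }
})
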