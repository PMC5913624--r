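small_config <- function(...) {
  corpus_config(n_articles_a = 20, n_articles_b = 20,
                n_background_articles = 100, n_background_concepts = 60,
                n_planted_chains = 2, n_common_terms = 1,
                linking_threshold = 20, ...)
}

test_that("planted triples hit exact ceiling(penetrance * n) member articles", {
  corpus <- generate_corpus(small_config(penetrance_a = 0.5, penetrance_b = 0.13,
                                         seed = 2))
  truth <- corpus$truth$planted_chains
  p <- corpus$predications
  for (i in seq_len(nrow(truth))) {
    in_a <- p$subject_id == truth$subject[i] & p$predicate == truth$predicate_1[i] &
      p$object_id == truth$link[i]
    expect_equal(sort(unique(p$article_id[in_a])), truth$articles_a[[i]])
    expect_length(truth$articles_a[[i]], ceiling(0.5 * 20))
    expect_length(truth$articles_b[[i]], ceiling(0.13 * 20))
    expect_true(all(truth$articles_a[[i]] %in% corpus$set_a_ids))
    expect_true(all(truth$articles_b[[i]] %in% corpus$set_b_ids))
  }
})

test_that("the same seed reproduces byte-identical corpus files", {
  d1 <- tempfile("corpus1"); d2 <- tempfile("corpus2")
  generate_corpus(small_config(seed = 9), out_dir = d1)
  generate_corpus(small_config(seed = 9), out_dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- tempfile("corpus3")
  generate_corpus(small_config(seed = 10), out_dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "predications.tsv"))),
    unname(tools::md5sum(file.path(d3, "predications.tsv")))))
})

test_that("injected common terms exceed the linking threshold; rate 0 injects none", {
  corpus <- generate_corpus(corpus_config(seed = 4))
  store <- build_store(corpus$predications, corpus$mesh_annotations)
  for (g in corpus$truth$common_terms) {
    expect_gt(unname(store$concept_occurrence_freq[g]),
              corpus$config$linking_threshold)
  }
  quiet <- generate_corpus(small_config(common_term_rate = 0, seed = 4))
  expect_length(quiet$truth$common_terms, 0)
})

test_that("ground truth is recountable from the emitted files", {
  dir <- tempfile("corpus")
  corpus <- generate_corpus(small_config(seed = 5), out_dir = dir)
  preds <- read_predications(file.path(dir, "predications.tsv"))
  expect_equal(as.data.frame(preds), as.data.frame(corpus$predications),
               ignore_attr = TRUE)
  truth <- corpus$truth$planted_chains
  for (i in seq_len(nrow(truth))) {
    key <- triple_key(truth$link[i], truth$predicate_2[i], truth$object[i])
    expect_equal(provenance_oracle(preds, key, corpus$set_b_ids),
                 truth$articles_b[[i]])
  }
})

test_that("config contracts reject impossible vocabularies and rates", {
  expect_error(corpus_config(n_background_concepts = 10, n_planted_chains = 5),
               "vocabulary too small")
  expect_error(corpus_config(penetrance_a = 0), "penetrance_a")
  expect_error(corpus_config(zipf_exponent = -1), "zipf_exponent")
})

test_that("recovery metrics count matches by identity 5-tuple", {
  corpus <- generate_corpus(small_config(seed = 6))
  truth <- corpus$truth
  planted <- truth$planted_chains
  as_chain <- function(i) tibble::tibble(
    subject_a_id = planted$subject[i], subject_a_name = "", subject_a_semtype = "",
    predicate_1 = planted$predicate_1[i],
    shared_id = planted$link[i], shared_name = "", shared_semtype = "",
    predicate_2 = planted$predicate_2[i],
    object_b_id = planted$object[i], object_b_name = "",
    triple_a = triple_key(planted$subject[i], planted$predicate_1[i], planted$link[i]),
    triple_b = triple_key(planted$link[i], planted$predicate_2[i], planted$object[i]),
    uniq_a = 4L, uniq_b = 4L, score = 8, mean_p_corrected = 1e-9
  )
  bogus <- as_chain(1) |> dplyr::mutate(predicate_1 = "TREATS", score = 3)

  full <- dplyr::bind_rows(as_chain(1), as_chain(2))
  ev <- evaluate_recovery(full, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)

  half <- dplyr::bind_rows(as_chain(1), bogus)
  ev2 <- evaluate_recovery(half, truth)
  expect_equal(ev2$recall, 0.5)
  expect_equal(ev2$precision, 0.5)
  expect_equal(ev2$rank_of_planted, 1L)  # higher score ranks first

  ev3 <- evaluate_recovery(full[0, ], truth)
  expect_equal(ev3$recall, 0)
  expect_equal(ev3$precision, 1)  # no false claims by convention
})
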