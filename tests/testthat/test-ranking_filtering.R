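fake_chains <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_a_id = sprintf("S%02d", seq_len(n)),
    subject_a_name = sprintf("subject %d", seq_len(n)),
    subject_a_semtype = "gngm",
    predicate_1 = sample(c("INHIBITS", "AFFECTS", "CAUSES"), n, replace = TRUE),
    shared_id = sprintf("X%02d", sample(5, n, replace = TRUE)),
    shared_name = sprintf("linker %d", sample(5, n, replace = TRUE)),
    shared_semtype = "aapp",
    predicate_2 = sample(c("ASSOCIATED_WITH", "TREATS"), n, replace = TRUE),
    object_b_id = sprintf("O%02d", seq_len(n)),
    object_b_name = sprintf("object %d", seq_len(n)),
    triple_a = sprintf("ta%03d", seq_len(n)),
    triple_b = sprintf("tb%03d", seq_len(n)),
    uniq_a = sample(1:20, n, replace = TRUE),
    uniq_b = sample(1:20, n, replace = TRUE),
    p_corrected_a = runif(n, 0, 1e-4),
    p_corrected_b = runif(n, 0, 1e-4),
    odds_ratio_a = runif(n, 0.5, 30),
    odds_ratio_b = runif(n, 0.5, 30),
    pfr_1 = sample(1:8, n, replace = TRUE),
    pfr_2 = sample(1:8, n, replace = TRUE)
  ) |>
    dplyr::mutate(score = eq1_score(uniq_a, uniq_b),
                  mean_p_corrected = (p_corrected_a + p_corrected_b) / 2)
}

test_that("balance score matches hand-derived values and its properties", {
  expect_equal(eq1_score(5, 5), 10)
  expect_equal(eq1_score(2, 8), 2.5)
  expect_equal(eq1_score(1, 100), 1.01)
  expect_lt(eq1_score(1, 100), eq1_score(5, 5))  # balance beats raw total
  expect_error(eq1_score(0, 3), ">= 1")

  grid <- expand.grid(a = 1:12, b = 1:12)
  s <- eq1_score(grid$a, grid$b)
  expect_equal(s, eq1_score(grid$b, grid$a))          # symmetric
  expect_true(all(s <= grid$a + grid$b))              # bounded by total
  for (mx in 3:12) {                                  # increasing in min side
    vals <- eq1_score(1:mx, rep(mx, mx))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("orderings are total, deterministic and key-appropriate", {
  ch <- fake_chains(25)
  by_score <- order_results(ch, "score")
  expect_true(all(diff(by_score$score) <= 0))
  by_p <- order_results(ch, "mean_p_corrected")
  expect_true(all(diff(by_p$mean_p_corrected) >= 0))
  by_pfr <- order_results(ch, "pfr")
  expect_true(all(diff(pmin(by_pfr$pfr_1, by_pfr$pfr_2)) <= 0))

  # equal scores: larger total support first
  tie <- ch[1:2, ]
  tie$uniq_a <- c(5L, 3L); tie$uniq_b <- c(5L, 3L)
  tie$score <- eq1_score(tie$uniq_a, tie$uniq_b) * 0 + 1  # force equal scores
  ordered <- order_results(tie, "score")
  expect_equal(ordered$uniq_a[1], 5L)

  shared <- tibble::tibble(key = c("D1", "D2"), uniq_a = c(2L, 3L),
                           uniq_b = c(2L, 3L), p_corrected_a = 1e-7,
                           p_corrected_b = 1e-7, odds_ratio_a = 5,
                           odds_ratio_b = 5, score = eq1_score(c(2, 3), c(2, 3)),
                           mean_p_corrected = 1e-7, mesh_depth = c(3L, 1L))
  expect_equal(order_results(shared, "mesh_depth")$key, c("D1", "D2"))
  expect_error(order_results(shared, "pfr"), "triple")
  expect_error(order_results(fake_chains(3), "mesh_depth"), "mesh")
})

test_that("filters stage in fixed order and record survivor counts", {
  ch <- fake_chains(60, seed = 3)
  spec <- filter_spec(max_mean_p_corrected = 5e-5, min_odds_ratio = 2, top_n = 5)
  out <- apply_filters(ch, spec)
  counts <- attr(out, "stage_counts")
  expect_true(all(diff(counts) <= 0))  # never increases
  expect_lte(nrow(out), 5)

  # brute-force check of the same spec
  manual <- ch[ch$mean_p_corrected <= 5e-5 &
               ch$odds_ratio_a >= 2 & ch$odds_ratio_b >= 2, ]
  expect_equal(unname(counts["odds_ratio"]), nrow(manual))
  manual <- order_results(manual, "score")
  expect_equal(out$triple_a, manual$triple_a[seq_len(min(5, nrow(manual)))])

  # row-order invariance of the survivor set
  out2 <- apply_filters(ch[sample(nrow(ch)), ], spec)
  expect_setequal(out2$triple_a, out$triple_a)
})

test_that("keyword include/restrict semantics act on the named position", {
  ch <- fake_chains(40, seed = 9)
  drop <- apply_filters(ch, filter_spec(exclude_keywords = list(shared = "linker 3")))
  expect_false(any(grepl("linker 3", drop$shared_name)))
  expect_equal(nrow(drop), sum(!grepl("linker 3", ch$shared_name)))

  keep <- apply_filters(ch, filter_spec(include_keywords = list(shared = "X01")))
  expect_true(all(keep$shared_id == "X01"))
  expect_equal(nrow(keep), sum(ch$shared_id == "X01"))

  pred <- apply_filters(ch, filter_spec(include_keywords = list(predicate_1 = "inhibits")))
  expect_true(all(pred$predicate_1 == "INHIBITS"))  # case-insensitive

  expect_error(filter_spec(include_keywords = list(shared = "x"),
                           exclude_keywords = list(shared = "x")),
               "included and excluded")
  expect_error(filter_spec(include_keywords = list(bogus = "x")), "position")
})

test_that("dynamic first-pass defaults scale with result volume", {
  expect_equal(dynamic_defaults(fake_chains(10))$top_n, Inf)
  mid <- dynamic_defaults(fake_chains(500))
  expect_equal(mid$top_n, 100)
  expect_equal(mid$min_pfr, 0)
  big <- dynamic_defaults(fake_chains(1500))
  expect_equal(big$top_n, 100)
  expect_equal(big$min_pfr, 6)
  # and the large-volume spec actually truncates
  out <- apply_filters(fake_chains(1500), big)
  expect_lte(nrow(out), 100)
  expect_true(all(pmin(out$pfr_1, out$pfr_2) >= 6))
})
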