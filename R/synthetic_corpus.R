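PREDICATE_VOCAB <- c(
  "ASSOCIATED_WITH", "AFFECTS", "COEXISTS_WITH", "PROCESS_OF", "PART_OF",
  "INTERACTS_WITH", "CAUSES", "TREATS", "STIMULATES", "INHIBITS",
  "PREDISPOSES", "AUGMENTS"
)

#' Configuration for the synthetic corpus generator
#'
#' Describes a study corpus with two article sets (A and B), a background
#' literature, Zipf-distributed background concept usage, a handful of
#' planted mechanism chains A -> X -> B, and injected ubiquitous
#' ("Patients"/"Cells"-like) concepts whose global occurrence exceeds the
#' linking-term threshold. Defaults define the package's reference study
#' conditions: 200-article sets over a 2,000-article background, a
#' 500-concept vocabulary with Zipf exponent 1.2, five planted chains at
#' penetrance 0.1, three injected common terms and a linking threshold
#' rescaled to 100 occurrences (the published full-corpus value of 150,000 is
#' meaningless at this corpus size).
#'
#' @param n_articles_a,n_articles_b,n_background_articles Article counts.
#' @param n_background_concepts Concept vocabulary size.
#' @param zipf_exponent Exponent of the rank-frequency law used to sample
#'   background concepts (> 0; larger means more skew).
#' @param n_planted_chains Number of planted mechanism chains.
#' @param penetrance_a,penetrance_b Fraction of set members carrying each
#'   planted triple, in (0, 1].
#' @param n_common_terms Number of injected above-threshold common concepts.
#' @param common_term_rate Per-article probability of receiving a triple that
#'   mentions an injected common term.
#' @param triples_per_article Mean background triples per article (>= 1).
#' @param linking_threshold Linking-term occurrence cap used downstream.
#' @param bernoulli If `TRUE`, planted triples are Bernoulli-sampled per
#'   article at the penetrance rate (for power studies); the default plants
#'   exact `ceiling(penetrance * n)` counts so contingency tables are known.
#' @param seed Integer RNG seed; the corpus is a pure function of the config.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_articles_a = 200, n_articles_b = 200,
                          n_background_articles = 2000,
                          n_background_concepts = 500,
                          zipf_exponent = 1.2,
                          n_planted_chains = 5,
                          penetrance_a = 0.1, penetrance_b = 0.1,
                          n_common_terms = 3, common_term_rate = 0.3,
                          triples_per_article = 4,
                          linking_threshold = 100,
                          bernoulli = FALSE,
                          seed = 1) {
  stopifnot(
    n_articles_a >= 1, n_articles_b >= 1, n_background_articles >= 0,
    n_background_concepts >= 1, zipf_exponent > 0,
    n_planted_chains >= 0,
    penetrance_a > 0, penetrance_a <= 1, penetrance_b > 0, penetrance_b <= 1,
    n_common_terms >= 0, common_term_rate >= 0, common_term_rate <= 1,
    triples_per_article >= 1, linking_threshold > 0
  )
  n_reserved <- 3 * n_planted_chains + n_common_terms
  if (n_reserved >= n_background_concepts) {
    stop("concept vocabulary too small: ", n_reserved,
         " reserved planted/common concepts need a vocabulary larger than ",
         n_background_concepts, call. = FALSE)
  }
  structure(list(
    n_articles_a = n_articles_a, n_articles_b = n_articles_b,
    n_background_articles = n_background_articles,
    n_background_concepts = n_background_concepts,
    zipf_exponent = zipf_exponent,
    n_planted_chains = n_planted_chains,
    penetrance_a = penetrance_a, penetrance_b = penetrance_b,
    n_common_terms = n_common_terms, common_term_rate = common_term_rate,
    triples_per_article = triples_per_article,
    linking_threshold = linking_threshold,
    bernoulli = bernoulli,
    seed = as.integer(seed)
  ), class = "corpus_config")
}

concept_label <- function(i) sprintf("C%07d", i)
descriptor_of <- function(concept_id) sub("^C", "D", concept_id)

#' Generate a synthetic literature corpus with planted mechanisms
#'
#' Emits the four input files the pipeline consumes (predications, MeSH
#' annotations, MeSH tree, PMID lists for sets A and B) plus the ground truth
#' needed to score recovery. Background triples draw subject and object
#' concepts from a Zipf rank-frequency law over the non-reserved vocabulary,
#' independently of set membership, so background keys carry no true signal.
#' Each planted chain (S_i, P1_i, X_i, P2_i, O_i) places its first triple in
#' exactly `ceiling(penetrance_a * n_articles_a)` distinct set-A articles and
#' its second in `ceiling(penetrance_b * n_articles_b)` set-B articles.
#' Injected common terms are scattered across the whole corpus until their
#' occurrence counts sit far above the linking threshold, and each also forms
#' a decoy chain at planted penetrance so the linking-term filter is
#' genuinely exercised. The MeSH side mirrors the concept side: each
#' article's concepts are annotated as major descriptors (with per-article
#' dropout noise on the background side), so all three enrichment methods are
#' testable from one corpus.
#'
#' @param config A [corpus_config()].
#' @param out_dir Directory to write corpus files into, or `NULL` to skip
#'   writing and return tables only.
#' @return A list with the corpus tables (`predications`,
#'   `mesh_annotations`, `mesh_tree`, `set_a_ids`, `set_b_ids`), file `paths`
#'   (when written), the `config`, and `truth` (planted chains with their
#'   supporting article IDs, decoy chains, and injected common terms).
#' @export
generate_corpus <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  ids_a <- 1000000L + seq_len(config$n_articles_a)
  ids_b <- 2000000L + seq_len(config$n_articles_b)
  ids_bg <- if (config$n_background_articles > 0) {
    3000000L + seq_len(config$n_background_articles)
  } else integer()
  all_ids <- c(ids_a, ids_b, ids_bg)

  vocab <- concept_label(seq_len(config$n_background_concepts))
  n_chain_concepts <- 3 * config$n_planted_chains
  reserved <- utils::tail(vocab, n_chain_concepts + config$n_common_terms)
  background_vocab <- setdiff(vocab, reserved)
  chain_concepts <- utils::head(reserved, n_chain_concepts)
  common_terms <- utils::tail(reserved, config$n_common_terms)
  if (config$n_common_terms == 0) common_terms <- character()

  # background rank-frequency law
  w <- seq_along(background_vocab)^(-config$zipf_exponent)
  w <- w / sum(w)
  pred_w <- seq_along(PREDICATE_VOCAB)^(-1)
  pred_w <- pred_w / sum(pred_w)

  rows <- list()
  add_rows <- function(article_id, subject_id, predicate, object_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      article_id = as.integer(article_id), subject_id = subject_id,
      predicate = predicate, object_id = object_id
    )
  }

  # background triples for every article
  n_tr <- 1L + stats::rpois(length(all_ids), config$triples_per_article - 1)
  art_rep <- rep(all_ids, n_tr)
  total <- sum(n_tr)
  subj <- sample(background_vocab, total, replace = TRUE, prob = w)
  obj <- sample(background_vocab, total, replace = TRUE, prob = w)
  clash <- subj == obj
  while (any(clash)) {
    obj[clash] <- sample(background_vocab, sum(clash), replace = TRUE, prob = w)
    clash <- subj == obj
  }
  preds <- sample(PREDICATE_VOCAB, total, replace = TRUE, prob = pred_w)
  add_rows(art_rep, subj, preds, obj)

  # injected ubiquitous concepts, scattered corpus-wide
  if (config$n_common_terms > 0 && config$common_term_rate > 0) {
    hit <- stats::runif(length(all_ids)) < config$common_term_rate
    if (any(hit)) {
      g <- sample(common_terms, sum(hit), replace = TRUE)
      partner <- sample(background_vocab, sum(hit), replace = TRUE, prob = w)
      as_subject <- stats::runif(sum(hit)) < 0.5
      add_rows(all_ids[hit][as_subject], g[as_subject], "PROCESS_OF",
               partner[as_subject])
      add_rows(all_ids[hit][!as_subject], partner[!as_subject], "PROCESS_OF",
               g[!as_subject])
    }
  }

  plant_side <- function(article_pool, penetrance) {
    if (config$bernoulli) {
      article_pool[stats::runif(length(article_pool)) < penetrance]
    } else {
      k <- ceiling(penetrance * length(article_pool))
      sort(sample(article_pool, k))
    }
  }

  planted <- NULL
  if (config$n_planted_chains > 0) {
    chain_pred_1 <- rep_len(c("INHIBITS", "STIMULATES", "INTERACTS_WITH"),
                            config$n_planted_chains)
    chain_pred_2 <- rep_len(c("ASSOCIATED_WITH", "CAUSES", "PREDISPOSES"),
                            config$n_planted_chains)
    planted <- tibble::tibble(
      subject = chain_concepts[seq(1, n_chain_concepts, by = 3)],
      predicate_1 = chain_pred_1,
      link = chain_concepts[seq(2, n_chain_concepts, by = 3)],
      predicate_2 = chain_pred_2,
      object = chain_concepts[seq(3, n_chain_concepts, by = 3)]
    )
    planted$articles_a <- vector("list", nrow(planted))
    planted$articles_b <- vector("list", nrow(planted))
    for (i in seq_len(nrow(planted))) {
      arts_a <- plant_side(ids_a, config$penetrance_a)
      arts_b <- plant_side(ids_b, config$penetrance_b)
      add_rows(arts_a, planted$subject[i], planted$predicate_1[i], planted$link[i])
      add_rows(arts_b, planted$link[i], planted$predicate_2[i], planted$object[i])
      planted$articles_a[[i]] <- arts_a
      planted$articles_b[[i]] <- arts_b
    }
  }

  # decoy chains routed through the common terms: enriched on both sides but
  # linked by an above-threshold concept, so the linking filter must drop them
  decoys <- NULL
  if (config$n_common_terms > 0 && config$n_planted_chains > 0) {
    decoys <- tibble::tibble(
      subject = planted$subject[rep_len(seq_len(nrow(planted)), config$n_common_terms)],
      predicate_1 = "AFFECTS",
      link = common_terms,
      predicate_2 = "AFFECTS",
      object = planted$object[rep_len(seq_len(nrow(planted)), config$n_common_terms)]
    )
    for (i in seq_len(nrow(decoys))) {
      add_rows(plant_side(ids_a, config$penetrance_a),
               decoys$subject[i], decoys$predicate_1[i], decoys$link[i])
      add_rows(plant_side(ids_b, config$penetrance_b),
               decoys$link[i], decoys$predicate_2[i], decoys$object[i])
    }
  }

  pred_tab <- do.call(rbind, rows)
  pred_tab <- pred_tab[order(pred_tab$article_id, pred_tab$subject_id,
                             pred_tab$predicate, pred_tab$object_id), ]
  predications <- tibble::tibble(
    article_id = pred_tab$article_id,
    subject_id = pred_tab$subject_id,
    subject_name = concept_name(pred_tab$subject_id),
    subject_semtype = semtype_of(pred_tab$subject_id),
    predicate = pred_tab$predicate,
    object_id = pred_tab$object_id,
    object_name = concept_name(pred_tab$object_id),
    object_semtype = semtype_of(pred_tab$object_id)
  )

  # MeSH mirror: annotate each article's concepts as major descriptors, with
  # dropout noise on background concepts and occasional non-major extras
  slots <- unique(rbind(
    data.frame(article_id = predications$article_id, concept = predications$subject_id),
    data.frame(article_id = predications$article_id, concept = predications$object_id)
  ))
  is_reserved <- slots$concept %in% reserved
  keep <- is_reserved | stats::runif(nrow(slots)) < 0.7
  major_ann <- slots[keep, ]
  extra_idx <- stats::runif(length(all_ids)) < 0.2
  extra <- data.frame(
    article_id = all_ids[extra_idx],
    concept = sample(background_vocab, sum(extra_idx), replace = TRUE, prob = w)
  )
  mesh_annotations <- tibble::tibble(
    article_id = c(major_ann$article_id, extra$article_id),
    descriptor_id = descriptor_of(c(major_ann$concept, extra$concept)),
    descriptor_name = concept_name(c(major_ann$concept, extra$concept)),
    is_major = c(rep(TRUE, nrow(major_ann)), rep(FALSE, nrow(extra)))
  )
  mesh_annotations <- mesh_annotations[order(mesh_annotations$article_id,
                                             mesh_annotations$descriptor_id), ]

  # tree: every descriptor gets one position at depth 1..4
  all_desc <- sort(unique(descriptor_of(vocab)))
  depth <- sample(1:4, length(all_desc), replace = TRUE)
  tree_nums <- vapply(seq_along(all_desc), function(i) {
    paste(c("C04", sprintf("%03d", sample(999, depth[i] - 1, replace = TRUE))),
          collapse = ".")
  }, character(1))
  mesh_tree <- structure(as.list(tree_nums), names = all_desc, class = "mesh_tree")

  truth <- list(
    planted_chains = planted,
    decoy_chains = decoys,
    common_terms = if (config$common_term_rate > 0) common_terms else character(),
    linking_threshold = config$linking_threshold
  )

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      predications = file.path(out_dir, "predications.tsv"),
      mesh_annotations = file.path(out_dir, "mesh_annotations.tsv"),
      mesh_tree = file.path(out_dir, "mesh_tree.tsv"),
      set_a = file.path(out_dir, "set_a.pmids"),
      set_b = file.path(out_dir, "set_b.pmids")
    )
    write_corpus_table(predications, paths$predications)
    write_corpus_table(mesh_annotations, paths$mesh_annotations)
    write_mesh_tree(mesh_tree, paths$mesh_tree)
    write_pmid_list(ids_a, paths$set_a)
    write_pmid_list(ids_b, paths$set_b)
  }

  list(
    predications = predications,
    mesh_annotations = tibble::as_tibble(mesh_annotations),
    mesh_tree = mesh_tree,
    set_a_ids = ids_a,
    set_b_ids = ids_b,
    paths = paths,
    config = config,
    truth = truth
  )
}

concept_name <- function(concept_id) paste0("concept ", sub("^C0*", "", concept_id))
semtype_of <- function(concept_id) {
  types <- c("gngm", "dsyn", "aapp", "orch", "celf")
  types[(as.integer(sub("^C", "", concept_id)) %% length(types)) + 1L]
}

#' Score recovery of planted mechanism chains
#'
#' Matches reported chains to the planted ground truth on the identity
#' 5-tuple (subject, predicate 1, link, predicate 2, object).
#'
#' @param chains Tibble from [overlap_triples()] on the generated corpus.
#' @param truth The `truth` component returned by [generate_corpus()].
#' @return A list with `recall` (fraction of planted chains recovered),
#'   `precision` (fraction of reported chains that are planted; 1 by
#'   convention when nothing is reported), `rank_of_planted` (positions of
#'   the recovered planted chains when chains are ordered by score), and
#'   `common_term_leaks` (reported chains linked through an injected common
#'   term, which a correct linking filter reduces to zero).
#' @export
evaluate_recovery <- function(chains, truth) {
  tuple <- function(s, p1, x, p2, o) paste(s, p1, x, p2, o, sep = "\u001f")
  planted <- if (is.null(truth$planted_chains)) character() else with(
    truth$planted_chains, tuple(subject, predicate_1, link, predicate_2, object)
  )
  reported <- if (nrow(chains) == 0) character() else unique(with(
    chains, tuple(subject_a_id, predicate_1, shared_id, predicate_2, object_b_id)
  ))
  recall <- if (length(planted) == 0) 1 else mean(planted %in% reported)
  precision <- if (length(reported) == 0) 1 else mean(reported %in% planted)
  rank_of_planted <- integer()
  if (nrow(chains) > 0) {
    ranked <- order_results(chains, "score")
    rtup <- with(ranked, tuple(subject_a_id, predicate_1, shared_id,
                               predicate_2, object_b_id))
    rtup <- unique(rtup)
    rank_of_planted <- sort(match(planted, rtup))
    rank_of_planted <- rank_of_planted[!is.na(rank_of_planted)]
  }
  leaks <- if (nrow(chains) == 0) character() else
    intersect(unique(chains$shared_id), truth$common_terms)
  list(recall = recall, precision = precision,
       rank_of_planted = rank_of_planted, common_term_leaks = leaks)
}
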