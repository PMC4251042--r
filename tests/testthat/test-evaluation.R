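test_that("cross-validation plans group targets and balance fold sizes", {
  ids <- sprintf("t%02d", 1:20)
  plan <- make_cv_plan(ids, n_folds = 10, seed = 1)
  expect_equal(unname(table(plan$fold)), rep(2L, 10), ignore_attr = TRUE)
  expect_identical(plan, make_cv_plan(ids, n_folds = 10, seed = 1))
  expect_false(identical(plan$fold[order(plan$target_id)],
                         make_cv_plan(ids, 10, seed = 2)$fold[order(plan$target_id)]))
  expect_error(make_cv_plan(ids[1:5], n_folds = 10), "at least 10 targets")
  # all pairs of one target land in one fold by construction
  pairs <- enumerate_pairs(tiny_proteins())
  plan2 <- make_cv_plan(tiny_proteins(), n_folds = 5, seed = 3)
  joined <- dplyr::left_join(pairs, plan2, by = "target_id")
  per_target <- dplyr::summarise(joined, k = dplyr::n_distinct(fold),
                                 .by = target_id)
  expect_true(all(per_target$k == 1))
})

test_that("leakage removal drops pairs templated on test-fold targets", {
  pairs <- tibble::tibble(
    target_id = c("a", "a", "b", "c", "c"),
    template_id = c("b", "c", "c", "a", "b"),
    relationship = "none", positive = FALSE
  )
  plan <- tibble::tibble(target_id = c("a", "b", "c"), fold = c(1L, 2L, 2L))
  attr(plan, "n_folds") <- 2L
  train <- training_pairs_for_fold(pairs, plan, 1)
  # c->a uses the test-fold target 'a' as template and must go;
  # b->c and c->b lie fully outside the test fold and stay
  expect_setequal(paste(train$target_id, train$template_id), c("b c", "c b"))
  expect_error(training_pairs_for_fold(pairs, plan, 3), "unknown fold")
  # test fold holding every target leaves nothing to train on
  plan_all <- tibble::tibble(target_id = c("a", "b", "c"), fold = 1L)
  attr(plan_all, "n_folds") <- 1L
  expect_error(training_pairs_for_fold(pairs, plan_all, 1), "empty training")
})

test_that("leakage removal keeps pairs fully outside the test fold", {
  feats <- tiny_features()
  plan <- make_cv_plan(feats, n_folds = 4, seed = 2)
  held <- plan$target_id[plan$fold == 1]
  train <- training_pairs_for_fold(feats, plan, 1)
  expect_false(any(train$target_id %in% held))
  expect_false(any(train$template_id %in% held))
  outside <- dplyr::filter(feats, !target_id %in% held, !template_id %in% held)
  expect_equal(nrow(train), nrow(outside))
})

test_that("negative subsampling keeps positives and caps at availability", {
  pairs <- tibble::tibble(
    target_id = sprintf("t%03d", 1:204),
    template_id = "x",
    relationship = c(rep("family", 4), rep("none", 200)),
    positive = c(rep(TRUE, 4), rep(FALSE, 200))
  )
  sub <- subsample_negatives(pairs, ratio = 25, seed = 1)
  expect_equal(sum(sub$positive), 4)
  expect_equal(sum(!sub$positive), 100)
  expect_equal(sum(!subsample_negatives(pairs, 1, 1)$positive), 4)
  # ratio above availability keeps everything
  expect_equal(nrow(subsample_negatives(pairs, 1000, 1)), nrow(pairs))
  expect_identical(subsample_negatives(pairs, 25, seed = 7),
                   subsample_negatives(pairs, 25, seed = 7))
  expect_error(subsample_negatives(dplyr::filter(pairs, !positive), 25, 1),
               "no positive")
  expect_error(subsample_negatives(pairs, 0, 1), "positive")
})

test_that("template ranking is descending with lexicographic tie-breaks", {
  scores <- tibble::tibble(
    target_id = "t",
    template_id = c("z", "a", "m", "b"),
    prob = c(0.1, 0.9, 0.5, 0.5)
  )
  r <- rank_templates(scores)
  expect_equal(r$template_id, c("a", "b", "m", "z"))
  expect_equal(r$rank, 1:4)
  expect_error(rank_templates(scores[0, ]), "no scored templates")
  single <- rank_templates(tibble::tibble(target_id = "t", template_id = "q",
                                          prob = 0.3))
  expect_equal(single$rank, 1L)
})

test_that("top-k sensitivity counts hand-enumerated fixtures correctly", {
  # 3 eligible targets; correct family template at rank 1, 3 and 7
  mk_target <- function(tid, correct_rank) {
    tibble::tibble(
      target_id = tid,
      template_id = sprintf("%s_m%02d", tid, 1:10),
      relationship = ifelse(seq_len(10) == correct_rank, "family", "none"),
      prob = seq(1, 0.1, length.out = 10)
    )
  }
  scores <- dplyr::bind_rows(mk_target("t1", 1), mk_target("t2", 3),
                             mk_target("t3", 7))
  t1 <- topk_sensitivity(scores, "family", 1)
  t5 <- topk_sensitivity(scores, "family", 5)
  expect_equal(t1$hits, 1)
  expect_equal(t1$eligible, 3)
  expect_equal(t1$sensitivity_pct, 100 / 3)
  expect_equal(t5$hits, 2)
  expect_equal(t5$sensitivity_pct, 200 / 3)
  expect_gte(t5$hits, t1$hits)
  expect_error(topk_sensitivity(dplyr::mutate(scores, relationship = "none"),
                                "family", 1), "no eligible")
})

test_that("higher-level relatives are excluded before scoring a level", {
  # family relative ranked 1st would mask the superfamily hit at rank 2
  scores <- tibble::tibble(
    target_id = "t",
    template_id = c("fam", "sf", "fold", "bg"),
    relationship = c("family", "superfamily", "fold", "none"),
    prob = c(0.9, 0.8, 0.7, 0.6)
  )
  expect_equal(topk_sensitivity(scores, "superfamily", 1)$hits, 1)
  expect_equal(topk_sensitivity(scores, "fold", 1)$hits, 1)
  expect_equal(topk_sensitivity(scores, "family", 1)$hits, 1)
  # exclusion removes family relatives but does not promote the level past
  # a better-scoring fold or background template
  masked <- dplyr::mutate(scores, prob = c(0.9, 0.2, 0.7, 0.6))
  expect_equal(topk_sensitivity(masked, "superfamily", 1)$hits, 0)
  expect_equal(topk_sensitivity(masked, "superfamily", 5)$hits, 1)
})

test_that("pair error rate is the misclassified percentage", {
  expect_equal(pair_error_rate(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(pair_error_rate(c(rep(0, 199), 1), c(rep(0, 199), 0)), 0.5)
  expect_error(pair_error_rate(integer(), integer()), "no pairs")
  expect_error(pair_error_rate(c(0, 1), c(0)), "length mismatch")
  # an all-negative predictor errs on exactly the positive fraction
  expect_equal(pair_error_rate(rep(0, 951600),
                               c(rep(1, 7438), rep(0, 944162))),
               100 * 7438 / 951600)
})

test_that("cross-validation runs end to end, deterministically", {
  feats <- tiny_features()
  params <- forest_params(n_trees = 10, seed = 2)
  cv1 <- run_cross_validation(feats, params = params, n_folds = 4, seed = 5)
  cv2 <- run_cross_validation(feats, params = params, n_folds = 4, seed = 5)
  expect_identical(cv1$report, cv2$report)
  expect_identical(cv1$error_rate, cv2$error_rate)
  # every ordered pair is scored exactly once across the folds
  expect_equal(nrow(cv1$scores), nrow(feats))
  expect_equal(dplyr::n_distinct(paste(cv1$scores$target_id,
                                       cv1$scores$template_id)), nrow(feats))
  # top-5 dominates top-1 at every level
  expect_true(all(cv1$report$top5_hits >= cv1$report$top1_hits))
  expect_true(all(cv1$report$top1_pct >= 0 & cv1$report$top1_pct <= 100,
                  na.rm = TRUE))
  g <- glance(cv1)
  expect_equal(g$n_folds, 4)
  expect_s3_class(tidy(cv1), "tbl_df")
})

test_that("the imbalance sweep reruns the protocol per ratio", {
  feats <- tiny_features()
  params <- forest_params(n_trees = 5, seed = 2)
  sw <- imbalance_sweep(feats, ratios = c(4, 1), params = params,
                        n_folds = 4, seed = 5)
  expect_equal(nrow(sw), 2 * 3)
  expect_setequal(unique(sw$ratio), c(4, 1))
  expect_true(all(sw$top1_hits <= sw$eligible))
  sw2 <- imbalance_sweep(feats, ratios = c(4, 1), params = params,
                         n_folds = 4, seed = 5)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_error(imbalance_sweep(feats, numeric()), "non-empty")
})

test_that("the feature-count sweep truncates the canonical feature order", {
  feats <- tiny_features()
  p <- length(foldrec:::feature_cols(feats))
  params <- forest_params(n_trees = 5, seed = 2)
  sw <- feature_count_sweep(feats, counts = c(1, 5, p), params = params,
                            n_folds = 4, seed = 5)
  expect_equal(nrow(sw), 3 * 3)
  expect_setequal(unique(sw$n_features), c(1L, 5L, as.integer(p)))
  expect_error(feature_count_sweep(feats, counts = p + 1), "must lie in")
  # the full count reproduces the unrestricted run
  full <- run_cross_validation(feats, params = params,
                               plan = make_cv_plan(feats, 4, seed = 5))
  expect_equal(dplyr::filter(sw, n_features == p)$top1_pct, full$report$top1_pct)
})

test_that("sweep plots build without error", {
  feats <- tiny_features()
  sw <- imbalance_sweep(feats, ratios = c(2, 1),
                        params = forest_params(n_trees = 3, seed = 1),
                        n_folds = 4, seed = 5)
  plt <- ggplot2::autoplot(sw)
  expect_s3_class(plt, "ggplot")
})
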