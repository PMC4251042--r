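# the benchmarking protocol: grouped cross-validation with template-leakage
# removal, negative subsampling, per-target template ranking, Lindahl
# top-1/top-5 sensitivity, pooled pair error rate, and the two sweeps
# (training imbalance ratio, feature count)

SENSITIVITY_LEVELS <- c("family", "superfamily", "fold")

#' Grouped cross-validation plan
#'
#' Targets are shuffled by `seed` and dealt round-robin into `n_folds`
#' folds, so fold sizes (in targets) differ by at most one. All pairs that
#' share a target belong to the same fold by construction.
#'
#' @param x A protein table, a feature/pair table (its `target_id` column is
#'   used), or a character vector of target ids.
#' @param n_folds Number of folds (default 10).
#' @param seed Shuffle seed.
#' @return An `fr_cv_plan`: tibble with `target_id` and `fold`.
#' @export
make_cv_plan <- function(x, n_folds = 10, seed = 1) {
  ids <- if (is.character(x)) {
    unique(x)
  } else if (is.data.frame(x) && "id" %in% names(x)) {
    unique(x$id)
  } else if (is.data.frame(x) && "target_id" %in% names(x)) {
    unique(x$target_id)
  } else {
    abort("cannot extract target ids from x")
  }
  ids <- sort(ids)
  if (length(ids) < n_folds) {
    abort(sprintf("need at least %d targets for %d folds", n_folds, n_folds))
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  plan <- tibble::tibble(
    target_id = shuffled,
    fold = rep_len(seq_len(n_folds), length(shuffled))
  ) |>
    dplyr::arrange(.data$target_id)
  attr(plan, "n_folds") <- as.integer(n_folds)
  attr(plan, "seed") <- seed
  class(plan) <- c("fr_cv_plan", class(plan))
  plan
}

plan_targets <- function(plan, fold) plan$target_id[plan$fold == fold]

#' Training pairs for one held-out fold
#'
#' Drops every pair whose target is in the test fold, and additionally every
#' pair that uses a test-fold target as its template, so no information
#' about test targets leaks into training.
#'
#' @param pairs A pair or feature table.
#' @param plan An `fr_cv_plan`.
#' @param test_fold Fold index being held out.
#' @return The filtered training table (errors when empty).
#' @export
training_pairs_for_fold <- function(pairs, plan, test_fold) {
  n_folds <- attr(plan, "n_folds")
  if (!test_fold %in% seq_len(n_folds)) {
    abort(sprintf("unknown fold index %s (plan has %d folds)", test_fold, n_folds))
  }
  held_out <- plan_targets(plan, test_fold)
  out <- dplyr::filter(pairs, !.data$target_id %in% held_out,
                       !.data$template_id %in% held_out)
  if (nrow(out) == 0) abort("empty training set after leakage removal")
  out
}

#' Subsample training negatives to a fixed imbalance ratio
#'
#' Keeps every positive pair and a uniform random subset of
#' `floor(ratio * n_positives)` negatives (capped at the available count).
#' Apply to training pairs only -- never to a test fold.
#'
#' @param pairs Training pair/feature table with a `positive` column.
#' @param ratio Negatives kept per positive (> 0).
#' @param seed Sampling seed.
#' @return The subsampled table, original row order preserved.
#' @export
subsample_negatives <- function(pairs, ratio, seed = 1) {
  if (!is.numeric(ratio) || ratio <= 0) abort("ratio must be positive")
  pos <- which(pairs$positive)
  neg <- which(!pairs$positive)
  if (length(pos) == 0) abort("no positive pairs in the training set")
  n_keep <- min(floor(ratio * length(pos)), length(neg))
  keep_neg <- withr::with_seed(seed, sample(neg, n_keep))
  dplyr::slice(pairs, sort(c(pos, keep_neg)))
}

#' Rank templates for each target by predicted probability
#'
#' Descending by `prob`; ties broken by lexicographic template id so the
#' ranking is deterministic.
#'
#' @param scores Tibble with `target_id`, `template_id`, `prob`.
#' @param target Optional single target id to restrict to.
#' @return Tibble with a `rank` column, grouped rows per target.
#' @export
rank_templates <- function(scores, target = NULL) {
  if (!is.null(target)) scores <- dplyr::filter(scores, .data$target_id == target)
  if (nrow(scores) == 0) abort("no scored templates to rank")
  scores |>
    dplyr::arrange(.data$target_id, dplyr::desc(.data$prob), .data$template_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .by = "target_id")
}

level_exclusions <- function(level) {
  switch(level,
    family = character(),
    superfamily = "family",
    fold = c("family", "superfamily"),
    abort(sprintf("unknown level '%s'", level))
  )
}

#' Top-k recognition sensitivity at one hierarchy level
#'
#' Lindahl-protocol scoring: a target is eligible at a level when it has at
#' least one template whose deepest shared level is exactly that level.
#' Before taking the top k, templates related at an easier (deeper) level
#' are removed from the target's ranking -- family relatives for the
#' superfamily evaluation, family and superfamily relatives for the fold
#' evaluation. A hit is any surviving top-k template related at the level.
#'
#' @param scores Tibble with `target_id`, `template_id`, `relationship`,
#'   `prob` covering each eligible target's templates.
#' @param level `"family"`, `"superfamily"` or `"fold"`.
#' @param k Ranking depth (1 and 5 are the conventional choices).
#' @return One-row tibble: `level`, `k`, `hits`, `eligible`,
#'   `sensitivity_pct`.
#' @export
topk_sensitivity <- function(scores, level, k) {
  if (!is.numeric(k) || k < 1) abort("k must be >= 1")
  excl <- level_exclusions(level)
  eligible <- unique(scores$target_id[scores$relationship == level])
  if (length(eligible) == 0) {
    abort(sprintf("no eligible targets at the %s level", level))
  }
  hits <- scores |>
    dplyr::filter(.data$target_id %in% eligible,
                  !.data$relationship %in% excl) |>
    dplyr::arrange(dplyr::desc(.data$prob), .data$template_id) |>
    dplyr::slice_head(n = k, by = "target_id") |>
    dplyr::summarise(hit = any(.data$relationship == level), .by = "target_id")
  n_hit <- sum(hits$hit)
  n_eligible <- length(eligible)
  tibble::tibble(
    level = level, k = as.integer(k), hits = n_hit,
    eligible = n_eligible,
    sensitivity_pct = 100 * n_hit / n_eligible
  )
}

#' Top-1/top-5 sensitivity report across all three levels
#'
#' @param scores As in [topk_sensitivity()].
#' @return Tibble with one row per level: eligible-target count, top-1 and
#'   top-5 hit counts and percentages. Levels with no eligible targets get
#'   zero counts and `NA` percentages.
#' @export
sensitivity_report <- function(scores) {
  purrr::map_dfr(SENSITIVITY_LEVELS, function(level) {
    n_eligible <- dplyr::n_distinct(scores$target_id[scores$relationship == level])
    if (n_eligible == 0) {
      return(tibble::tibble(level = level, eligible = 0L,
                            top1_hits = 0L, top1_pct = NA_real_,
                            top5_hits = 0L, top5_pct = NA_real_))
    }
    t1 <- topk_sensitivity(scores, level, 1)
    t5 <- topk_sensitivity(scores, level, 5)
    tibble::tibble(level = level, eligible = t1$eligible,
                   top1_hits = t1$hits, top1_pct = t1$sensitivity_pct,
                   top5_hits = t5$hits, top5_pct = t5$sensitivity_pct)
  })
}

#' Pooled pair misclassification rate
#'
#' @param predicted Predicted classes (0/1 or logical).
#' @param actual True classes.
#' @return Percentage of misclassified pairs.
#' @export
pair_error_rate <- function(predicted, actual) {
  if (length(predicted) == 0) abort("cannot compute an error rate on no pairs")
  if (length(predicted) != length(actual)) abort("prediction/label length mismatch")
  100 * mean(as.integer(predicted) != as.integer(actual))
}

#' Run the full grouped cross-validation protocol
#'
#' For every fold: assemble the leakage-free training set, optionally
#' subsample negatives to `ratio`, train a forest, and score every pair of
#' the held-out targets. Fold results are pooled (counts summed, rates from
#' pooled counts) into a sensitivity report and a pair error rate at the
#' 0.5 probability threshold.
#'
#' @param features Feature table from [featurize_pairs()].
#' @param params Forest parameters; fold f trains with seed
#'   `params$seed + f` so folds are independent but reproducible.
#' @param n_folds,seed Plan construction (ignored when `plan` is given).
#' @param ratio Training negatives per positive; `NULL` keeps the natural
#'   distribution.
#' @param plan Optional pre-built `fr_cv_plan` (shared across sweep runs).
#' @return An `fr_cv`: `scores` (per-pair test predictions), `report`,
#'   `error_rate`, `plan`, `params`, `ratio`.
#' @export
run_cross_validation <- function(features, params = forest_params(),
                                 n_folds = 10, ratio = NULL, seed = 1,
                                 plan = NULL) {
  if (is.null(plan)) plan <- make_cv_plan(features, n_folds = n_folds, seed = seed)
  n_folds <- attr(plan, "n_folds")
  scores <- purrr::map_dfr(seq_len(n_folds), function(f) {
    train <- training_pairs_for_fold(features, plan, f)
    if (!is.null(ratio)) {
      train <- subsample_negatives(train, ratio, seed = seed + 104729 + f)
    }
    fold_params <- params
    fold_params$seed <- params$seed + f
    forest <- train_forest(train, params = fold_params)
    test <- dplyr::filter(features, .data$target_id %in% plan_targets(plan, f))
    dplyr::tibble(
      target_id = test$target_id,
      template_id = test$template_id,
      relationship = test$relationship,
      positive = test$positive,
      prob = predict(forest, test),
      fold = f
    )
  })
  structure(
    list(
      scores = scores,
      report = sensitivity_report(scores),
      error_rate = pair_error_rate(as.integer(scores$prob > 0.5), scores$positive),
      plan = plan, params = params, ratio = ratio
    ),
    class = "fr_cv"
  )
}

#' @export
print.fr_cv <- function(x, ...) {
  cat(sprintf("Grouped %d-fold cross-validation (%d trees%s)\n",
              attr(x$plan, "n_folds"), x$params$n_trees,
              if (is.null(x$ratio)) "" else sprintf(", %g:1 training ratio", x$ratio)))
  cat(sprintf("Pooled pair error rate: %.3f%%\n\n", x$error_rate))
  r <- x$report
  cat(sprintf("%-12s %9s %6s %7s %6s %7s\n",
              "Level", "Eligible", "Top1", "Top1%", "Top5", "Top5%"))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("%-12s %9d %6d %7.1f %6d %7.1f\n",
                r$level[i], r$eligible[i], r$top1_hits[i], r$top1_pct[i],
                r$top5_hits[i], r$top5_pct[i]))
  }
  invisible(x)
}

#' @method tidy fr_cv
#' @export
tidy.fr_cv <- function(x, ...) x$report

#' @method glance fr_cv
#' @export
glance.fr_cv <- function(x, ...) {
  tibble::tibble(
    error_rate_pct = x$error_rate,
    n_folds = attr(x$plan, "n_folds"),
    n_pairs = nrow(x$scores),
    n_targets = dplyr::n_distinct(x$scores$target_id),
    ratio = x$ratio %||% NA_real_,
    n_trees = x$params$n_trees
  )
}

sweep_result <- function(rows, var) {
  out <- dplyr::bind_rows(rows)
  attr(out, "sweep_var") <- var
  class(out) <- c("fr_sweep", class(out))
  out
}

#' Sensitivity under different training imbalance ratios
#'
#' Re-runs the cross-validation once per requested negatives:positives
#' training ratio, with one shared CV plan so only the training-set
#' composition varies. Mirrors the conventional ratio grid
#' 128:1, 100:1, 75:1, 50:1, 25:1 (plus 1:1) used to probe robustness to
#' class imbalance.
#'
#' @param features Feature table.
#' @param ratios Numeric vector of ratios (non-empty).
#' @param params,n_folds,seed,plan As in [run_cross_validation()].
#' @return An `fr_sweep` tibble: one row per ratio x level with top-1/top-5
#'   counts and percentages and the pooled error rate.
#' @export
imbalance_sweep <- function(features, ratios, params = forest_params(),
                            n_folds = 10, seed = 1, plan = NULL) {
  if (length(ratios) == 0) abort("ratios must be non-empty")
  if (is.null(plan)) plan <- make_cv_plan(features, n_folds = n_folds, seed = seed)
  rows <- purrr::map(ratios, function(r) {
    cv <- run_cross_validation(features, params = params, ratio = r,
                               seed = seed, plan = plan)
    dplyr::mutate(cv$report, ratio = r, error_rate_pct = cv$error_rate,
                  .before = 1)
  })
  sweep_result(rows, "ratio")
}

#' Sensitivity against the number of features
#'
#' Restricts the feature table to the first m features in the canonical
#' [feature_names()] order and re-runs the cross-validation for each m.
#'
#' @param features Feature table.
#' @param counts Feature counts to evaluate (each within 1..p).
#' @param params,n_folds,seed,plan As in [run_cross_validation()].
#' @return An `fr_sweep` tibble keyed by `n_features`.
#' @export
feature_count_sweep <- function(features, counts, params = forest_params(),
                                n_folds = 10, seed = 1, plan = NULL) {
  if (length(counts) == 0) abort("counts must be non-empty")
  fcols <- feature_cols(features)
  if (any(counts < 1 | counts > length(fcols))) {
    abort(sprintf("feature counts must lie in [1, %d]", length(fcols)))
  }
  if (is.null(plan)) plan <- make_cv_plan(features, n_folds = n_folds, seed = seed)
  meta <- intersect(names(features), FEATURE_META_COLS)
  rows <- purrr::map(counts, function(m) {
    sub <- features[, c(meta, fcols[seq_len(m)]), drop = FALSE]
    cv <- run_cross_validation(sub, params = params, seed = seed, plan = plan)
    dplyr::mutate(cv$report, n_features = as.integer(m),
                  error_rate_pct = cv$error_rate, .before = 1)
  })
  sweep_result(rows, "n_features")
}

#' Plot a sweep result
#'
#' Line plot of top-1 and top-5 sensitivity per hierarchy level against the
#' swept quantity (training ratio or feature count).
#'
#' @param object An `fr_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fr_sweep
#' @export
autoplot.fr_sweep <- function(object, ...) {
  var <- attr(object, "sweep_var")
  long <- object |>
    tidyr::pivot_longer(cols = c("top1_pct", "top5_pct"),
                        names_to = "top_k", values_to = "sensitivity_pct") |>
    dplyr::mutate(top_k = ifelse(.data$top_k == "top1_pct", "top 1", "top 5"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data[[var]], y = .data$sensitivity_pct,
                               colour = .data$level, linetype = .data$top_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = var, y = "sensitivity (%)",
                  colour = "level", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
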