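# R surface of the from-scratch random forest: split criterion, parameter
# object, training/prediction wrappers around the compiled grower, broom
# methods and exact text serialization

#' Shannon entropy of class counts, in bits
#'
#' @param class_counts Nonnegative counts per class, at least one positive.
#' @return \eqn{-\sum_i p_i \log_2 p_i} over the nonzero class fractions;
#'   in \eqn{[0, 1]} for two classes.
#' @export
#' @examples
#' entropy_bits(c(1, 3))  # 0.8112781
entropy_bits <- function(class_counts) {
  if (!is.numeric(class_counts) || any(class_counts < 0)) {
    abort("class counts must be nonnegative numbers")
  }
  n <- sum(class_counts)
  if (n == 0) abort("entropy of all-zero counts is undefined")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain of a candidate split, in bits
#'
#' Entropy of the parent minus the size-weighted mean entropy of the two
#' children; the quantity a tree split maximises.
#'
#' @param parent_counts,left_counts,right_counts Class-count vectors;
#'   left + right must equal parent elementwise.
#' @return Nonnegative gain in bits.
#' @export
#' @examples
#' information_gain(c(3, 1), c(2, 0), c(1, 1))  # 0.3112781
information_gain <- function(parent_counts, left_counts, right_counts) {
  if (length(left_counts) != length(parent_counts) ||
      length(right_counts) != length(parent_counts) ||
      any(left_counts + right_counts != parent_counts)) {
    abort("left and right counts must sum to the parent counts")
  }
  n <- sum(parent_counts)
  nl <- sum(left_counts)
  nr <- sum(right_counts)
  h_children <- 0
  if (nl > 0) h_children <- h_children + nl / n * entropy_bits(left_counts)
  if (nr > 0) h_children <- h_children + nr / n * entropy_bits(right_counts)
  entropy_bits(parent_counts) - h_children
}

#' Random-forest training parameters
#'
#' @param n_trees Number of trees (default 500).
#' @param feature_sampling `"per_split"` draws a fresh random feature subset
#'   at every node (the classical forest); `"per_tree"` fixes one random
#'   subspace per tree and considers all of it at every node.
#' @param n_features_sampled Size of the random feature subset; default
#'   `NULL` resolves to `ceiling(sqrt(p))` at training time; `"all"` uses
#'   every feature.
#' @param bootstrap Draw a bootstrap sample of size n per tree.
#' @param min_leaf Minimum training samples in a leaf.
#' @param max_depth Maximum tree depth, `Inf` for unlimited.
#' @param seed Master seed; tree t derives an independent random stream from
#'   (seed, t), so training is reproducible and order-independent.
#' @return An `fr_forest_params`.
#' @export
forest_params <- function(n_trees = 500,
                          feature_sampling = c("per_split", "per_tree"),
                          n_features_sampled = NULL,
                          bootstrap = TRUE, min_leaf = 1, max_depth = Inf,
                          seed = 1) {
  feature_sampling <- match.arg(feature_sampling)
  if (!is.numeric(n_trees) || n_trees < 1) abort("n_trees must be a positive integer")
  if (!is.numeric(min_leaf) || min_leaf < 1) abort("min_leaf must be >= 1")
  if (!(identical(n_features_sampled, "all") || is.null(n_features_sampled) ||
        (is.numeric(n_features_sampled) && n_features_sampled >= 1))) {
    abort("n_features_sampled must be NULL, a positive integer, or \"all\"")
  }
  structure(
    list(n_trees = as.integer(n_trees), feature_sampling = feature_sampling,
         n_features_sampled = n_features_sampled,
         bootstrap = isTRUE(bootstrap), min_leaf = as.integer(min_leaf),
         max_depth = max_depth, seed = seed),
    class = "fr_forest_params"
  )
}

#' Parameters for the single-decision-tree baseline
#'
#' One unbagged tree with access to every feature at every split: the
#' classical CART-style baseline a forest is compared against.
#'
#' @param seed Seed (only relevant if subsampling is re-enabled).
#' @param ... Overrides passed to [forest_params()].
#' @return An `fr_forest_params`.
#' @export
single_tree_params <- function(seed = 1, ...) {
  forest_params(n_trees = 1, bootstrap = FALSE, n_features_sampled = "all",
                seed = seed, ...)
}

# split a feature table (or matrix + labels) into the pieces training needs
as_training_data <- function(x, y = NULL) {
  if (is.null(y)) {
    if (!is.data.frame(x) || !("positive" %in% names(x))) {
      abort("supply labels via y= or a feature table with a 'positive' column")
    }
    y <- as.integer(x$positive)
    x <- x[, feature_cols(x), drop = FALSE]
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) abort("features must be numeric")
  storage.mode(x) <- "double"
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(x)) abort("labels and feature rows differ in length")
  if (!all(y %in% c(0L, 1L))) abort("labels must be binary (0/1)")
  list(X = x, y = y,
       feature_names = colnames(x) %||% paste0("x", seq_len(ncol(x))))
}

resolve_mtry <- function(n_features_sampled, p) {
  m <- if (is.null(n_features_sampled)) {
    ceiling(sqrt(p))
  } else if (identical(n_features_sampled, "all") || is.infinite(n_features_sampled)) {
    p
  } else {
    as.integer(n_features_sampled)
  }
  if (m < 1 || m > p) {
    abort(sprintf("n_features_sampled must lie in [1, %d]", p))
  }
  as.integer(m)
}

#' Train a random forest of information-gain decision trees
#'
#' Each tree is grown on a bootstrap sample (when `bootstrap = TRUE`) by
#' greedy recursive partitioning: candidate thresholds are midpoints between
#' consecutive distinct sorted feature values, the split maximising
#' information gain is taken (ties broken toward the lowest feature index,
#' then the lowest threshold), and growth stops at pure nodes, `min_leaf`,
#' `max_depth`, or when no split has positive gain. Leaves store raw class
#' fractions, and the forest's class probability is the arithmetic mean of
#' the per-tree probabilities.
#'
#' @param x A feature table (output of [featurize_pairs()], labels taken
#'   from its `positive` column) or a numeric matrix/data frame of features.
#' @param y Binary labels (0/1 or logical) when `x` is a plain matrix.
#' @param params An [forest_params()] object.
#' @return An `rf_forest`.
#' @export
train_forest <- function(x, y = NULL, params = forest_params()) {
  td <- as_training_data(x, y)
  if (nrow(td$X) < 1) abort("cannot train on zero samples")
  if (length(unique(td$y)) < 2) {
    warn("training labels contain a single class; every prediction will be constant")
  }
  p <- ncol(td$X)
  mtry <- resolve_mtry(params$n_features_sampled, p)
  max_depth <- if (is.infinite(params$max_depth)) -1L else as.integer(params$max_depth)
  trees <- train_forest_cpp(td$X, td$y, params$n_trees, mtry, params$min_leaf,
                            max_depth, params$feature_sampling == "per_split",
                            params$bootstrap, as.numeric(params$seed))
  structure(
    list(trees = trees, params = params, mtry = mtry,
         feature_names = td$feature_names, n_samples = nrow(td$X)),
    class = "rf_forest"
  )
}

#' Train a single decision tree
#'
#' The same grower as [train_forest()] restricted to one tree; by default an
#' unbagged tree with all features available at every split.
#'
#' @inheritParams train_forest
#' @param params Defaults to [single_tree_params()].
#' @return An `rf_tree`.
#' @export
train_tree <- function(x, y = NULL, params = single_tree_params()) {
  td <- as_training_data(x, y)
  if (nrow(td$X) < 1) abort("cannot train on zero samples")
  p <- ncol(td$X)
  mtry <- resolve_mtry(params$n_features_sampled, p)
  max_depth <- if (is.infinite(params$max_depth)) -1L else as.integer(params$max_depth)
  tree <- train_tree_cpp(td$X, td$y, mtry, params$min_leaf, max_depth,
                         params$feature_sampling == "per_split",
                         params$bootstrap, as.numeric(params$seed))
  structure(
    list(tree = tree, params = params, mtry = mtry,
         feature_names = td$feature_names, n_samples = nrow(td$X)),
    class = "rf_tree"
  )
}

# newdata -> feature matrix in the model's training column order
model_matrix_for <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing) > 0) {
      abort(paste0("newdata lacks feature column(s): ",
                   paste(missing, collapse = ", ")))
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    if (ncol(newdata) != length(object$feature_names)) {
      abort(sprintf("feature dimension mismatch: model has %d, input has %d",
                    length(object$feature_names), ncol(newdata)))
    }
    if (!is.null(colnames(newdata)) &&
        !identical(colnames(newdata), object$feature_names)) {
      abort(paste0("feature-name mismatch; model expects: ",
                   paste(object$feature_names, collapse = ", ")))
    }
  }
  storage.mode(newdata) <- "double"
  newdata
}

#' Predict with a random forest
#'
#' `type = "prob"` returns \eqn{P(c = 1 | v)}, the mean of the per-tree
#' class-1 probabilities; `type = "class"` thresholds at 0.5 with the tie
#' (exactly 0.5) going to class 0, the majority class of an imbalanced
#' fold-recognition dataset.
#'
#' @param object An `rf_forest`.
#' @param newdata Feature table, matrix, or a single feature vector.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return Numeric probabilities or integer classes, one per row.
#' @export
predict.rf_forest <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (length(object$trees) == 0) abort("empty forest")
  p1 <- predict_forest_cpp(object$trees, model_matrix_for(object, newdata))
  if (type == "prob") p1 else as.integer(p1 > 0.5)
}

#' @rdname predict.rf_forest
#' @export
predict.rf_tree <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p1 <- predict_tree_cpp(object$tree, model_matrix_for(object, newdata))
  if (type == "prob") p1 else as.integer(p1 > 0.5)
}

#' @export
print.rf_forest <- function(x, ...) {
  cat(sprintf("<random forest> %d trees, %d features (mtry %d, %s), %s\n",
              length(x$trees), length(x$feature_names), x$mtry,
              x$params$feature_sampling,
              if (x$params$bootstrap) "bootstrapped" else "unbagged"))
  invisible(x)
}

tree_depths <- function(tree) {
  n <- length(tree$feature)
  depth <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(tree$left[i])) {
      depth[tree$left[i]] <- depth[i] + 1L
      depth[tree$right[i]] <- depth[i] + 1L
    }
  }
  depth
}

#' Per-tree summary of a forest
#'
#' @param x An `rf_forest`.
#' @param ... Unused.
#' @return Tibble with one row per tree: node/leaf counts and depth.
#' @method tidy rf_forest
#' @export
tidy.rf_forest <- function(x, ...) {
  purrr::map_dfr(seq_along(x$trees), function(t) {
    tr <- x$trees[[t]]
    tibble::tibble(
      tree = t,
      n_nodes = length(tr$feature),
      n_leaves = sum(is.na(tr$feature)),
      depth = max(tree_depths(tr))
    )
  })
}

#' One-row summary of a forest
#'
#' @param x An `rf_forest`.
#' @param ... Unused.
#' @return One-row tibble of the resolved training parameters.
#' @method glance rf_forest
#' @export
glance.rf_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees),
    n_features = length(x$feature_names),
    n_features_sampled = x$mtry,
    feature_sampling = x$params$feature_sampling,
    bootstrap = x$params$bootstrap,
    min_leaf = x$params$min_leaf,
    max_depth = x$params$max_depth,
    seed = x$params$seed,
    n_samples = x$n_samples
  )
}

# ---- serialization -------------------------------------------------------
# JSON with doubles encoded as "%.17g" strings so save -> load -> predict is
# bit-exact

serialize_tree <- function(tree) {
  list(
    feature = ifelse(is.na(tree$feature), -1L, tree$feature),
    threshold = num_to_text(tree$threshold),
    left = ifelse(is.na(tree$left), -1L, tree$left),
    right = ifelse(is.na(tree$right), -1L, tree$right),
    p1 = num_to_text(tree$p1),
    n = tree$n
  )
}

deserialize_tree <- function(x) {
  to_na <- function(v) { v <- as.integer(v); v[v < 0] <- NA_integer_; v }
  list(
    feature = to_na(x$feature),
    threshold = text_to_num(x$threshold),
    left = to_na(x$left),
    right = to_na(x$right),
    p1 = text_to_num(x$p1),
    n = as.integer(x$n)
  )
}

#' Save / load a trained forest
#'
#' Self-describing JSON holding the parameters, feature names and full tree
#' structures; numeric values are stored in an exact text encoding, so a
#' round trip reproduces predictions bit for bit.
#'
#' @param object An `rf_forest`.
#' @param path File path.
#' @return `rf_save` the path invisibly; `rf_load` the restored `rf_forest`.
#' @export
rf_save <- function(object, path) {
  if (!inherits(object, "rf_forest")) abort("object must be an rf_forest")
  payload <- list(
    format = "foldrec_forest",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("foldrec")),
    params = list(
      n_trees = object$params$n_trees,
      feature_sampling = object$params$feature_sampling,
      n_features_sampled = object$mtry,
      bootstrap = object$params$bootstrap,
      min_leaf = object$params$min_leaf,
      max_depth = if (is.infinite(object$params$max_depth)) -1L
                  else as.integer(object$params$max_depth),
      seed = object$params$seed
    ),
    feature_names = object$feature_names,
    n_samples = object$n_samples,
    trees = lapply(object$trees, serialize_tree)
  )
  write_atomic(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  })
}

#' @rdname rf_save
#' @export
rf_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "foldrec_forest")) {
    abort(sprintf("'%s' is not a serialized forest", path))
  }
  pr <- lapply(x$params, unlist)
  params <- forest_params(
    n_trees = pr$n_trees,
    feature_sampling = pr$feature_sampling,
    n_features_sampled = pr$n_features_sampled,
    bootstrap = pr$bootstrap,
    min_leaf = pr$min_leaf,
    max_depth = if (pr$max_depth < 0) Inf else pr$max_depth,
    seed = pr$seed
  )
  trees <- lapply(x$trees, function(tr) deserialize_tree(lapply(tr, unlist)))
  structure(
    list(trees = trees, params = params,
         mtry = as.integer(pr$n_features_sampled),
         feature_names = unlist(x$feature_names),
         n_samples = unlist(x$n_samples)),
    class = "rf_forest"
  )
}
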