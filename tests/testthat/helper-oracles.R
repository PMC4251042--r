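# independent oracles and shared fixtures for the test suite

# Exhaustive alignment oracle: a monotone matching is fully determined by a
# choice of k rows and k cols (paired in sorted order); unmatched positions
# are scored as maximal index runs, each costing gap_open + len * gap_extend
# (internal runs only in local mode).  Independent of the DP implementation.
oracle_align_score <- function(S, gap_open, gap_extend, local = FALSE) {
  n <- nrow(S)
  m <- ncol(S)
  gap_cost <- function(len) if (len > 0) gap_open + len * gap_extend else 0
  run_cost <- function(bounds) {
    # bounds: sorted matched indices padded with 0 and (len + 1)
    sum(vapply(seq_len(length(bounds) - 1L),
               function(k) gap_cost(bounds[k + 1L] - bounds[k] - 1L), 0))
  }
  best <- if (local) 0 else gap_cost(n) + gap_cost(m)  # empty matching
  for (k in seq_len(min(n, m))) {
    rows <- utils::combn(n, k)
    cols <- utils::combn(m, k)
    for (ri in seq_len(ncol(rows))) {
      for (ci in seq_len(ncol(cols))) {
        ia <- rows[, ri]
        ib <- cols[, ci]
        s <- sum(S[cbind(ia, ib)])
        if (local) {
          # only runs between consecutive matches are penalised
          s <- s + run_cost(ia) + run_cost(ib)
        } else {
          s <- s + run_cost(c(0L, ia, n + 1L)) + run_cost(c(0L, ib, m + 1L))
        }
        if (s > best) best <- s
      }
    }
  }
  best
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# small substitution matrix over a 4-letter test alphabet
toy_submat <- function(match = 2, mismatch = -1, alphabet = c("A", "C", "G", "T")) {
  k <- length(alphabet)
  m <- matrix(mismatch, k, k, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

random_aa_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# hand-built forest whose trees are single leaves with fixed class-1
# probabilities; used to pin down the probability-averaging semantics
leaf_forest <- function(p1s, feature_names = "x1") {
  trees <- lapply(p1s, function(p) {
    list(feature = NA_integer_, threshold = 0, left = NA_integer_,
         right = NA_integer_, p1 = p, n = 1L)
  })
  structure(list(trees = trees,
                 params = forest_params(n_trees = length(p1s)),
                 mtry = 1L, feature_names = feature_names, n_samples = 1L),
            class = "rf_forest")
}

# tiny benchmark shared across test files (generated once per session):
# 3 folds x 2 superfamilies x 2 families x 2 proteins = 24 proteins
.fixture_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 404) {
  synth_config(n_struct_folds = 3, superfamilies_per_fold = 2,
               families_per_superfamily = 2, proteins_per_family = 2,
               seq_length = 40, msa_depth = 3, seed = seed)
}

tiny_proteins <- function() {
  if (is.null(.fixture_cache$tiny_proteins)) {
    .fixture_cache$tiny_proteins <- generate_benchmark(tiny_config())
  }
  .fixture_cache$tiny_proteins
}

tiny_features <- function() {
  if (is.null(.fixture_cache$tiny_features)) {
    .fixture_cache$tiny_features <- featurize_pairs(tiny_proteins())
  }
  .fixture_cache$tiny_features
}

# four hand-labelled proteins (one family pair, one superfamily relative,
# one unrelated fold) for bookkeeping tests
four_proteins <- function() {
  protein_tbl(
    id = c("p1", "p2", "p3", "p4"),
    sequence = c("MKTAYIAKQR", "MKTAYLAKQR", "MAGWNSRRSV", "QQQLLLPPPA"),
    family_id = c("a1", "a1", "a2", "b1"),
    superfamily_id = c("s1", "s1", "s1", "s2"),
    fold_id = c("f1", "f1", "f1", "f2")
  )
}
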