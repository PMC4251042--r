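# data model for a fold-recognition benchmark: proteins carrying
# family/superfamily/fold labels, ordered (target, template) pairs, and the
# deepest-shared-level relationship labelling

RELATIONSHIP_LEVELS <- c("family", "superfamily", "fold", "none")

#' Assemble and validate a protein table
#'
#' The central container of the package: one row per protein with its
#' sequence, its position in the three-level structural hierarchy
#' (family nested in superfamily nested in fold, as in SCOP), and optional
#' per-protein assets as list-columns: `msa` (character vector of aligned
#' sequences, first row the protein's own sequence) and `struct` (named
#' character vector of per-residue structural-state strings, e.g. 3-state
#' secondary structure `H`/`E`/`C` and 2-state accessibility `e`/`b`).
#'
#' @param id,sequence,family_id,superfamily_id,fold_id Character vectors of
#'   equal length.
#' @param msa Optional list of character vectors (or NULL entries).
#' @param struct Optional list of named character vectors (or NULL entries).
#' @return A validated tibble of class used throughout the package.
#' @export
protein_tbl <- function(id, sequence, family_id, superfamily_id, fold_id,
                        msa = NULL, struct = NULL) {
  n <- length(id)
  tbl <- tibble::tibble(
    id = as.character(id),
    sequence = as.character(sequence),
    family_id = as.character(family_id),
    superfamily_id = as.character(superfamily_id),
    fold_id = as.character(fold_id),
    msa = if (is.null(msa)) vector("list", n) else msa,
    struct = if (is.null(struct)) vector("list", n) else struct
  )
  validate_proteins(tbl)
}

#' Validate a protein table
#'
#' Checks the invariants the rest of the pipeline relies on: unique ids,
#' non-empty sequences, hierarchy consistency (all proteins of a family
#' share one superfamily and one fold; all proteins of a superfamily share
#' one fold), MSA first-row agreement and structural-track lengths.
#'
#' @param proteins A protein table.
#' @return The table, invisibly unchanged, or an error.
#' @export
validate_proteins <- function(proteins) {
  required <- c("id", "sequence", "family_id", "superfamily_id", "fold_id")
  missing <- setdiff(required, names(proteins))
  if (length(missing) > 0) {
    abort(paste0("protein table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- proteins$id[duplicated(proteins$id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate protein id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(proteins$sequence)) || any(nchar(proteins$sequence) == 0)) {
    abort("every protein needs a non-empty sequence")
  }
  lab <- proteins[, c("family_id", "superfamily_id", "fold_id")]
  if (anyNA(lab)) abort("hierarchy labels must not be missing")
  bad_fam <- proteins |>
    dplyr::summarise(
      k = dplyr::n_distinct(paste(.data$superfamily_id, .data$fold_id)),
      .by = "family_id"
    ) |>
    dplyr::filter(.data$k > 1)
  if (nrow(bad_fam) > 0) {
    abort(sprintf("family '%s' maps to more than one superfamily/fold",
                  bad_fam$family_id[[1]]))
  }
  bad_sf <- proteins |>
    dplyr::summarise(k = dplyr::n_distinct(.data$fold_id), .by = "superfamily_id") |>
    dplyr::filter(.data$k > 1)
  if (nrow(bad_sf) > 0) {
    abort(sprintf("superfamily '%s' maps to more than one fold", bad_sf$superfamily_id[[1]]))
  }
  if ("struct" %in% names(proteins)) {
    for (i in seq_len(nrow(proteins))) {
      st <- proteins$struct[[i]]
      if (!is.null(st) && any(nchar(st) != nchar(proteins$sequence[[i]]))) {
        abort(sprintf("structural track length mismatch for protein '%s'",
                      proteins$id[[i]]))
      }
    }
  }
  invisible(proteins)
}

#' Deepest shared hierarchy level of a protein pair
#'
#' Returns `"family"` when the two proteins share a family, `"superfamily"`
#' when they share a superfamily but not a family, `"fold"` when they share
#' only the fold, and `"none"` otherwise. Symmetric in its arguments.
#'
#' @param target,template Single-row protein records (one-row tibbles, data
#'   frames or named lists with the three hierarchy label fields).
#' @return One of `"family"`, `"superfamily"`, `"fold"`, `"none"`.
#' @export
label_relationship <- function(target, template) {
  grab <- function(x, f) {
    v <- if (is.data.frame(x)) x[[f]][[1]] else x[[f]]
    if (is.null(v) || is.na(v)) abort(sprintf("missing hierarchy label '%s'", f))
    as.character(v)
  }
  if (grab(target, "family_id") == grab(template, "family_id")) return("family")
  if (grab(target, "superfamily_id") == grab(template, "superfamily_id")) return("superfamily")
  if (grab(target, "fold_id") == grab(template, "fold_id")) return("fold")
  "none"
}

#' Enumerate all ordered (target, template) pairs
#'
#' Every ordered pair of distinct proteins, labelled with the deepest shared
#' hierarchy level; n proteins yield n(n-1) pairs. A pair is positive when
#' the proteins share at least the fold.
#'
#' @param proteins A validated protein table.
#' @return Tibble with columns `target_id`, `template_id`, `relationship`
#'   (factor-ordered character) and `positive` (logical).
#' @export
#' @examples
#' p <- protein_tbl(c("a", "b", "c"), c("MK", "MR", "ML"),
#'                  c("f1", "f1", "f2"), c("s1", "s1", "s2"),
#'                  c("x1", "x1", "x2"))
#' enumerate_pairs(p)
enumerate_pairs <- function(proteins) {
  validate_proteins(proteins)
  if (nrow(proteins) < 2) abort("pair enumeration needs at least 2 proteins")
  ids <- proteins$id
  fam <- proteins$family_id[match(ids, proteins$id)]
  sf <- proteins$superfamily_id[match(ids, proteins$id)]
  fo <- proteins$fold_id[match(ids, proteins$id)]
  n <- length(ids)
  ti <- rep(seq_len(n), each = n)
  pi <- rep(seq_len(n), times = n)
  keep <- ti != pi
  ti <- ti[keep]
  pi <- pi[keep]
  relationship <- dplyr::case_when(
    fam[ti] == fam[pi] ~ "family",
    sf[ti] == sf[pi] ~ "superfamily",
    fo[ti] == fo[pi] ~ "fold",
    TRUE ~ "none"
  )
  tibble::tibble(
    target_id = ids[ti],
    template_id = ids[pi],
    relationship = relationship,
    positive = relationship != "none"
  )
}

#' Summarise a fold-recognition benchmark
#'
#' Counts of positive/negative pairs, the negative:positive imbalance ratio
#' (infinite when there are no positives), and per-level target counts under
#' the Lindahl convention: a protein is counted as a target at level L when
#' it has at least one other protein whose deepest shared level with it is
#' exactly L, so a protein may be counted at several levels.
#'
#' @param proteins A protein table.
#' @param pairs Optional pre-enumerated pair table (saves recomputation).
#' @return One-row tibble.
#' @export
dataset_summary <- function(proteins, pairs = NULL) {
  if (is.null(pairs)) pairs <- enumerate_pairs(proteins)
  n_pos <- sum(pairs$positive)
  n_neg <- sum(!pairs$positive)
  per_level <- function(level) {
    dplyr::n_distinct(pairs$target_id[pairs$relationship == level])
  }
  tibble::tibble(
    n_proteins = nrow(proteins),
    n_pairs = nrow(pairs),
    n_positive = n_pos,
    n_negative = n_neg,
    imbalance_ratio = if (n_pos == 0) Inf else n_neg / n_pos,
    targets_family = per_level("family"),
    targets_superfamily = per_level("superfamily"),
    targets_fold = per_level("fold")
  )
}
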