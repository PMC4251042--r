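# the pairwise feature vector: five categories of similarity features for an
# ordered (target, template) pair, with indicator-style imputation for
# missing optional inputs (MSAs, structural tracks)

#' Feature-extraction configuration
#'
#' Selects which of the five feature categories are computed and fixes the
#' numerical knobs. The categories are: amino-acid composition kernels
#' (monomer and dimer compositions compared by cosine, correlation and
#' Gaussian kernels), sequence-sequence alignment scores, sequence-profile
#' alignment scores (both directions), profile-profile alignment scores, and
#' structural-state compatibility per track. Categories whose inputs are
#' missing for a pair are imputed to 0 and flagged by a companion binary
#' `*_imputed` feature.
#'
#' @param categories Character subset of
#'   `c("composition", "seq_seq", "seq_profile", "profile_profile",
#'   "structural")`.
#' @param tracks Structural track names scored when `"structural"` is
#'   enabled.
#' @param submat Substitution matrix for sequence-sequence alignment
#'   (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties shared by all alignments.
#' @param pseudocount Profile pseudocount per residue.
#' @param gamma_monomer,gamma_dimer Gaussian kernel bandwidths (defaults
#'   1/20 and 1/400, i.e. one over the vector length).
#' @return An `fr_feature_config`.
#' @export
feature_config <- function(categories = c("composition", "seq_seq",
                                          "seq_profile", "profile_profile",
                                          "structural"),
                           tracks = c("ss", "acc"),
                           submat = NULL,
                           gap_open = -11, gap_extend = -1,
                           pseudocount = 0.01,
                           gamma_monomer = 1 / 20,
                           gamma_dimer = 1 / 400) {
  all_cats <- c("composition", "seq_seq", "seq_profile", "profile_profile",
                "structural")
  bad <- setdiff(categories, all_cats)
  if (length(bad) > 0) {
    abort(sprintf("unknown feature categor%s: %s",
                  if (length(bad) > 1) "ies" else "y",
                  paste(bad, collapse = ", ")))
  }
  if (length(categories) == 0) abort("at least one feature category is required")
  structure(
    list(categories = intersect(all_cats, categories), tracks = tracks,
         submat = submat, gap_open = gap_open, gap_extend = gap_extend,
         pseudocount = pseudocount, gamma_monomer = gamma_monomer,
         gamma_dimer = gamma_dimer),
    class = "fr_feature_config"
  )
}

#' Canonical feature names for a configuration
#'
#' The fixed order of the feature vector; the feature-count sweep truncates
#' this order from the left.
#'
#' @param config An `fr_feature_config`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(config = feature_config()) {
  out <- character()
  if ("composition" %in% config$categories) {
    out <- c(out, "comp_mono_cosine", "comp_mono_correlation", "comp_mono_gaussian",
             "comp_di_cosine", "comp_di_correlation", "comp_di_gaussian")
  }
  if ("seq_seq" %in% config$categories) {
    out <- c(out, "aln_global", "aln_global_norm", "aln_local", "aln_local_norm")
  }
  if ("seq_profile" %in% config$categories) {
    out <- c(out, "sp_target_prof", "sp_target_prof_norm",
             "sp_template_prof", "sp_template_prof_norm", "sp_imputed")
  }
  if ("profile_profile" %in% config$categories) {
    out <- c(out, "pp_global", "pp_global_norm", "pp_local", "pp_local_norm",
             "pp_imputed")
  }
  if ("structural" %in% config$categories) {
    out <- c(out, paste0("struct_", config$tracks), "struct_imputed")
  }
  out
}

# per-protein reusable assets so dataset featurization is O(n) alignments of
# profiles/compositions, not O(n^2)
protein_assets <- function(protein, config) {
  seq <- if (is.data.frame(protein)) protein$sequence[[1]] else protein$sequence
  msa <- if (is.data.frame(protein)) protein$msa[[1]] else protein$msa
  struct <- if (is.data.frame(protein)) protein$struct[[1]] else protein$struct
  a <- list(sequence = seq)
  if ("composition" %in% config$categories) {
    a$mono <- monomer_composition(seq)
    a$di <- if (nchar(seq) >= 2) dimer_composition(seq) else NULL
  }
  if (any(c("seq_profile", "profile_profile") %in% config$categories)) {
    a$profile <- if (!is.null(msa) && length(msa) > 0) {
      build_profile(msa, pseudocount = config$pseudocount)
    }
  }
  if ("structural" %in% config$categories) {
    a$struct <- struct
  }
  a
}

# the actual per-pair computation over precomputed assets
featurize_from_assets <- function(at, ap, config) {
  nm <- feature_names(config)
  v <- stats::setNames(numeric(length(nm)), nm)

  if ("composition" %in% config$categories) {
    v["comp_mono_cosine"] <- cosine_similarity(at$mono, ap$mono)
    v["comp_mono_correlation"] <- correlation_similarity(at$mono, ap$mono)
    v["comp_mono_gaussian"] <- gaussian_similarity(at$mono, ap$mono,
                                                   gamma = config$gamma_monomer)
    if (!is.null(at$di) && !is.null(ap$di)) {
      v["comp_di_cosine"] <- cosine_similarity(at$di, ap$di)
      v["comp_di_correlation"] <- correlation_similarity(at$di, ap$di)
      v["comp_di_gaussian"] <- gaussian_similarity(at$di, ap$di,
                                                   gamma = config$gamma_dimer)
    }
  }

  aln_global <- NULL
  if ("seq_seq" %in% config$categories) {
    aln_global <- align_sequences(at$sequence, ap$sequence, mode = "global",
                                  submat = config$submat,
                                  gap_open = config$gap_open,
                                  gap_extend = config$gap_extend)
    aln_local <- align_sequences(at$sequence, ap$sequence, mode = "local",
                                 submat = config$submat,
                                 gap_open = config$gap_open,
                                 gap_extend = config$gap_extend)
    v["aln_global"] <- aln_global$score
    v["aln_global_norm"] <- aln_global$normalized_score
    v["aln_local"] <- aln_local$score
    v["aln_local_norm"] <- aln_local$normalized_score
  }

  if ("seq_profile" %in% config$categories) {
    imputed <- FALSE
    if (!is.null(at$profile)) {
      sp <- align_sequence_profile(at$profile, ap$sequence, mode = "global",
                                   gap_open = config$gap_open,
                                   gap_extend = config$gap_extend)
      v["sp_target_prof"] <- sp$score
      v["sp_target_prof_norm"] <- sp$normalized_score
    } else {
      imputed <- TRUE
    }
    if (!is.null(ap$profile)) {
      sp <- align_sequence_profile(ap$profile, at$sequence, mode = "global",
                                   gap_open = config$gap_open,
                                   gap_extend = config$gap_extend)
      v["sp_template_prof"] <- sp$score
      v["sp_template_prof_norm"] <- sp$normalized_score
    } else {
      imputed <- TRUE
    }
    v["sp_imputed"] <- as.numeric(imputed)
  }

  pp_global <- NULL
  if ("profile_profile" %in% config$categories) {
    if (!is.null(at$profile) && !is.null(ap$profile)) {
      pp_global <- align_profiles(at$profile, ap$profile, mode = "global",
                                  gap_open = config$gap_open,
                                  gap_extend = config$gap_extend)
      pp_local <- align_profiles(at$profile, ap$profile, mode = "local",
                                 gap_open = config$gap_open,
                                 gap_extend = config$gap_extend)
      v["pp_global"] <- pp_global$score
      v["pp_global_norm"] <- pp_global$normalized_score
      v["pp_local"] <- pp_local$score
      v["pp_local_norm"] <- pp_local$normalized_score
    } else {
      v["pp_imputed"] <- 1
    }
  }

  if ("structural" %in% config$categories) {
    # compatibility is read off the global profile-profile alignment; when
    # profiles are unavailable the sequence-sequence global alignment is the
    # fallback frame of reference
    ref <- pp_global
    if (is.null(ref)) {
      ref <- aln_global %||% align_sequences(at$sequence, ap$sequence,
                                             mode = "global",
                                             submat = config$submat,
                                             gap_open = config$gap_open,
                                             gap_extend = config$gap_extend)
    }
    imputed <- FALSE
    for (tr in config$tracks) {
      tt <- if (tr %in% names(at$struct)) at$struct[[tr]] else NULL
      tp <- if (tr %in% names(ap$struct)) ap$struct[[tr]] else NULL
      if (is.null(tt) || is.null(tp) || is.na(tt) || is.na(tp)) {
        imputed <- TRUE
      } else {
        v[paste0("struct_", tr)] <- structural_compatibility(tt, tp, ref)
      }
    }
    v["struct_imputed"] <- as.numeric(imputed)
  }

  v
}

#' Feature vector for one (target, template) pair
#'
#' @param target,template Single-row protein records (see [protein_tbl()]).
#' @param config An `fr_feature_config`.
#' @return Named numeric vector in the order of [feature_names()]; never
#'   fails on missing MSAs or tracks (those features are imputed to 0 with
#'   the matching `*_imputed` indicator set to 1).
#' @export
featurize_pair <- function(target, template, config = feature_config()) {
  featurize_from_assets(protein_assets(target, config),
                        protein_assets(template, config), config)
}

#' Feature table for a whole benchmark
#'
#' Computes the feature vector of every ordered (target, template) pair.
#' Per-protein work (compositions, profiles) is done once per protein.
#'
#' @param proteins A protein table.
#' @param pairs Optional pair table from [enumerate_pairs()]; enumerated
#'   when omitted.
#' @param config An `fr_feature_config`.
#' @param verbose Print a progress line every 2000 pairs.
#' @return The pair table with one numeric column per feature appended.
#' @export
featurize_pairs <- function(proteins, pairs = NULL,
                            config = feature_config(), verbose = FALSE) {
  validate_proteins(proteins)
  if (is.null(pairs)) pairs <- enumerate_pairs(proteins)
  assets <- lapply(seq_len(nrow(proteins)), function(i) {
    protein_assets(proteins[i, ], config)
  })
  names(assets) <- proteins$id
  nm <- feature_names(config)
  X <- matrix(NA_real_, nrow = nrow(pairs), ncol = length(nm),
              dimnames = list(NULL, nm))
  for (i in seq_len(nrow(pairs))) {
    X[i, ] <- featurize_from_assets(assets[[pairs$target_id[[i]]]],
                                    assets[[pairs$template_id[[i]]]], config)
    if (verbose && i %% 2000 == 0) {
      message(sprintf("featurized %d / %d pairs", i, nrow(pairs)))
    }
  }
  dplyr::bind_cols(pairs, tibble::as_tibble(X))
}

# metadata columns that precede the feature columns in a feature table
FEATURE_META_COLS <- c("target_id", "template_id", "relationship", "positive",
                       "fold", "prob")

feature_cols <- function(tbl) setdiff(names(tbl), FEATURE_META_COLS)
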