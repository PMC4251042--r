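# pairwise alignment plumbing: sequence-sequence, sequence-profile and
# profile-profile dynamic programming with affine gaps, plus
# structural-state compatibility evaluated on an alignment

# BLOSUM62 is lazy-loaded once from Biostrings
the <- new.env(parent = emptyenv())

default_submat <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62
  }
  the$blosum62
}

new_alignment <- function(score, pairs, len_a, len_b, mode) {
  structure(
    list(
      score = score,
      aligned_pairs = pairs,  # k x 2 integer matrix, 0-based, increasing
      normalized_score = score / min(len_a, len_b),
      mode = mode
    ),
    class = "fr_alignment"
  )
}

#' @export
print.fr_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment> score %.4g (normalized %.4g), %d aligned pairs\n",
              x$mode, x$score, x$normalized_score, nrow(x$aligned_pairs)))
  invisible(x)
}

run_dp <- function(S, gap_open, gap_extend, mode) {
  storage.mode(S) <- "double"
  res <- align_dp_cpp(S, gap_open, gap_extend, identical(mode, "local"))
  new_alignment(res$score, res$pairs, nrow(S), ncol(S), mode)
}

#' Align two amino-acid sequences
#'
#' Affine-gap dynamic programming (Needleman-Wunsch for `mode = "global"`,
#' Smith-Waterman for `mode = "local"`). A gap of length k scores
#' `gap_open + k * gap_extend`; the defaults (BLOSUM62, -11/-1) follow BLAST
#' conventions. Traceback ties prefer diagonal over up over left, so the
#' reported alignment is deterministic.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param mode `"global"` or `"local"`.
#' @param submat Substitution matrix with residue dimnames; default BLOSUM62.
#' @param gap_open,gap_extend Gap penalties (<= 0).
#' @return An `fr_alignment`: `score`, `aligned_pairs` (0-based k x 2 matrix
#'   of matched coordinates), `normalized_score` (score divided by the
#'   shorter sequence length).
#' @export
#' @examples
#' align_sequences("HEAGAWGHEE", "PAWHEAE")$score
align_sequences <- function(a, b, mode = c("global", "local"), submat = NULL,
                            gap_open = -11, gap_extend = -1) {
  mode <- match.arg(mode)
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  if (is.null(submat)) submat <- default_submat()
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  ia <- match(ca, rownames(submat))
  ib <- match(cb, colnames(submat))
  if (anyNA(ia)) {
    abort(sprintf("residue '%s' absent from the substitution matrix", ca[which(is.na(ia))[1]]))
  }
  if (anyNA(ib)) {
    abort(sprintf("residue '%s' absent from the substitution matrix", cb[which(is.na(ib))[1]]))
  }
  S <- submat[ia, ib, drop = FALSE]
  run_dp(S, gap_open, gap_extend, mode)
}

#' Build a sequence profile from a multiple sequence alignment
#'
#' Per-column pseudocount-smoothed residue frequencies. The first MSA row is
#' the reference; columns where the reference carries a gap are dropped, so
#' the profile length equals the reference's ungapped length. Gap characters
#' in other rows are excluded from the counts.
#'
#' @param msa Character vector of equal-length aligned sequences; first row
#'   is the reference.
#' @param pseudocount Added to every residue count in every column
#'   (default 0.01); keep it positive when the profile will be aligned, so
#'   log-ratio scores stay finite.
#' @return An `fr_profile`: `length` and `mat`, an L x 20 matrix whose rows
#'   sum to 1.
#' @export
build_profile <- function(msa, pseudocount = 0.01) {
  if (length(msa) == 0) abort("empty MSA")
  if (length(unique(nchar(msa))) != 1) abort("ragged MSA: rows differ in length")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  rows <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  ref <- rows[1, ]
  keep <- !(ref %in% c("-", "."))
  rows <- rows[, keep, drop = FALSE]
  L <- ncol(rows)
  mat <- matrix(pseudocount, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- rows[, j]
    col <- col[!(col %in% c("-", "."))]
    for (letter in unique(col)) {
      mat[j, ] <- mat[j, ] + residue_distribution(letter) * sum(col == letter)
    }
  }
  mat <- mat / rowSums(mat)
  structure(list(length = L, mat = mat, pseudocount = pseudocount),
            class = "fr_profile")
}

#' @export
print.fr_profile <- function(x, ...) {
  cat(sprintf("<profile> %d columns, pseudocount %g\n", x$length, x$pseudocount))
  invisible(x)
}

# position-score matrix of a profile against per-position residue
# distributions (20 x m); background uniform 1/20, scores clamped so a zero
# profile entry stays finite
profile_score_matrix <- function(mat, D) {
  S <- log2(20 * (mat %*% D))
  pmax(S, -1e6)
}

#' Align a profile against a sequence
#'
#' Dynamic-programming alignment where matching profile column c to residue
#' r scores \eqn{\log_2(c[r] / b[r])} against a uniform background
#' \eqn{b[r] = 1/20}; gap handling and tie-breaking as in
#' [align_sequences()].
#'
#' @param profile An `fr_profile`.
#' @param seq Non-empty amino-acid string.
#' @inheritParams align_sequences
#' @return An `fr_alignment`; `aligned_pairs` uses (profile column,
#'   sequence position) 0-based coordinates.
#' @export
align_sequence_profile <- function(profile, seq, mode = c("global", "local"),
                                   gap_open = -11, gap_extend = -1) {
  mode <- match.arg(mode)
  if (!inherits(profile, "fr_profile")) abort("first argument must be an fr_profile")
  if (nchar(seq) == 0) abort("sequence must be non-empty")
  D <- residue_distribution_matrix(seq_chars(seq))
  S <- profile_score_matrix(profile$mat, D)
  run_dp(S, gap_open, gap_extend, mode)
}

#' Align two profiles
#'
#' Dynamic programming with the dot-product profile-profile column score
#' \eqn{\log_2(\sum_r p[r] q[r] / \sum_r b[r]^2)} with uniform background
#' \eqn{b = 1/20} (so two identical single-residue columns score
#' \eqn{\log_2 20}).
#'
#' @param p,q `fr_profile` objects.
#' @inheritParams align_sequences
#' @return An `fr_alignment` in (p column, q column) 0-based coordinates.
#' @export
align_profiles <- function(p, q, mode = c("global", "local"),
                           gap_open = -11, gap_extend = -1) {
  mode <- match.arg(mode)
  if (!inherits(p, "fr_profile") || !inherits(q, "fr_profile")) {
    abort("both arguments must be fr_profile objects")
  }
  if (p$length == 0 || q$length == 0) abort("cannot align an empty profile")
  S <- pmax(log2(20 * tcrossprod(p$mat, q$mat)), -1e6)
  run_dp(S, gap_open, gap_extend, mode)
}

#' Structural-state compatibility of an aligned pair
#'
#' Fraction of aligned positions whose structural states (e.g. 3-state
#' secondary structure) are identical; 0 for an empty alignment.
#'
#' @param track_t,track_p Per-residue state strings of target and template.
#' @param aligned_pairs An `fr_alignment` or a 0-based k x 2 integer matrix
#'   of (target position, template position) matches.
#' @return A number in \eqn{[0, 1]}.
#' @export
structural_compatibility <- function(track_t, track_p, aligned_pairs) {
  if (inherits(aligned_pairs, "fr_alignment")) {
    aligned_pairs <- aligned_pairs$aligned_pairs
  }
  if (is.null(dim(aligned_pairs)) || ncol(aligned_pairs) != 2) {
    abort("aligned_pairs must be a k x 2 matrix")
  }
  if (nrow(aligned_pairs) == 0) return(0)
  ct <- seq_chars(track_t)
  cp <- seq_chars(track_p)
  it <- aligned_pairs[, 1] + 1L
  ip <- aligned_pairs[, 2] + 1L
  if (any(it < 1L) || any(it > length(ct)) || any(ip < 1L) || any(ip > length(cp))) {
    abort("aligned position out of range for the given tracks")
  }
  mean(ct[it] == cp[ip])
}
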