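# amino-acid composition features and the kernel similarities applied to
# them: the sequence/family-information feature category

#' Monomer (single amino-acid) composition
#'
#' Relative frequency of each of the 20 standard amino acids in a sequence.
#' Non-standard letters (B, Z, J, X, U, O) contribute a uniform share over
#' their ambiguity set; X contributes 1/20 to every residue.
#'
#' @param sequence Non-empty amino-acid string.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' monomer_composition("AAC")[c("A", "C")]
monomer_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("sequence must be a single non-empty string")
  }
  chars <- seq_chars(sequence)
  idx <- match(chars, AA20)
  counts <- tabulate(idx[!is.na(idx)], nbins = 20)
  names(counts) <- AA20
  counts <- as.numeric(counts)
  names(counts) <- AA20
  for (letter in unique(chars[is.na(idx)])) {
    d <- residue_distribution(letter)  # errors on unknown letters
    counts <- counts + d * sum(chars == letter)
  }
  counts / length(chars)
}

#' Dimer (ordered amino-acid pair) composition
#'
#' Relative frequency of each of the 400 ordered residue pairs among the
#' L - 1 overlapping windows of a sequence. Ambiguous letters contribute the
#' outer product of their per-letter distributions.
#'
#' @param sequence Amino-acid string of length >= 2.
#' @return Named numeric vector of length 400 summing to 1; names are the
#'   two-letter dimers in column-major order over the alphabet.
#' @export
#' @examples
#' dimer_composition("AAC")[c("AA", "AC")]
dimer_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 2L) {
    abort("dimer composition requires a sequence of length >= 2")
  }
  chars <- seq_chars(sequence)
  L <- length(chars)
  dimer_names <- as.vector(outer(AA20, AA20, paste0))
  idx <- match(chars, AA20)
  if (!anyNA(idx)) {
    # pure-standard fast path: dimer (a, b) sits at a + 20 * (b - 1)
    code <- idx[-L] + 20L * (idx[-1L] - 1L)
    counts <- tabulate(code, nbins = 400)
    out <- counts / (L - 1)
    names(out) <- dimer_names
    return(out)
  }
  D <- residue_distribution_matrix(chars)
  acc <- matrix(0, 20, 20)
  for (i in seq_len(L - 1L)) {
    acc <- acc + tcrossprod(D[, i], D[, i + 1L])
  }
  out <- as.vector(acc) / (L - 1)
  names(out) <- dimer_names
  out
}

#' Cosine similarity of two nonnegative vectors
#'
#' @param u,v Equal-length numeric vectors, each with at least one nonzero
#'   entry.
#' @return dot(u, v) / (||u|| ||v||); in \eqn{[0, 1]} for nonnegative input.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Pearson-correlation similarity
#'
#' Pearson correlation of two vectors, with the convention that a constant
#' vector (zero variance) yields 0 rather than NA: a constant composition
#' carries no correlation signal.
#'
#' @param u,v Equal-length numeric vectors of length >= 2.
#' @return Correlation in \eqn{[-1, 1]}, or 0 when either vector is constant.
#' @export
correlation_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  if (length(u) < 2L) abort("correlation requires vectors of length >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  stats::cor(u, v)
}

#' Gaussian-kernel similarity
#'
#' \eqn{\exp(-\gamma \lVert u - v \rVert^2)}. The default bandwidth
#' \eqn{\gamma = 1/d} (d = vector length) is scale-free across the monomer
#' (d = 20) and dimer (d = 400) compositions.
#'
#' @param u,v Equal-length numeric vectors.
#' @param gamma Positive kernel bandwidth.
#' @return Similarity in \eqn{(0, 1]}.
#' @export
gaussian_similarity <- function(u, v, gamma = 1 / length(u)) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    abort("gamma must be a positive number")
  }
  exp(-gamma * sum((u - v)^2))
}
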