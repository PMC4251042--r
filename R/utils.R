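# shared constants and small helpers

# the 20 standard amino acids, alphabetical one-letter codes
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ambiguity sets: each non-standard letter contributes a uniform share over
# its set (X over all 20; U/O map to their closest standard residue)
AA_AMBIGUITY <- list(
  B = c("D", "N"),
  Z = c("E", "Q"),
  J = c("I", "L"),
  X = AA20,
  U = "C",
  O = "K"
)

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Ungapped sequence identity
#'
#' Fraction of positions with identical residues when two equal-length
#' sequences are compared position by position; for unequal lengths the
#' comparison runs over the shorter sequence and the denominator is the
#' shorter length.
#'
#' @param a,b Amino-acid strings.
#' @return A number in \eqn{[0, 1]}.
#' @export
sequence_identity <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  n <- min(length(ca), length(cb))
  if (n == 0L) abort("cannot compute identity of an empty sequence")
  mean(ca[seq_len(n)] == cb[seq_len(n)])
}

# per-residue distribution over AA20 as a 20-vector; errors on unknown letters
residue_distribution <- function(letter) {
  out <- numeric(20)
  names(out) <- AA20
  i <- match(letter, AA20)
  if (!is.na(i)) {
    out[i] <- 1
    return(out)
  }
  set <- AA_AMBIGUITY[[letter]]
  if (is.null(set)) {
    abort(sprintf("unknown residue '%s'", letter))
  }
  out[set] <- 1 / length(set)
  out
}

# 20 x L matrix of per-position residue distributions for a sequence
residue_distribution_matrix <- function(chars) {
  idx <- match(chars, AA20)
  if (anyNA(idx)) {
    cols <- vapply(chars, residue_distribution, numeric(20))
    dimnames(cols) <- list(AA20, NULL)
    return(cols)
  }
  m <- matrix(0, nrow = 20, ncol = length(chars), dimnames = list(AA20, NULL))
  m[cbind(idx, seq_along(chars))] <- 1
  m
}

# exact text round-trip for doubles (used by model serialization)
num_to_text <- function(x) sprintf("%.17g", x)
text_to_num <- function(x) as.numeric(x)

# write-then-rename so interrupted runs never leave truncated files
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("failed to write '%s'", path))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
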