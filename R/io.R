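# on-disk benchmark interchange: a tab-separated manifest pointing at
# per-protein FASTA sequences, aligned-FASTA MSAs and FASTA-like structural
# track files, plus TSV feature tables

#' Write a benchmark to disk
#'
#' Layout: `manifest.tsv` (columns protein_id, family_id, superfamily_id,
#' fold_id, fasta_path, msa_path, struct_path; `-` marks a missing optional
#' asset) with paths relative to the manifest; `seq/<id>.fasta`,
#' `msa/<id>.afa` (aligned FASTA) and `struct/<id>.track` (FASTA-like, one
#' record per track name). A `provenance.json` records the generator config
#' and package version when the table came from [generate_benchmark()].
#'
#' @param proteins A protein table.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_benchmark <- function(proteins, dir) {
  validate_proteins(proteins)
  for (sub in c("", "seq", "msa", "struct")) {
    d <- file.path(dir, sub)
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      abort(sprintf("cannot create output directory '%s'", d))
    }
  }
  n <- nrow(proteins)
  fasta_path <- file.path("seq", paste0(proteins$id, ".fasta"))
  msa_path <- character(n)
  struct_path <- character(n)
  for (i in seq_len(n)) {
    id <- proteins$id[[i]]
    seq_set <- Biostrings::BStringSet(stats::setNames(proteins$sequence[[i]], id))
    Biostrings::writeXStringSet(seq_set, file.path(dir, fasta_path[[i]]))
    msa <- proteins$msa[[i]]
    if (!is.null(msa) && length(msa) > 0) {
      msa_path[[i]] <- file.path("msa", paste0(id, ".afa"))
      rows <- stats::setNames(msa, c(id, paste0(id, "_hom", seq_len(length(msa) - 1))))
      Biostrings::writeXStringSet(Biostrings::BStringSet(rows),
                                  file.path(dir, msa_path[[i]]))
    } else {
      msa_path[[i]] <- "-"
    }
    st <- proteins$struct[[i]]
    if (!is.null(st) && length(st) > 0) {
      struct_path[[i]] <- file.path("struct", paste0(id, ".track"))
      Biostrings::writeXStringSet(Biostrings::BStringSet(st),
                                  file.path(dir, struct_path[[i]]))
    } else {
      struct_path[[i]] <- "-"
    }
  }
  manifest <- tibble::tibble(
    protein_id = proteins$id,
    family_id = proteins$family_id,
    superfamily_id = proteins$superfamily_id,
    fold_id = proteins$fold_id,
    fasta_path = fasta_path,
    msa_path = msa_path,
    struct_path = struct_path
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  write_atomic(manifest_path, function(tmp) readr::write_tsv(manifest, tmp))
  config <- attr(proteins, "config")
  if (!is.null(config)) {
    write_atomic(file.path(dir, "provenance.json"), function(tmp) {
      jsonlite::write_json(
        list(generator = unclass(config),
             package_version = as.character(utils::packageVersion("foldrec"))),
        tmp, auto_unbox = TRUE, digits = NA)
    })
  }
  invisible(manifest_path)
}

read_fasta_vec <- function(path, what) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf("malformed %s file '%s': %s",
                                                    what, path, conditionMessage(e))))
  stats::setNames(as.character(set), names(set))
}

#' Read a benchmark from a manifest
#'
#' Inverse of [write_benchmark()]: resolves the per-protein FASTA, aligned
#' FASTA and track paths relative to the manifest and rebuilds the protein
#' table.
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return A validated protein table.
#' @export
read_benchmark <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest '%s' does not exist", manifest_path))
  }
  base <- dirname(manifest_path)
  manifest <- readr::read_tsv(manifest_path, col_types = readr::cols(.default = "c"))
  need <- c("protein_id", "family_id", "superfamily_id", "fold_id",
            "fasta_path", "msa_path", "struct_path")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(manifest)
  sequence <- character(n)
  msa <- vector("list", n)
  struct <- vector("list", n)
  for (i in seq_len(n)) {
    seqs <- read_fasta_vec(file.path(base, manifest$fasta_path[[i]]), "FASTA")
    if (length(seqs) != 1) {
      abort(sprintf("expected one record in '%s', found %d",
                    manifest$fasta_path[[i]], length(seqs)))
    }
    sequence[[i]] <- unname(seqs)
    if (manifest$msa_path[[i]] != "-") {
      msa[[i]] <- unname(read_fasta_vec(file.path(base, manifest$msa_path[[i]]),
                                        "aligned FASTA"))
    }
    if (manifest$struct_path[[i]] != "-") {
      struct[[i]] <- read_fasta_vec(file.path(base, manifest$struct_path[[i]]),
                                    "track")
    }
  }
  protein_tbl(manifest$protein_id, sequence, manifest$family_id,
              manifest$superfamily_id, manifest$fold_id,
              msa = msa, struct = struct)
}

#' Write / read a feature table as TSV
#'
#' Header: `target_id`, `template_id`, `relationship`, then the feature
#' names. The logical `positive` column is not stored (it is implied by
#' `relationship != "none"`) and is restored on read.
#'
#' @param features Feature table from [featurize_pairs()].
#' @param path TSV path.
#' @return `write_feature_table` the path invisibly; `read_feature_table`
#'   the restored tibble.
#' @export
write_feature_table <- function(features, path) {
  out <- features[, setdiff(names(features), c("positive", "fold", "prob"))]
  write_atomic(path, function(tmp) readr::write_tsv(out, tmp))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(target_id = "c", template_id = "c",
                            relationship = "c", .default = "d")
  )
  dplyr::mutate(tbl, positive = .data$relationship != "none",
                .after = "relationship")
}
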