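#' Read protein sequences from a FASTA file
#'
#' Reads plain or gzipped FASTA. The id of each record is the header token
#' before the first whitespace; residues are upper-cased. Ambiguity letters
#' (X, B, Z, U, O) are retained. Records with empty sequences, duplicate ids,
#' or residues outside the alphabet raise a descriptive error naming the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `residues`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 some description", "acdef"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file '%s' does not exist", path), call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(tibble(id = character(), residues = character()))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- tibble(id = ids, residues = unname(toupper(as.character(set))))
  check_seq_tbl(out, arg = basename(path))
  out
}

#' Write protein sequences to a FASTA file
#'
#' Round-trip stable with [read_fasta()] on (id, residues) pairs.
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @param path Output path (`.gz` suffix writes gzipped FASTA).
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_seq_tbl(seqs, arg = "seqs")
  set <- Biostrings::AAStringSet(stats::setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(seqs)
}

#' Filter sequences by length window
#'
#' Keeps records whose residue count lies in `[min_len, max_len]`, inclusive
#' on both ends; input order is preserved. The default window 800-1600 is the
#' mining pre-filter used throughout the package.
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @param min_len,max_len Inclusive residue-count bounds (both >= 1).
#' @return The surviving rows of `seqs`.
#' @export
filter_by_length <- function(seqs, min_len = 800L, max_len = 1600L) {
  check_seq_tbl(seqs, arg = "seqs")
  if (min_len > max_len) {
    stop("`min_len` must be <= `max_len`", call. = FALSE)
  }
  if (min_len < 1) {
    stop("`min_len` must be >= 1", call. = FALSE)
  }
  len <- nchar(seqs$residues)
  seqs[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Attach a class label to a sequence table
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @param label 1 for the Cas9-like positive class, 0 for negatives.
#' @return `seqs` with a `label` column.
#' @export
label_sequences <- function(seqs, label) {
  check_seq_tbl(seqs, arg = "seqs")
  if (length(label) != 1 || !label %in% c(0, 1)) {
    stop("`label` must be a single 0 or 1", call. = FALSE)
  }
  dplyr::mutate(seqs, label = as.integer(label))
}
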