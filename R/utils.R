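# Residue alphabet: 20 standard amino acids plus the ambiguity/rare letters
# X, B, Z, U, O that occur in real genome translations. PAD is the encoder's
# padding token and never appears in residue strings.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTENDED <- c(AA_STANDARD, "X", "B", "Z", "U", "O")
AA_REGEX <- paste0("^[", paste(AA_EXTENDED, collapse = ""), "]+$")

#' Residue alphabets
#'
#' `aa_standard()` returns the 20 standard amino-acid letters;
#' `aa_extended()` adds the ambiguity letters X, B, Z, U and O that are kept
#' (not dropped) throughout the package.
#'
#' @return Character vector of single-letter residue codes.
#' @export
aa_standard <- function() AA_STANDARD

#' @rdname aa_standard
#' @export
aa_extended <- function() AA_EXTENDED

# Deterministic 31-bit hash of (seed, key) used to derive per-sequence and
# per-threshold RNG seeds; stable under reordering of the input records.
derive_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Validate a sequence table (columns id, residues; optionally label).
check_seq_tbl <- function(x, require_label = FALSE, arg = "x") {
  if (!is.data.frame(x)) {
    stop(sprintf("`%s` must be a data frame with columns `id` and `residues`", arg),
         call. = FALSE)
  }
  need <- c("id", "residues", if (require_label) "label")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("`%s` is missing column(s): %s", arg,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$id)) {
    dup <- x$id[duplicated(x$id)][1]
    stop(sprintf("duplicate sequence id '%s' in `%s`", dup, arg), call. = FALSE)
  }
  if (nrow(x) > 0) {
    if (any(!nzchar(x$residues))) {
      bad <- x$id[!nzchar(x$residues)][1]
      stop(sprintf("record '%s' has an empty sequence", bad), call. = FALSE)
    }
    ok <- grepl(AA_REGEX, x$residues)
    if (any(!ok)) {
      bad_id <- x$id[!ok][1]
      bad_char <- setdiff(strsplit(x$residues[!ok][1], "")[[1]], AA_EXTENDED)[1]
      stop(sprintf("record '%s' contains residue '%s' outside the allowed alphabet",
                   bad_id, bad_char), call. = FALSE)
    }
  }
  if (require_label && nrow(x) > 0 && !all(x$label %in% c(0, 1))) {
    stop(sprintf("`%s` labels must all be 0 or 1", arg), call. = FALSE)
  }
  invisible(x)
}

#' Dataset metadata
#'
#' Provenance metadata (source, shuffle threshold, seed, ...) attached to the
#' sequence tibbles produced by the generators in this package.
#'
#' @param x A tibble produced by, e.g., [build_negative_dataset()].
#' @return A named list (possibly empty).
#' @export
dataset_metadata <- function(x) {
  md <- attr(x, "metadata")
  if (is.null(md)) list() else md
}

`dataset_metadata<-` <- function(x, value) {
  attr(x, "metadata") <- value
  x
}
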