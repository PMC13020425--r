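#' Partially shuffle a single protein sequence
#'
#' Selects `k = round(threshold * L)` positions uniformly at random without
#' replacement and permutes the residues at those positions among themselves
#' by a uniform random permutation (a position may map to itself). The
#' residue multiset — and hence the amino-acid composition — is exactly
#' preserved; at most `k` positions change. Deterministic given `seed`.
#'
#' @param residues A single residue string.
#' @param threshold Fraction of positions to shuffle, in `[0, 1]`.
#' @param seed RNG seed.
#' @return The shuffled residue string.
#' @examples
#' shuffle_sequence("ACDEFGHIKL", threshold = 1, seed = 7)
#' @export
shuffle_sequence <- function(residues, threshold, seed) {
  if (length(residues) != 1 || !is.character(residues) || !nzchar(residues)) {
    stop("`residues` must be a single non-empty string", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  k <- round(threshold * L)
  if (k > 1) {
    withr::with_seed(as.integer(seed), {
      pos <- sample.int(L, k)
      perm <- sample.int(k)
    })
    chars[pos] <- chars[pos][perm]
  }
  paste(chars, collapse = "")
}

#' Build a shuffled negative dataset from labeled positives
#'
#' One shuffled negative per positive, labeled 0; ids are suffixed so they
#' stay unique when positives and negatives are combined. Per-sequence seeds
#' are derived from `seed` and the sequence id, so the result does not depend
#' on record order. The threshold and seed are recorded in the dataset
#' metadata (see [dataset_metadata()]).
#'
#' @param positives A tibble with columns `id`, `residues` and, if present,
#'   `label` all equal to 1.
#' @param threshold Fraction of positions to shuffle, in `[0, 1]`.
#' @param seed Base RNG seed.
#' @return A tibble with columns `id`, `residues`, `label` (all 0).
#' @export
build_negative_dataset <- function(positives, threshold, seed) {
  check_seq_tbl(positives, arg = "positives")
  if ("label" %in% names(positives) && nrow(positives) > 0 &&
      !all(positives$label == 1)) {
    stop("`positives` must all be labeled 1", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  suffix <- sprintf("_neg%02d", round(threshold * 100))
  out <- tibble(
    id = paste0(positives$id, suffix),
    residues = purrr::map_chr(seq_len(nrow(positives)), function(i) {
      shuffle_sequence(positives$residues[i], threshold,
                       derive_seed(seed, positives$id[i]))
    }),
    label = rep(0L, nrow(positives))
  )
  dataset_metadata(out) <- list(source = "shuffled_negatives",
                                threshold = threshold, seed = as.integer(seed))
  out
}

#' Generate negative datasets over a sweep of shuffle thresholds
#'
#' The default sweep, thresholds 0.1 to 1.0 in steps of 0.1, produces the ten
#' negative datasets used to pick the training threshold. Per-threshold seeds
#' are derived deterministically from `base_seed`.
#'
#' @param positives A tibble of positive sequences (`id`, `residues`).
#' @param thresholds Fractions in `(0, 1]`.
#' @param base_seed Base RNG seed.
#' @return A tibble with one row per threshold and columns `threshold`,
#'   `seed`, and `data` (a list column of negative datasets).
#' @export
shuffle_sweep <- function(positives, thresholds = seq(0.1, 1.0, by = 0.1),
                          base_seed = 1L) {
  if (length(thresholds) == 0) {
    stop("`thresholds` must be non-empty", call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("all `thresholds` must lie in (0, 1]", call. = FALSE)
  }
  seeds <- vapply(thresholds,
                  function(p) derive_seed(base_seed, sprintf("threshold_%.6f", p)),
                  integer(1))
  tibble(
    threshold = thresholds,
    seed = seeds,
    data = purrr::map2(thresholds, seeds,
                       function(p, s) build_negative_dataset(positives, p, s))
  )
}
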