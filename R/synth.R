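# Fixed default motifs planted in synthetic positives. Width 12 (the top of
# the supported 8-12 range) so that motif spans are comparable in size to
# the top-5% saliency window of an 800-1200 residue sequence, which keeps
# motif-localization properties measurable.
CF_MOTIFS <- c("WDYKHFRMCQLP", "GNAVESTIWKYD", "HMPLCRFQGEAV")

# Swiss-Prot-like background amino-acid frequencies (percent).
CF_UNIPROT_FREQ <- c(
  A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
  I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
  R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
)

#' Default planted motifs
#'
#' Three fixed width-12 residue strings planted in every synthetic positive.
#'
#' @return Character vector of motif strings.
#' @export
default_motifs <- function() CF_MOTIFS

#' Generate a motif-planted synthetic positive dataset
#'
#' Each sequence is background-sampled (uniform over the 20 standard
#' residues, or Swiss-Prot-like frequencies) with every motif planted
#' verbatim at its jittered relative position. Planted spans are recorded as
#' ground truth in `attr(, "motif_spans")`. Deterministic given `seed`.
#'
#' @param n Number of sequences.
#' @param length_range Inclusive `c(min, max)` sequence length range.
#' @param motifs Character vector of motif strings (widths 8-12 advised).
#' @param motif_rel_pos Relative positions (fractions of the length) of the
#'   motif centers; recycled against `motifs`.
#' @param jitter Uniform positional jitter, in residues, around each center.
#' @param background `"uniform"` or `"uniprot"`.
#' @param seed RNG seed.
#' @return A tibble (`id`, `residues`, `label` = 1) with attributes
#'   `motif_spans` (tibble: id, motif, start, end) and `metadata`.
#' @export
make_positive_set <- function(n = 400L, length_range = c(800L, 1200L),
                              motifs = default_motifs(),
                              motif_rel_pos = c(0.15, 0.5, 0.85),
                              jitter = 25L, background = c("uniform", "uniprot"),
                              seed = 1L) {
  background <- match.arg(background)
  if (length(length_range) != 2 || length_range[1] > length_range[2]) {
    stop("`length_range` must be c(min, max)", call. = FALSE)
  }
  widths <- nchar(motifs)
  if (length(motifs) > 0) {
    if (any(!grepl(AA_REGEX, motifs))) {
      stop("motifs must use the residue alphabet", call. = FALSE)
    }
    rel <- rep_len(motif_rel_pos, length(motifs))
    if (sum(widths) + 2 * length(motifs) * jitter > length_range[1]) {
      stop("motifs (plus jitter) do not fit within the minimum length",
           call. = FALSE)
    }
  }
  prob <- if (background == "uniform") rep(1 / 20, 20) else
    CF_UNIPROT_FREQ[AA_STANDARD] / sum(CF_UNIPROT_FREQ)

  withr::with_seed(as.integer(seed), {
    spans_list <- vector("list", n)
    residues <- character(n)
    for (i in seq_len(n)) {
      L <- sample(seq(length_range[1], length_range[2]), 1)
      chars <- sample(AA_STANDARD, L, replace = TRUE, prob = prob)
      placed <- tibble(motif = integer(), start = integer(), end = integer())
      for (m in seq_along(motifs)) {
        w <- widths[m]
        ok <- FALSE
        for (try in seq_len(100)) {
          center <- round(rel[m] * L) + sample(seq(-jitter, jitter), 1)
          start <- min(max(1L, center - floor(w / 2)), L - w + 1L)
          end <- start + w - 1L
          if (nrow(placed) == 0 ||
              all(end < placed$start | start > placed$end)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(sprintf("could not place motif %d without overlap in sequence %d",
                       m, i), call. = FALSE)
        }
        chars[start:end] <- strsplit(motifs[m], "")[[1]]
        placed <- dplyr::bind_rows(placed,
                                   tibble(motif = m, start = start, end = end))
      }
      residues[i] <- paste(chars, collapse = "")
      if (nrow(placed) > 0) {
        placed$id <- sprintf("pos_%04d", i)
        spans_list[[i]] <- placed
      }
    }
  })
  out <- tibble(id = sprintf("pos_%04d", seq_len(n)), residues = residues,
                label = 1L)
  attr(out, "motif_spans") <- if (n > 0 && length(motifs) > 0) {
    dplyr::bind_rows(spans_list)[, c("id", "motif", "start", "end")]
  } else {
    tibble(id = character(), motif = integer(), start = integer(),
           end = integer())
  }
  dataset_metadata(out) <- list(source = "synthetic_positives", seed = seed,
                                background = background,
                                motifs = motifs)
  out
}

#' Ground-truth motif spans of a synthetic positive set
#'
#' @param x A dataset from [make_positive_set()].
#' @return A tibble with columns `id`, `motif`, `start`, `end`.
#' @export
motif_spans <- function(x) {
  sp <- attr(x, "motif_spans")
  if (is.null(sp)) stop("`x` carries no motif-span ground truth", call. = FALSE)
  sp
}

#' Simulate an indel-free homolog family
#'
#' Homologs are point-substituted copies of the reference: each position is
#' substituted with probability `sub_rate` (positions listed in `conserved`
#' with `sub_rate / 10`), drawing uniformly from the 19 other standard
#' residues. Having no indels, the rows are already aligned and the column
#' map is the identity. The reference is included as the first row.
#'
#' @param reference A residue string or one-row tibble (`id`, `residues`).
#' @param n Number of homologs (in addition to the reference row).
#' @param sub_rate Per-position substitution rate in `[0, 1]`.
#' @param conserved Integer positions substituted at `sub_rate / 10`.
#' @param seed RNG seed.
#' @return An alignment tibble (`id`, `aligned`) with attributes
#'   `conserved`, `ref_id`.
#' @export
make_homolog_family <- function(reference, n = 100L, sub_rate = 0.1,
                                conserved = integer(), seed = 1L) {
  if (is.data.frame(reference)) {
    ref_id <- reference$id[1]
    ref <- reference$residues[1]
  } else {
    ref_id <- "ref"
    ref <- reference
  }
  if (sub_rate < 0 || sub_rate > 1) stop("`sub_rate` must be in [0, 1]", call. = FALSE)
  chars <- strsplit(ref, "")[[1]]
  L <- length(chars)
  if (any(conserved < 1 | conserved > L)) {
    stop("`conserved` positions out of range", call. = FALSE)
  }
  rate <- rep(sub_rate, L)
  rate[conserved] <- sub_rate / 10
  rows <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      hit <- which(stats::runif(L) < rate)
      h <- chars
      for (p in hit) {
        h[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1)
      }
      paste(h, collapse = "")
    }, character(1))
  })
  out <- tibble(id = c(ref_id, sprintf("hom_%04d", seq_len(n))),
                aligned = c(ref, rows))
  attr(out, "conserved") <- as.integer(conserved)
  attr(out, "ref_id") <- ref_id
  dataset_metadata(out) <- list(source = "synthetic_homologs", seed = seed,
                                sub_rate = sub_rate)
  out
}

#' Build an annotation table for mining tests
#'
#' Takes an explicit per-record specification (columns `length`,
#' `pfam_hits`, `repeat_count`, `score`) so that cascade survivors are
#' hand-enumerable, assigns ids, and shuffles row order (seeded) so nothing
#' downstream depends on record order. An empty spec yields an empty table.
#'
#' @param spec A tibble with columns `length`, `pfam_hits` (comma-separated
#'   string), `repeat_count` (NA allowed), `score`.
#' @param seed RNG seed for the row shuffle.
#' @return An annotation tibble with an added `id` column.
#' @export
make_mining_table <- function(spec, seed = 1L) {
  stopifnot(is.data.frame(spec))
  need <- c("length", "pfam_hits", "repeat_count", "score")
  if (nrow(spec) == 0) {
    return(tibble(id = character(), length = integer(),
                  pfam_hits = character(), repeat_count = integer(),
                  score = numeric()))
  }
  missing_cols <- setdiff(need, names(spec))
  if (length(missing_cols) > 0) {
    stop(sprintf("spec is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- as_tibble(spec)
  out$id <- sprintf("cand_%04d", seq_len(nrow(out)))
  out <- out[, c("id", need)]
  withr::with_seed(as.integer(seed), {
    out <- out[sample(nrow(out)), , drop = FALSE]
  })
  out
}

#' A mining table shaped like a real screen
#'
#' A deterministic record specification for [make_mining_table()]: eight
#' 100-residue bins over the 800-1600 window plus two out-of-window records;
#' the 1301-1400 bin carries the most multi-domain entries and all the
#' high-scoring candidates, with repeat counts placed on the strict >50
#' boundary (49, 50, 51, 56, 60 and one missing) so every cascade stage is
#' hand-checkable. The top-scoring keeper lacks repeat information; the
#' second-highest score carries 56 repeats and therefore ranks first after
#' the repeat filter.
#'
#' @return A tibble usable as the `spec` of [make_mining_table()].
#' @export
mining_table_preset <- function() {
  doms <- cas9_pfam_domains()
  pf <- function(k) paste(doms[seq_len(k)], collapse = ",")
  filler <- dplyr::bind_rows(lapply(c(820L, 930L, 1040L, 1150L, 1260L,
                                      1450L, 1560L), function(len) {
    tibble(length = len + 0:2,
           pfam_hits = c(pf(2), pf(3), pf(1)),
           repeat_count = c(0L, 3L, NA),
           score = c(0.2, 0.4, 0.1))
  }))
  target <- tibble(
    length = c(1310L, 1320L, 1330L, 1340L, 1350L, 1360L, 1370L,
               1380L, 1390L, 1395L, 1302L, 1399L),
    pfam_hits = c(pf(5), pf(5), pf(5), pf(4), pf(4), pf(3), pf(3),
                  pf(3), pf(3), pf(3), pf(2), pf(2)),
    repeat_count = c(NA, 56L, 60L, 51L, 50L, 49L, 12L,
                     5L, 0L, 7L, 2L, 1L),
    score = c(0.98, 0.96, 0.95, 0.93, 0.92, 0.91, 0.55,
              0.52, 0.40, 0.30, 0.60, 0.45)
  )
  out_of_window <- tibble(length = c(799L, 1601L),
                          pfam_hits = c(pf(5), pf(5)),
                          repeat_count = c(99L, 99L), score = c(0.99, 0.99))
  dplyr::bind_rows(filler, target, out_of_window)
}
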