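# Cas9-related Pfam domains used for bin selection.
CAS9_PFAMS <- c("RuvC_III", "Cas9_BH", "Cas9_REC", "HNH_4", "Cas9_PI")

#' Cas9-related Pfam domain names
#'
#' The default domain set used by [select_bin_by_pfam()]: RuvC_III, Cas9_BH,
#' Cas9_REC, HNH_4 and Cas9_PI.
#'
#' @return Character vector of Pfam domain names.
#' @export
cas9_pfam_domains <- function() CAS9_PFAMS

#' Read a candidate annotation table
#'
#' Annotation tables are produced by external tools (profile-HMM domain
#' search, CRISPR repeat detection) and ingested as tab-separated text with a
#' header row and columns `id`, `length`, `pfam_hits` (comma-separated domain
#' names, may be empty) and `repeat_count` (may be missing/NA when no repeat
#' information exists for the source genome). An optional `score` column
#' carries precomputed model scores.
#'
#' @param path Path to a TSV file.
#' @return A tibble of annotation records.
#' @export
read_annotations <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    length = readr::col_integer(),
    pfam_hits = readr::col_character(),
    repeat_count = readr::col_integer(),
    .default = readr::col_guess()
  ))
  if (!all(c("id", "length") %in% names(out))) {
    stop("annotation table must have `id` and `length` columns", call. = FALSE)
  }
  if (!"pfam_hits" %in% names(out)) out$pfam_hits <- ""
  out$pfam_hits[is.na(out$pfam_hits)] <- ""
  if (!"repeat_count" %in% names(out)) out$repeat_count <- NA_integer_
  out
}

#' Partition annotation records into length bins
#'
#' Records inside the inclusive window are assigned to half-open bins
#' `[lo, lo + bin_width)` starting at the window minimum; the final bin is
#' closed at the window maximum. Bin labels are rendered `"lo+1-hi"` (e.g. a
#' width-100 bin starting at 1300 is labeled `"1301-1400"`). Records outside
#' the window are dropped.
#'
#' @param records An annotation tibble with `id` and `length` columns.
#' @param window Inclusive `c(min, max)` length window.
#' @param bin_width Bin width in residues.
#' @return `records` restricted to the window, with a `bin` factor column
#'   whose levels cover all bins in order.
#' @export
bin_by_length <- function(records, window = c(800L, 1600L), bin_width = 100L) {
  stopifnot(is.data.frame(records), all(c("id", "length") %in% names(records)))
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (length(window) != 2 || window[1] > window[2]) {
    stop("`window` must be c(min, max) with min <= max", call. = FALSE)
  }
  starts <- seq(window[1], window[2] - 1, by = bin_width)
  ends <- pmin(starts + bin_width, window[2])
  labels <- sprintf("%d-%d", starts + 1, ends)
  out <- records[records$length >= window[1] & records$length <= window[2], ,
                 drop = FALSE]
  idx <- pmin(findInterval(out$length, starts), length(starts))
  out$bin <- factor(labels[idx], levels = labels)
  out
}

#' Select the length bin richest in multi-domain Cas9 annotations
#'
#' For each bin, counts records annotated with at least 3, 4 and 5 distinct
#' Cas9-related Pfam domains, plus per-domain totals. The chosen bin
#' maximizes the count at `min_domains` distinct domains; ties are broken
#' toward the longer-length bin with a warning.
#'
#' @param binned Output of [bin_by_length()] (must contain `bin` and
#'   `pfam_hits` columns).
#' @param cas9_pfams Domain names counted as Cas9-related.
#' @param min_domains Distinct-domain threshold used for the selection.
#' @return A list with `chosen` (bin label), `counts` (per-bin tibble with
#'   `n`, `n_ge3`, `n_ge4`, `n_ge5` and per-domain totals), and `records`
#'   (the records of the chosen bin with a `pfam_count` column).
#' @export
select_bin_by_pfam <- function(binned, cas9_pfams = cas9_pfam_domains(),
                               min_domains = 3L) {
  stopifnot(is.data.frame(binned),
            all(c("bin", "pfam_hits") %in% names(binned)))
  if (length(cas9_pfams) == 0) stop("`cas9_pfams` must be non-empty", call. = FALSE)
  if (nrow(binned) == 0) stop("no records to select a bin from", call. = FALSE)

  hits <- lapply(strsplit(ifelse(is.na(binned$pfam_hits), "", binned$pfam_hits),
                          ","),
                 function(h) unique(intersect(trimws(h), cas9_pfams)))
  binned$pfam_count <- lengths(hits)

  counts <- binned |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_ge3 = sum(.data$pfam_count >= 3),
      n_ge4 = sum(.data$pfam_count >= 4),
      n_ge5 = sum(.data$pfam_count >= 5),
      .groups = "drop"
    )
  for (dom in cas9_pfams) {
    counts[[dom]] <- vapply(levels(binned$bin), function(b) {
      sum(vapply(hits[binned$bin == b], function(h) dom %in% h, logical(1)))
    }, integer(1), USE.NAMES = FALSE)
  }
  key <- if (min_domains %in% 3:5) counts[[paste0("n_ge", min_domains)]] else
    vapply(levels(binned$bin), function(b) {
      sum(binned$pfam_count[binned$bin == b] >= min_domains)
    }, integer(1))
  if (max(key) == 0) {
    stop(sprintf("no bin contains records with >= %d Cas9-related domains",
                 min_domains), call. = FALSE)
  }
  best <- which(key == max(key))
  if (length(best) > 1) {
    warning("bin selection tie broken toward the longer-length bin",
            call. = FALSE)
    best <- max(best)
  }
  chosen <- as.character(counts$bin[best])
  list(chosen = chosen, counts = counts,
       records = binned[as.character(binned$bin) == chosen, , drop = FALSE])
}

#' Score candidates and apply the prediction-score filters
#'
#' Every candidate is scored (either with a trained model on the supplied
#' sequences, or using a precomputed `score` column); the returned threshold
#' table counts candidates with score strictly above `report_cutoff` and at
#' or above `keep_cutoff`. Survivors are those with `score >= keep_cutoff`.
#' Candidates that cannot be scored (bad residues or missing sequence) are
#' skipped with a warning.
#'
#' @param candidates A tibble of candidate records (`id`, ...; a `score`
#'   column if `model` is NULL).
#' @param model Optional trained `cas_classifier`.
#' @param seqs Sequences for the candidates (`id`, `residues`), required when
#'   `model` is supplied.
#' @param report_cutoff Reporting threshold (strict `>`).
#' @param keep_cutoff Survival threshold (`>=`).
#' @return A list with `scored` (all scored candidates), `survivors`, and
#'   `thresholds` (a tibble: cutoff, comparator, n).
#' @export
score_and_filter <- function(candidates, model = NULL, seqs = NULL,
                             report_cutoff = 0.5, keep_cutoff = 0.9) {
  stopifnot(is.data.frame(candidates))
  if (!is.null(model)) {
    if (is.null(seqs)) stop("`seqs` is required when `model` is given", call. = FALSE)
    sc <- predict(model, seqs)
    candidates$score <- sc$score[match(candidates$id, sc$id)]
  }
  if (!"score" %in% names(candidates)) {
    stop("`candidates` needs a `score` column when no model is supplied",
         call. = FALSE)
  }
  bad <- is.na(candidates$score)
  if (any(bad)) {
    warning(sprintf("skipping %d unscoreable candidate(s): %s", sum(bad),
                    paste(head(candidates$id[bad], 3), collapse = ", ")),
            call. = FALSE)
  }
  scored <- candidates[!bad, , drop = FALSE]
  thresholds <- tibble(
    cutoff = c(report_cutoff, keep_cutoff),
    comparator = c(">", ">="),
    n = c(sum(scored$score > report_cutoff),
          sum(scored$score >= keep_cutoff))
  )
  list(scored = scored,
       survivors = scored[scored$score >= keep_cutoff, , drop = FALSE],
       thresholds = thresholds)
}

#' Rank score survivors by CRISPR repeat support
#'
#' Records with no repeat information are excluded with a warning (a genome
#' with no detected repeats cannot support its candidate). Survivors with
#' `repeat_count > min_repeats` (strict) are ordered by model score
#' descending and assigned `final_rank` 1..n.
#'
#' @param survivors A tibble with `score` and `repeat_count` columns.
#' @param min_repeats Strict lower bound on the repeat count.
#' @return The ranked survivors with a `final_rank` column.
#' @export
rank_by_repeats <- function(survivors, min_repeats = 50L) {
  stopifnot(is.data.frame(survivors),
            all(c("score", "repeat_count") %in% names(survivors)))
  no_rep <- is.na(survivors$repeat_count)
  if (any(no_rep)) {
    warning(sprintf("excluding %d candidate(s) lacking repeat information: %s",
                    sum(no_rep),
                    paste(head(survivors$id[no_rep], 3), collapse = ", ")),
            call. = FALSE)
  }
  kept <- survivors[!no_rep & survivors$repeat_count > min_repeats &
                      !is.na(survivors$repeat_count), , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("no candidate passes the repeat filter", call. = FALSE)
    kept$final_rank <- integer(0)
    return(kept)
  }
  kept <- kept[order(-kept$score), , drop = FALSE]
  kept$final_rank <- seq_len(nrow(kept))
  kept
}

#' Run the full genome-mining cascade
#'
#' Length window -> 100-residue bins -> Pfam-count bin selection -> model
#' score thresholds -> CRISPR repeat ranking. Each stage's survivor set is a
#' subset of the previous stage's.
#'
#' @inheritParams bin_by_length
#' @inheritParams select_bin_by_pfam
#' @inheritParams score_and_filter
#' @inheritParams rank_by_repeats
#' @return A list with the per-stage artifacts (`binned`, `bin_counts`,
#'   `chosen_bin`, `thresholds`, `survivors`, `ranked`) and a `stages`
#'   tibble of survivor counts.
#' @export
mine_cascade <- function(records, model = NULL, seqs = NULL,
                         window = c(800L, 1600L), bin_width = 100L,
                         cas9_pfams = cas9_pfam_domains(), min_domains = 3L,
                         report_cutoff = 0.5, keep_cutoff = 0.9,
                         min_repeats = 50L) {
  binned <- bin_by_length(records, window, bin_width)
  sel <- select_bin_by_pfam(binned, cas9_pfams, min_domains)
  sf <- score_and_filter(sel$records, model, seqs, report_cutoff, keep_cutoff)
  ranked <- rank_by_repeats(sf$survivors, min_repeats)
  stages <- tibble(
    stage = c("input", "in_window", "chosen_bin", "score_report",
              "score_keep", "repeat_ranked"),
    n = c(nrow(records), nrow(binned), nrow(sel$records),
          sf$thresholds$n[1], nrow(sf$survivors), nrow(ranked))
  )
  list(binned = binned, bin_counts = sel$counts, chosen_bin = sel$chosen,
       thresholds = sf$thresholds, scored = sf$scored,
       survivors = sf$survivors, ranked = ranked, stages = stages)
}
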