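#' Per-residue Grad-CAM saliency ("fingerprint") for protein sequences
#'
#' For each sequence, the gradient of the positive-class logit with respect
#' to the last convolutional layer's activation map is averaged over
#' positions to give per-channel weights; the rectified weighted channel sum
#' is the class-activation map (CAM). The CAM is linearly interpolated from
#' conv-layer resolution back to residue resolution and min-max normalized to
#' `[0, 1]` (an all-zero CAM stays all-zero). Sequences longer than the
#' encoder capacity are scored on the truncated prefix with a warning.
#'
#' @param model A trained `cas_classifier`.
#' @param seqs A tibble with columns `id` and `residues`.
#' @return A tibble of class `cas_fingerprint` with columns `id`, `position`
#'   (1-based), `residue`, `saliency`; the per-sequence model scores are
#'   available via `attr(, "scores")`.
#' @export
compute_fingerprints <- function(model, seqs) {
  stopifnot(inherits(model, "cas_classifier"))
  check_seq_tbl(seqs, arg = "seqs")
  if (nrow(model$history) == 0) {
    stop("`model` is untrained; fit with epochs > 0 before computing fingerprints",
         call. = FALSE)
  }
  cfg <- cpp_config(model$config, model$spec)
  res <- purrr::map(seq_len(nrow(seqs)), function(i) {
    chars <- strsplit(seqs$residues[i], "")[[1]]
    if (length(chars) > model$spec$max_len) {
      warning(sprintf("sequence '%s' longer than max_len=%d; fingerprint computed on the prefix",
                      seqs$id[i], model$spec$max_len), call. = FALSE)
      chars <- chars[seq_len(model$spec$max_len)]
    }
    tokens <- match(chars, model$spec$alphabet)
    if (anyNA(tokens)) {
      stop(sprintf("record '%s' contains residue '%s' outside the encoder alphabet",
                   seqs$id[i], chars[which(is.na(tokens))[1]]), call. = FALSE)
    }
    gc <- cpp_gradcam(model$params, tokens, cfg)
    sal <- upsample_cam(gc$cam, length(chars), gc$stride)
    list(fp = tibble(id = seqs$id[i], position = seq_along(chars),
                     residue = chars, saliency = sal),
         score = tibble(id = seqs$id[i], score = gc$score))
  })
  out <- dplyr::bind_rows(purrr::map(res, "fp"))
  attr(out, "scores") <- dplyr::bind_rows(purrr::map(res, "score"))
  class(out) <- c("cas_fingerprint", class(out))
  out
}

# Linear interpolation from conv resolution (one value per `stride` residues)
# to residue resolution, then min-max normalization.
upsample_cam <- function(cam, L, stride) {
  if (length(cam) == 1) {
    sal <- rep(cam, L)
  } else {
    centers <- (seq_along(cam) - 1) * stride + (stride + 1) / 2
    sal <- approx(x = centers, y = cam, xout = seq_len(L), rule = 2)$y
  }
  lo <- min(sal)
  hi <- max(sal)
  if (hi == 0) return(rep(0, L))
  if (hi == lo) return(rep(1, L))
  (sal - lo) / (hi - lo)
}

#' Call saliency peaks on fingerprints
#'
#' A peak is a local maximum whose saliency exceeds `mean + z * sd` of the
#' sequence's saliency vector (flat vectors yield no peaks). Maxima closer
#' than `min_separation` residues are pruned, keeping the higher one.
#'
#' @param fps A `cas_fingerprint` tibble from [compute_fingerprints()].
#' @param z Threshold multiplier on the saliency standard deviation.
#' @param min_separation Minimum residue distance between retained peaks.
#' @return `fps` with a logical `is_peak` column.
#' @export
detect_peaks <- function(fps, z = 2, min_separation = 20L) {
  stopifnot(is.data.frame(fps),
            all(c("id", "position", "saliency") %in% names(fps)))
  out <- fps |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(is_peak = call_peaks_one(.data$saliency, z, min_separation)) |>
    dplyr::ungroup()
  class(out) <- unique(c("cas_fingerprint", class(out)))
  attr(out, "scores") <- attr(fps, "scores")
  out
}

call_peaks_one <- function(s, z, min_separation) {
  L <- length(s)
  is_peak <- rep(FALSE, L)
  if (L == 0) return(is_peak)
  threshold <- mean(s) + z * (if (L > 1) sd(s) else 0)
  left <- c(-Inf, s[-L])
  right <- c(s[-1], -Inf)
  cand <- which(s >= left & s >= right & s > threshold)
  if (length(cand) == 0) return(is_peak)
  # greedy non-maximum suppression, highest saliency first
  cand <- cand[order(-s[cand], cand)]
  kept <- integer()
  for (p in cand) {
    if (all(abs(kept - p) >= min_separation)) kept <- c(kept, p)
  }
  is_peak[kept] <- TRUE
  is_peak
}

#' Tabulate fingerprint peaks, optionally against annotated positions
#'
#' @param fps A `cas_fingerprint` tibble with an `is_peak` column (see
#'   [detect_peaks()]).
#' @param annotations Optional tibble with columns `id`, `position` and
#'   (optionally) `label`, e.g. known active-site residues. When supplied,
#'   the report gives the distance from each annotation to the nearest
#'   called peak of that sequence (`NA` when the sequence has no peaks).
#' @return A tibble: per-sequence peak positions, or per-annotation nearest
#'   peak distances when `annotations` is supplied.
#' @export
fingerprint_report <- function(fps, annotations = NULL) {
  stopifnot(is.data.frame(fps), "is_peak" %in% names(fps))
  peaks <- fps |>
    dplyr::filter(.data$is_peak) |>
    dplyr::select("id", peak = "position", "saliency") |>
    dplyr::arrange(.data$id, .data$peak)
  if (is.null(annotations)) return(peaks)
  stopifnot(all(c("id", "position") %in% names(annotations)))
  annotations |>
    as_tibble() |>
    dplyr::mutate(
      nearest_peak = purrr::map2_int(.data$id, .data$position, function(i, p) {
        pk <- peaks$peak[peaks$id == i]
        if (length(pk) == 0) NA_integer_ else pk[which.min(abs(pk - p))]
      }),
      distance = abs(.data$nearest_peak - .data$position)
    )
}

#' Fraction of top-saliency positions inside annotated spans
#'
#' For each sequence, takes the `top_frac` highest-saliency positions (ties
#' broken toward earlier positions) and reports the fraction falling inside
#' the given spans — used to quantify how well fingerprints localize planted
#' motifs or known functional sites.
#'
#' @param fps A `cas_fingerprint` tibble.
#' @param spans A tibble with columns `id`, `start`, `end` (1-based,
#'   inclusive).
#' @param top_frac Fraction of positions to take, per sequence.
#' @return A tibble with columns `id`, `n_top`, `n_inside`, `fraction`.
#' @export
saliency_enrichment <- function(fps, spans, top_frac = 0.05) {
  stopifnot(is.data.frame(fps), is.data.frame(spans),
            all(c("id", "start", "end") %in% names(spans)))
  fps |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      L <- nrow(df)
      n_top <- max(1L, ceiling(top_frac * L))
      ord <- order(-df$saliency, df$position)
      top_pos <- df$position[ord[seq_len(n_top)]]
      sp <- spans[spans$id == key$id, , drop = FALSE]
      inside <- vapply(top_pos, function(p) {
        any(p >= sp$start & p <= sp$end)
      }, logical(1))
      tibble(n_top = n_top, n_inside = sum(inside),
             fraction = mean(inside))
    }) |>
    dplyr::ungroup()
}

#' @export
autoplot.cas_fingerprint <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$saliency)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~id, ncol = 1) +
    ggplot2::labs(x = "residue position", y = "Grad-CAM saliency")
  if ("is_peak" %in% names(object)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(object, .data$is_peak),
      colour = "red", size = 1
    )
  }
  p
}
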