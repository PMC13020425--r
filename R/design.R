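#' Read a homolog multiple-sequence alignment from aligned FASTA
#'
#' All rows must have equal aligned length; the gap character is `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `aligned`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- tibble(id = sub("\\s.*$", "", names(set)),
                aligned = toupper(as.character(set)))
  validate_alignment(out)
  out
}

validate_alignment <- function(aln, ref_id = NULL) {
  stopifnot(is.data.frame(aln), all(c("id", "aligned") %in% names(aln)))
  if (nrow(aln) == 0) stop("alignment is empty", call. = FALSE)
  widths <- nchar(aln$aligned)
  if (length(unique(widths)) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  if (anyDuplicated(aln$id)) stop("duplicate ids in alignment", call. = FALSE)
  if (!is.null(ref_id) && !ref_id %in% aln$id) {
    stop(sprintf("reference '%s' not found in alignment", ref_id), call. = FALSE)
  }
  invisible(aln)
}

# Columns of the alignment where the reference is ungapped, in order; the
# i-th entry is the alignment column of reference position i.
alignment_column_map <- function(aln, ref_id) {
  validate_alignment(aln, ref_id)
  ref <- strsplit(aln$aligned[aln$id == ref_id], "")[[1]]
  which(ref != "-")
}

#' Position-specific amino-acid probability (PSAP) conservation matrix
#'
#' For each reference position, residue counts over the aligned column (gaps
#' and non-standard letters excluded) are converted to probabilities with a
#' pseudocount: `P[s, a] = (n_a + alpha) / (N + 20 * alpha)`. Columns where
#' the reference is gapped are skipped; columns with no observed standard
#' residues get a uniform row with a warning.
#'
#' @param aln An alignment tibble (`id`, `aligned`).
#' @param ref_id Id of the reference row; probabilities are indexed by its
#'   ungapped positions.
#' @param alpha Pseudocount (default 1).
#' @return A numeric matrix (reference positions x 20 standard residues) of
#'   class `cas_psap`; rows sum to 1.
#' @export
psap <- function(aln, ref_id, alpha = 1) {
  validate_alignment(aln, ref_id)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  cmap <- alignment_column_map(aln, ref_id)
  rows <- strsplit(aln$aligned, "")
  mat <- do.call(rbind, rows) # rows x columns
  P <- matrix(0, nrow = length(cmap), ncol = length(AA_STANDARD),
              dimnames = list(as.character(seq_along(cmap)), AA_STANDARD))
  empty <- character()
  for (s in seq_along(cmap)) {
    col <- mat[, cmap[s]]
    col <- col[col %in% AA_STANDARD]
    n <- length(col)
    if (n == 0 && alpha == 0) {
      empty <- c(empty, s)
      P[s, ] <- 1 / length(AA_STANDARD)
      next
    }
    counts <- tabulate(match(col, AA_STANDARD), nbins = length(AA_STANDARD))
    P[s, ] <- (counts + alpha) / (n + length(AA_STANDARD) * alpha)
    if (n == 0) empty <- c(empty, s)
  }
  if (length(empty) > 0) {
    warning(sprintf("%d alignment column(s) with no standard residues: uniform probabilities used",
                    length(empty)), call. = FALSE)
  }
  structure(P, class = c("cas_psap", class(P)),
            ref_id = ref_id, alpha = alpha)
}

#' @export
tidy.cas_psap <- function(x, ...) {
  tibble(
    site = rep(seq_len(nrow(x)), times = ncol(x)),
    residue = rep(colnames(x), each = nrow(x)),
    probability = as.vector(unclass(x))
  )
}

#' Model-derived characteristic matrix over a homolog family
#'
#' Computes the Grad-CAM fingerprint of every homolog on its ungapped
#' sequence, projects per-residue saliency into reference coordinates via
#' the alignment, and stratifies by residue identity: `C[s, a]` is the mean
#' saliency of homologs carrying residue `a` at the column aligned to
#' reference position `s`, defined where the support count `n[s, a]` reaches
#' `min_support`. Core sites are positions whose mean saliency across all
#' homologs exceeds the `core_quantile` percentile.
#'
#' @param model A trained `cas_classifier`.
#' @param aln An alignment tibble (`id`, `aligned`).
#' @param ref_id Id of the reference row.
#' @param min_support Minimum homolog count for `C[s, a]` to be defined.
#' @param core_quantile Quantile of mean saliency defining core sites.
#' @return An object of class `cas_charmat`: list with `C` (positions x 20,
#'   `NA` where unsupported), `n` (support counts), `mean_saliency`, `core`
#'   (logical per position), and the parameters used.
#' @export
characteristic_matrix <- function(model, aln, ref_id, min_support = 3L,
                                  core_quantile = 0.75) {
  stopifnot(inherits(model, "cas_classifier"))
  validate_alignment(aln, ref_id)
  cmap <- alignment_column_map(aln, ref_id)
  Lref <- length(cmap)
  naa <- length(AA_STANDARD)
  sal_sum <- matrix(0, Lref, naa, dimnames = list(NULL, AA_STANDARD))
  sal_n <- matrix(0L, Lref, naa, dimnames = list(NULL, AA_STANDARD))
  tot_sum <- numeric(Lref)
  tot_n <- integer(Lref)

  for (i in seq_len(nrow(aln))) {
    chars <- strsplit(aln$aligned[i], "")[[1]]
    ungapped <- chars[chars != "-"]
    seq_str <- paste(ungapped, collapse = "")
    if (!grepl(AA_REGEX, seq_str)) {
      warning(sprintf("skipping homolog '%s' with unscoreable residues",
                      aln$id[i]), call. = FALSE)
      next
    }
    fp <- compute_fingerprints(model,
                               tibble(id = aln$id[i], residues = seq_str))
    sal <- fp$saliency
    respos <- cumsum(chars != "-") # residue index at each alignment column
    colchars <- chars[cmap]
    nongap <- which(colchars != "-")
    v <- sal[respos[cmap[nongap]]]
    tot_sum[nongap] <- tot_sum[nongap] + v
    tot_n[nongap] <- tot_n[nongap] + 1L
    a <- match(colchars[nongap], AA_STANDARD)
    std <- !is.na(a)
    ij <- cbind(nongap[std], a[std])
    sal_sum[ij] <- sal_sum[ij] + v[std]
    sal_n[ij] <- sal_n[ij] + 1L
  }
  C <- sal_sum / sal_n
  C[sal_n < min_support] <- NA_real_
  mean_sal <- ifelse(tot_n > 0, tot_sum / tot_n, NA_real_)
  core <- !is.na(mean_sal) &
    mean_sal > quantile(mean_sal, core_quantile, na.rm = TRUE)
  structure(
    list(C = C, n = sal_n, mean_saliency = mean_sal, core = core,
         ref_id = ref_id, min_support = as.integer(min_support),
         core_quantile = core_quantile),
    class = "cas_charmat"
  )
}

#' @export
tidy.cas_charmat <- function(x, ...) {
  tibble(
    site = rep(seq_len(nrow(x$C)), times = ncol(x$C)),
    residue = rep(colnames(x$C), each = nrow(x$C)),
    value = as.vector(x$C),
    support = as.vector(x$n),
    core = rep(x$core, times = ncol(x$C))
  )
}

#' @export
print.cas_charmat <- function(x, ...) {
  cat(sprintf("<cas_charmat> %d reference positions, %d core sites (q=%.2f), min_support=%d\n",
              nrow(x$C), sum(x$core), x$core_quantile, x$min_support))
  invisible(x)
}

#' Rank candidate point mutations by combined Diff scores
#'
#' Candidates are all (core site, mutant residue) pairs where both the
#' mutant's and the wild-type's characteristic values are defined. Each gets
#' a characteristic Diff `C[s, mut] - C[s, wt]` and a conservation Diff
#' `P[s, mut] - P[s, wt]`; both Diff lists are ranked descending (ties share
#' the minimum rank) and the total ranking score is the sum of the two
#' ranks. Candidates with total rank strictly below `total_cutoff` are
#' returned, sorted by total rank, then site, then mutant residue.
#'
#' @param charmat A `cas_charmat` from [characteristic_matrix()].
#' @param psap_mat A `cas_psap` from [psap()] on the same reference.
#' @param ref The reference sequence: a single residue string or a one-row
#'   tibble with a `residues` column.
#' @param total_cutoff Strict upper bound on the total ranking score.
#' @return A tibble of class `cas_mutations` with columns `site`, `wt`,
#'   `mut`, `diff_char`, `diff_cons`, `rank_char`, `rank_cons`,
#'   `total_rank`, `notation` ("wtPOSmut").
#' @export
rank_mutations <- function(charmat, psap_mat, ref, total_cutoff = 30L) {
  stopifnot(inherits(charmat, "cas_charmat"), inherits(psap_mat, "cas_psap"))
  if (is.data.frame(ref)) ref <- ref$residues[1]
  wt <- strsplit(ref, "")[[1]]
  if (length(wt) != nrow(charmat$C) || length(wt) != nrow(psap_mat)) {
    stop("`charmat`, `psap_mat` and `ref` must share reference coordinates",
         call. = FALSE)
  }
  cand <- list()
  for (s in which(charmat$core)) {
    w <- wt[s]
    if (!w %in% AA_STANDARD || is.na(charmat$C[s, w])) next
    for (a in AA_STANDARD) {
      if (a == w || is.na(charmat$C[s, a])) next
      cand[[length(cand) + 1]] <- tibble(
        site = s, wt = w, mut = a,
        diff_char = unname(charmat$C[s, a] - charmat$C[s, w]),
        diff_cons = unname(psap_mat[s, a] - psap_mat[s, w])
      )
    }
  }
  if (length(cand) == 0) {
    warning("no mutation candidates (no supported core-site substitutions)",
            call. = FALSE)
    out <- tibble(site = integer(), wt = character(), mut = character(),
                  diff_char = numeric(), diff_cons = numeric(),
                  rank_char = integer(), rank_cons = integer(),
                  total_rank = integer(), notation = character())
    class(out) <- c("cas_mutations", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(cand)
  out$rank_char <- rank(-out$diff_char, ties.method = "min")
  out$rank_cons <- rank(-out$diff_cons, ties.method = "min")
  out$total_rank <- out$rank_char + out$rank_cons
  out$notation <- sprintf("%s%d%s", out$wt, out$site, out$mut)
  out <- out[out$total_rank < total_cutoff, , drop = FALSE]
  out <- out[order(out$total_rank, out$site, out$mut), , drop = FALSE]
  class(out) <- c("cas_mutations", class(out))
  out
}

#' Write a mutation-design report
#'
#' @param candidates A `cas_mutations` tibble from [rank_mutations()].
#' @param path Output TSV path; an empty candidate set writes a header-only
#'   file.
#' @return `candidates`, invisibly.
#' @export
report_designs <- function(candidates, path) {
  stopifnot(is.data.frame(candidates))
  cols <- c("site", "wt", "mut", "diff_char", "diff_cons",
            "rank_char", "rank_cons", "total_rank", "notation")
  readr::write_tsv(as_tibble(candidates)[, cols], path)
  invisible(candidates)
}
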