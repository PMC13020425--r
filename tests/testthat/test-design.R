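mini_aln <- function(rows, ids = paste0("h", seq_along(rows))) {
  tibble::tibble(id = ids, aligned = rows)
}

test_that("PSAP columns match hand-computed probabilities", {
  # unanimity, no pseudocount
  a1 <- mini_aln(c("A", "A"))
  p1 <- psap(a1, "h1", alpha = 0)
  expect_equal(unname(p1[1, "A"]), 1.0)
  expect_equal(sum(p1[1, ] > 0), 1)

  # even split
  a2 <- mini_aln(c("A", "C"))
  p2 <- psap(a2, "h1", alpha = 0)
  expect_equal(unname(p2[1, c("A", "C")]), c(0.5, 0.5))

  # pseudocount: (3 + 1) / (3 + 20)
  a3 <- mini_aln(c("A", "A", "A"))
  p3 <- psap(a3, "h1", alpha = 1)
  expect_equal(unname(p3[1, "A"]), 4 / 23)
  expect_equal(unname(p3[1, "C"]), 1 / 23)
})

test_that("PSAP rows sum to one and ignore row order", {
  rows <- withr::with_seed(4, vapply(1:12, function(i) {
    paste(sample(aa_standard(), 30, replace = TRUE), collapse = "")
  }, character(1)))
  aln <- mini_aln(rows)
  P <- psap(aln, "h1")
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  perm <- c(1, 7, 3, 12, 5, 6, 2, 8, 9, 10, 11, 4) # reference row kept
  P2 <- psap(aln[perm, ], "h1")
  expect_equal(unclass(P), unclass(P2), ignore_attr = TRUE)
})

test_that("gap handling: reference gaps drop columns, all-gap columns warn", {
  aln <- mini_aln(c("AC-DE", "AC-DE", "A--DE"), c("ref", "h1", "h2"))
  P <- psap(aln, "ref", alpha = 0)
  expect_equal(nrow(P), 4) # reference has 4 ungapped positions
  expect_equal(unname(P[2, "C"]), 1.0) # gap in h2 excluded from the column

  aln2 <- mini_aln(c("AX", "AX"), c("ref", "h1")) # X never counted
  expect_warning(P2 <- psap(aln2, "ref", alpha = 1), "uniform")
  expect_equal(unname(P2[2, "A"]), 1 / 20)
})

test_that("PSAP recovers forced conservation and forced variability", {
  # one column forced highly conserved (substitution rate /10), the rest
  # substituted at a rate high enough to dilute the wild type below half
  ref <- withr::with_seed(5, paste(sample(aa_standard(), 40, replace = TRUE),
                                   collapse = ""))
  aln <- make_homolog_family(ref, n = 500, sub_rate = 0.55, conserved = 7L,
                             seed = 1)
  P <- psap(aln, "ref", alpha = 1)
  expect_gte(max(P[7, ]), 0.9)
  expect_lte(max(P[20, ]), 0.5)
})

test_that("conservation differences are antisymmetric", {
  rows <- withr::with_seed(6, vapply(1:20, function(i) {
    paste(sample(aa_standard(), 15, replace = TRUE), collapse = "")
  }, character(1)))
  P <- psap(mini_aln(rows), "h1")
  for (s in c(1, 8, 15)) {
    expect_equal(P[s, "A"] - P[s, "W"], -(P[s, "W"] - P[s, "A"]))
  }
})

test_that("the characteristic matrix stratifies homolog saliency by residue", {
  model <- cf_tiny_model()
  pos <- cf_tiny_positives()
  ref <- pos[1, ]
  # identical copies: C[s, wt] must equal the reference saliency everywhere
  aln <- make_homolog_family(ref, n = 4, sub_rate = 0, seed = 2)
  cm <- characteristic_matrix(model, aln, ref_id = ref$id, min_support = 2)
  fp <- compute_fingerprints(model, ref)
  wt <- strsplit(ref$residues, "")[[1]]
  idx <- cbind(seq_along(wt), match(wt, aa_standard()))
  expect_equal(unname(cm$C[idx]), fp$saliency, tolerance = 1e-12)
  expect_equal(unname(cm$n[idx]), rep(5L, length(wt)))
  # unsupported (never observed) substitutions stay undefined
  expect_true(anyNA(cm$C))
  # support below min_support is masked
  cm5 <- characteristic_matrix(model, aln, ref_id = ref$id, min_support = 6)
  expect_true(all(is.na(cm5$C)))
  # core sites: top quartile of mean saliency
  expect_equal(sum(cm$core), sum(cm$mean_saliency >
                                   quantile(cm$mean_saliency, 0.75)))
})

test_that("mean of two homolog saliencies lands in the matrix cell", {
  model <- cf_tiny_model()
  pos <- cf_tiny_positives()
  ref <- pos[1, ]
  aln <- make_homolog_family(ref, n = 30, sub_rate = 0.15, seed = 3)
  cm <- characteristic_matrix(model, aln, ref_id = ref$id, min_support = 2)
  # recompute one supported cell by brute force
  fps <- compute_fingerprints(model,
                              tibble::tibble(id = aln$id,
                                             residues = aln$aligned))
  chars <- strsplit(aln$aligned, "")
  s <- which(cm$n[, "A"] >= 2)[1]
  skip_if(is.na(s))
  vals <- vapply(seq_len(nrow(aln)), function(i) {
    if (chars[[i]][s] == "A") fps$saliency[fps$id == aln$id[i]][s] else NA_real_
  }, numeric(1))
  expect_equal(unname(cm$C[s, "A"]), mean(vals, na.rm = TRUE), tolerance = 1e-12)
})

manual_charmat <- function(C, core) {
  structure(list(C = C, n = matrix(99L, nrow(C), ncol(C), dimnames = dimnames(C)),
                 mean_saliency = rowMeans(C, na.rm = TRUE), core = core,
                 ref_id = "ref", min_support = 1L, core_quantile = 0.75),
            class = "cas_charmat")
}
manual_psap <- function(P) {
  structure(P / rowSums(P), class = c("cas_psap", class(P)),
            ref_id = "ref", alpha = 1)
}

test_that("mutation ranking reproduces an exhaustive brute-force oracle", {
  naa <- length(aa_standard())
  for (case in 1:5) {
    L <- 8
    withr::with_seed(100 + case, {
      C <- matrix(stats::runif(L * naa), L, naa,
                  dimnames = list(NULL, aa_standard()))
      C[sample(length(C), 40)] <- NA
      P <- matrix(stats::rgamma(L * naa, 1), L, naa,
                  dimnames = list(NULL, aa_standard()))
      core <- stats::runif(L) > 0.3
      ref <- paste(sample(aa_standard(), L, replace = TRUE), collapse = "")
    })
    cm <- manual_charmat(C, core)
    pm <- manual_psap(P)
    cutoff <- 30L
    got <- suppressWarnings(rank_mutations(cm, pm, ref, cutoff))

    # oracle: enumerate every candidate, rank by counting larger Diffs
    wt <- strsplit(ref, "")[[1]]
    cand <- NULL
    for (s in which(core)) {
      if (is.na(C[s, wt[s]])) next
      for (a in setdiff(aa_standard(), wt[s])) {
        if (is.na(C[s, a])) next
        cand <- rbind(cand, data.frame(
          site = s, wt = wt[s], mut = a,
          diff_char = C[s, a] - C[s, wt[s]],
          diff_cons = pm[s, a] - pm[s, wt[s]]
        ))
      }
    }
    if (is.null(cand) || nrow(cand) == 0) {
      expect_equal(nrow(got), 0)
      next
    }
    cand$total <- cf_rank_brute(cand$diff_char) + cf_rank_brute(cand$diff_cons)
    keep <- cand[cand$total < cutoff, ]
    keep <- keep[order(keep$total, keep$site, keep$mut), ]
    expect_equal(got$site, keep$site)
    expect_equal(got$mut, keep$mut)
    expect_equal(got$total_rank, keep$total)
    expect_equal(got$diff_char, keep$diff_char, tolerance = 1e-12)
  }
})

test_that("the double-first candidate always survives and the cutoff is strict", {
  C <- matrix(0.5, 2, 20, dimnames = list(NULL, aa_standard()))
  C[1, "C"] <- 0.9 # best characteristic jump at site 1: A -> C
  P <- matrix(1, 2, 20, dimnames = list(NULL, aa_standard()))
  P[1, "C"] <- 5   # best conservation jump too
  cm <- manual_charmat(C, core = c(TRUE, TRUE))
  pm <- manual_psap(P)
  got <- rank_mutations(cm, pm, "AA", total_cutoff = 3)
  expect_equal(got$notation[1], "A1C")
  expect_equal(got$total_rank[1], 2)
  # everything else ties at rank 2 in both lists -> total 4, cut at 3
  expect_equal(nrow(got), 1)
})

test_that("design reports render notation and survive empty input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  cand <- tibble::tibble(site = 623L, wt = "V", mut = "I",
                         diff_char = 0.1, diff_cons = 0.2,
                         rank_char = 1L, rank_cons = 2L, total_rank = 3L,
                         notation = "V623I")
  report_designs(cand, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$notation, "V623I")

  empty <- cand[0, ]
  report_designs(empty, f)
  back2 <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back2), 0)
  expect_true(all(c("site", "wt", "mut", "total_rank") %in% names(back2)))
})

test_that("alignments must be rectangular with a known reference", {
  expect_error(validate_alignment <- read_alignment(tempfile()), "")
  aln <- mini_aln(c("ACD", "AC"))
  expect_error(psap(aln, "h1"), "unequal")
  expect_error(psap(mini_aln("ACD"), "nope"), "not found")
})
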