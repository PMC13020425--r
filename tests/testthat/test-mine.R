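toy_records <- function() {
  tibble::tibble(
    id = paste0("r", 1:6),
    length = c(799L, 800L, 1301L, 1355L, 1600L, 1601L),
    pfam_hits = c("", "RuvC_III", "RuvC_III,Cas9_BH,Cas9_REC",
                  "RuvC_III,Cas9_BH,Cas9_REC,HNH_4",
                  "HNH_4", ""),
    repeat_count = c(NA, 3L, 60L, 55L, 1L, NA),
    score = c(0.99, 0.2, 0.95, 0.97, 0.3, 0.99)
  )
}

test_that("length binning partitions the window into labeled bins", {
  binned <- bin_by_length(toy_records())
  expect_equal(nrow(binned), 4) # 799 and 1601 dropped
  expect_equal(length(levels(binned$bin)), 8)
  expect_equal(as.character(binned$bin[binned$id == "r3"]), "1301-1400")
  expect_equal(as.character(binned$bin[binned$id == "r5"]), "1501-1600")
  expect_equal(as.character(binned$bin[binned$id == "r2"]), "801-900")
  # partition: every in-window record in exactly one bin
  expect_equal(sum(table(binned$bin)), nrow(binned))
  expect_error(bin_by_length(toy_records(), bin_width = 0), "bin_width")
})

test_that("bin selection maximizes multi-domain counts with documented ties", {
  recs <- tibble::tibble(
    id = paste0("x", 1:9),
    length = c(810L, 910L, 915L, 1310L, 1315L, 1320L, 1325L, 1330L, 1510L),
    pfam_hits = c(
      "RuvC_III,Cas9_BH,Cas9_REC",                       # bin 801-900: one >=3
      "RuvC_III", "Cas9_BH",                             # bin 901-1000: none
      "RuvC_III,Cas9_BH,Cas9_REC,HNH_4,Cas9_PI",         # target bin
      "RuvC_III,Cas9_BH,Cas9_REC,HNH_4",
      "RuvC_III,Cas9_BH,Cas9_REC",
      "RuvC_III,Cas9_BH,Cas9_REC",
      "RuvC_III,RuvC_III,Cas9_BH",                       # duplicates count once
      "HNH_4,Cas9_PI"
    ),
    repeat_count = NA_integer_, score = 0.5
  )
  sel <- select_bin_by_pfam(bin_by_length(recs))
  expect_equal(sel$chosen, "1301-1400")
  counts <- sel$counts
  target <- counts[counts$bin == "1301-1400", ]
  expect_equal(target$n_ge3, 4)
  expect_equal(target$n_ge4, 2)
  expect_equal(target$n_ge5, 1)
  expect_equal(target$RuvC_III, 5)
  expect_equal(target$Cas9_PI, 1)
  expect_equal(sel$records$pfam_count[sel$records$id == "x8"], 2)

  # all-zero hits: selection impossible
  none <- dplyr::mutate(recs, pfam_hits = "")
  expect_error(select_bin_by_pfam(bin_by_length(none)), ">= 3")

  # tie goes to the longer-length bin with a warning
  tied <- recs[c(1, 4), ]
  expect_warning(sel2 <- select_bin_by_pfam(bin_by_length(tied)), "tie")
  expect_equal(sel2$chosen, "1301-1400")
})

test_that("score filters use a strict report cutoff and inclusive keep cutoff", {
  cand <- tibble::tibble(id = paste0("c", 1:5),
                         score = c(0.4, 0.6, 0.95, 0.5, 0.9))
  sf <- score_and_filter(cand)
  # strictly above 0.5: 0.6, 0.95, 0.9 (the 0.5 record itself is excluded)
  expect_equal(sf$thresholds$n[sf$thresholds$comparator == ">"], 3)
  expect_equal(sf$thresholds$n[sf$thresholds$comparator == ">="], 2) # 0.95, 0.90
  expect_equal(sort(sf$survivors$id), c("c3", "c5"))

  minimal <- tibble::tibble(id = paste0("t", 1:3), score = c(0.4, 0.6, 0.95))
  sfm <- score_and_filter(minimal)
  expect_equal(sfm$thresholds$n, c(2L, 1L))
  allzero <- tibble::tibble(id = "z", score = 0)
  sfz <- score_and_filter(allzero)
  expect_equal(sfz$thresholds$n, c(0L, 0L))
  expect_equal(nrow(sfz$survivors), 0)

  withna <- tibble::tibble(id = c("a", "b"), score = c(NA, 0.95))
  expect_warning(sfn <- score_and_filter(withna), "unscoreable")
  expect_equal(sfn$survivors$id, "b")

  expect_error(score_and_filter(tibble::tibble(id = "a")), "score")
})

test_that("repeat ranking is strict at the threshold and ordered by score", {
  surv <- tibble::tibble(
    id = paste0("s", 1:5),
    score = c(0.99, 0.96, 0.95, 0.93, 0.92),
    repeat_count = c(NA, 56L, 49L, 51L, 50L)
  )
  expect_warning(ranked <- rank_by_repeats(surv), "repeat information")
  # strict > 50: keeps 56 and 51 only; NA excluded
  expect_equal(ranked$id, c("s2", "s4"))
  expect_equal(ranked$final_rank, 1:2)
  # the 56-repeat candidate had the second-highest overall score yet ranks
  # first once the repeat-less top scorer is excluded
  expect_equal(ranked$repeat_count[ranked$final_rank == 1], 56L)

  none <- tibble::tibble(id = "a", score = 0.95, repeat_count = 10L)
  expect_warning(out <- rank_by_repeats(none), "no candidate")
  expect_equal(nrow(out), 0)
})

test_that("the full cascade reproduces the hand enumeration on the preset table", {
  tab <- make_mining_table(mining_table_preset(), seed = 5)
  res <- suppressWarnings(mine_cascade(tab))
  expect_equal(res$chosen_bin, "1301-1400")
  expect_equal(res$stages$n,
               c(input = 35, in_window = 33, chosen_bin = 12,
                 score_report = 9, score_keep = 6, repeat_ranked = 3),
               ignore_attr = TRUE)
  # survivors of each stage are nested
  expect_true(all(res$survivors$id %in% res$scored$id))
  expect_true(all(res$ranked$id %in% res$survivors$id))
  # final ranking: 56-repeat candidate first (score 0.96), then 60 (0.95),
  # then 51 (0.93)
  expect_equal(res$ranked$repeat_count, c(56L, 60L, 51L))
  expect_equal(res$ranked$score, c(0.96, 0.95, 0.93))
  expect_equal(res$ranked$final_rank, 1:3)
})

test_that("annotation tables round-trip through TSV", {
  tab <- make_mining_table(mining_table_preset(), seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, f)
  back <- read_annotations(f)
  expect_equal(back$id, tab$id)
  expect_equal(back$repeat_count, tab$repeat_count)
  expect_equal(back$pfam_hits, ifelse(is.na(tab$pfam_hits) | tab$pfam_hits == "",
                                      "", tab$pfam_hits))
})
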