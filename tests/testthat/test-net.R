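test_that("encoding pads, truncates, and indexes the alphabet", {
  spec <- encoder_spec(max_len = 5)
  enc <- encode_sequences(tibble::tibble(id = "s", residues = "ACD"), spec)
  expect_equal(enc$tokens[1, ], c(1L, 2L, 3L, spec$pad_index, spec$pad_index))
  expect_equal(enc$lengths, 3L)

  exact <- encode_sequences(tibble::tibble(id = "s", residues = "ACDEF"), spec)
  expect_equal(exact$lengths, 5L)
  expect_false(any(exact$tokens == spec$pad_index))

  expect_warning(
    tr <- encode_sequences(tibble::tibble(id = "long", residues = "ACDEFGH"),
                           spec),
    "truncated"
  )
  expect_equal(tr$lengths, 5L)
  expect_equal(tr$tokens[1, ], c(1L, 2L, 3L, 4L, 5L))

  expect_error(encode_sequences(tibble::tibble(id = "bad", residues = "AJD"),
                                spec),
               "'J'")
})

test_that("splits are stratified, disjoint, exhaustive and seeded", {
  ds <- dplyr::bind_rows(
    label_sequences(make_positive_set(100, c(30, 40), motifs = character(),
                                      seed = 1), 1),
    label_sequences(
      dplyr::mutate(make_positive_set(100, c(30, 40), motifs = character(),
                                      seed = 2),
                    id = paste0(id, "_n"))[, c("id", "residues")], 0)
  )
  sp <- split_train_test(ds, 0.8, seed = 4)
  expect_equal(table(sp$train$label), table(c(rep(0, 80), rep(1, 80))))
  expect_equal(table(sp$test$label), table(c(rep(0, 20), rep(1, 20))))
  expect_equal(sort(c(sp$train$id, sp$test$id)), sort(ds$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- split_train_test(ds, 0.8, seed = 4)
  expect_identical(sp, sp2)

  half <- split_train_test(ds[c(1:10, 101:110), ], 0.5, seed = 1)
  expect_equal(nrow(half$train), 10)
  expect_equal(sum(half$train$label), 5)

  expect_error(split_train_test(ds[c(1, 101:105), ], 0.8, 1), "at least 2")
})

test_that("the classifier learns the planted-motif problem", {
  m <- cf_tiny_model()
  expect_gte(m$eval$test_accuracy, 0.8)
  expect_gte(m$eval$auc, 0.9)
  expect_equal(nrow(m$history), 10)
  expect_true(all(is.finite(m$history$loss)))
  g <- glance(m)
  expect_true(all(c("train_accuracy", "test_accuracy", "auc", "n_train") %in%
                    names(g)))
  expect_equal(g$tp + g$fp + g$tn + g$fn, m$n_test)
})

test_that("training and scoring are reproducible given the seeds", {
  pos <- cf_tiny_positives()
  neg <- build_negative_dataset(pos, 1.0, seed = 302)
  cfg <- model_config(epochs = 2L, batch_size = 16L, split_seed = 31L,
                      init_seed = 32L)
  spec <- encoder_spec(max_len = 140L)
  m1 <- train_classifier(pos, neg, cfg, spec)
  m2 <- train_classifier(pos, neg, cfg, spec)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, pos), predict(m2, pos))
})

test_that("an untrained model scores at chance on balanced data", {
  pos <- cf_tiny_positives()
  neg <- build_negative_dataset(pos, 1.0, seed = 302)
  m0 <- suppressWarnings(
    train_classifier(pos, neg,
                     model_config(epochs = 0L, split_seed = 31L,
                                  init_seed = 32L),
                     encoder_spec(max_len = 140L))
  )
  expect_lt(abs(m0$eval$test_accuracy - 0.5), 0.1)
})

test_that("prediction preserves order, handles duplicates and skips bad rows", {
  m <- cf_tiny_model()
  pos <- cf_tiny_positives()
  twice <- dplyr::bind_rows(
    pos[1:2, c("id", "residues")],
    dplyr::mutate(pos[1:2, c("id", "residues")], id = paste0(id, "_dup"))
  )
  sc <- predict(m, twice)
  expect_equal(sc$id, twice$id)
  expect_equal(sc$score[1:2], sc$score[3:4])
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  expect_equal(nrow(predict(m, pos[0, ])), 0)

  mixed <- tibble::tibble(id = c("ok", "bad"),
                          residues = c(pos$residues[1], "ACDJ"))
  expect_warning(scm <- predict(m, mixed), "skipping")
  expect_false(is.na(scm$score[1]))
  expect_true(is.na(scm$score[2]))
})

test_that("positives score higher than their shuffled negatives", {
  m <- cf_tiny_model()
  pos <- cf_tiny_positives()
  neg <- build_negative_dataset(pos, 1.0, seed = 302)
  sp <- predict(m, pos)$score
  sn <- predict(m, neg)$score
  expect_gt(mean(sp), mean(sn))
})

test_that("a saved model reloads with identical behaviour", {
  m <- cf_tiny_model()
  pos <- cf_tiny_positives()
  dir <- withr::local_tempdir()
  save_classifier(m, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  m2 <- load_classifier(dir)
  expect_identical(predict(m, pos), predict(m2, pos))
  expect_equal(m2$config$conv_filters, m$config$conv_filters)
})

test_that("model configuration rejects invalid shapes", {
  expect_error(model_config(conv_filters = integer()), "at least one")
  expect_error(model_config(conv_kernel = c(6L, 7L)), "odd")
  expect_error(model_config(conv_kernel = 7L), "equal length")
  expect_error(model_config(train_fraction = 1.2), "train_fraction")
  expect_error(model_config(epochs = -1L), "epochs")
})
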