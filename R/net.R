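#' Encoder specification
#'
#' Maps residues to integer tokens for the network. The alphabet is the 20
#' standard amino acids plus X, B, Z, U, O, with a distinct PAD token used to
#' right-pad sequences to `max_len`. The default capacity of 1820 residues
#' accommodates the longest Cas9-like positives handled by the package.
#'
#' @param max_len Maximum residue capacity (longer sequences are truncated
#'   with a warning at encoding time).
#' @return An object of class `cf_encoder_spec`.
#' @export
encoder_spec <- function(max_len = 1820L) {
  if (max_len < 1) stop("`max_len` must be >= 1", call. = FALSE)
  structure(
    list(alphabet = AA_EXTENDED,
         pad_index = length(AA_EXTENDED) + 1L,
         vocab = length(AA_EXTENDED) + 1L,
         max_len = as.integer(max_len)),
    class = "cf_encoder_spec"
  )
}

#' Encode sequences as padded token-index matrices
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @param spec An [encoder_spec()].
#' @return A list with `tokens` (integer matrix, one row per record, PAD
#'   filled), `lengths` (residue counts clamped to `max_len`), and `ids`.
#' @export
encode_sequences <- function(seqs, spec = encoder_spec()) {
  check_seq_tbl(seqs, arg = "seqs")
  stopifnot(inherits(spec, "cf_encoder_spec"))
  n <- nrow(seqs)
  tokens <- matrix(spec$pad_index, nrow = n, ncol = spec$max_len)
  lens <- integer(n)
  too_long <- character()
  for (i in seq_len(n)) {
    chars <- strsplit(seqs$residues[i], "")[[1]]
    idx <- match(chars, spec$alphabet)
    if (anyNA(idx)) {
      stop(sprintf("record '%s' contains residue '%s' outside the encoder alphabet",
                   seqs$id[i], chars[which(is.na(idx))[1]]), call. = FALSE)
    }
    if (length(idx) > spec$max_len) {
      too_long <- c(too_long, seqs$id[i])
      idx <- idx[seq_len(spec$max_len)]
    }
    lens[i] <- length(idx)
    tokens[i, seq_along(idx)] <- idx
  }
  if (length(too_long) > 0) {
    warning(sprintf("%d sequence(s) longer than max_len=%d truncated: %s",
                    length(too_long), spec$max_len,
                    paste(head(too_long, 3), collapse = ", ")), call. = FALSE)
  }
  list(tokens = tokens, lengths = lens, ids = seqs$id)
}

#' Model configuration for the CNN-LSTM classifier
#'
#' Defaults are sized for single-CPU training: a 16-wide token embedding, two
#' 1-D convolution blocks (32 filters each, kernels 7 then 3) with max-pool
#' widths 2 then 8, a 32-unit LSTM whose time-averaged hidden state feeds a
#' 16-unit ReLU dense layer and a sigmoid output. The narrow second kernel
#' keeps the receptive field of the Grad-CAM target layer close to motif
#' scale, and the first pool width of 2 keeps that layer at half-residue
#' resolution; the combined pooling of 16 keeps the LSTM input short. All
#' numbers are overridable.
#'
#' @param embedding Embedding width.
#' @param conv_filters,conv_kernel,conv_pool Integer vectors, one entry per
#'   conv block (at least one block; kernels must be odd).
#' @param lstm_units,dense_units Recurrent and dense widths.
#' @param lstm_readout How the LSTM hidden states become the dense-layer
#'   input: `"mean"` (time average, the default: every sequence region
#'   contributes to the readout, which keeps Grad-CAM attribution balanced
#'   along the sequence), `"mean_max"` (concatenated time average and
#'   per-unit maximum), `"sum"`, `"max"`, or `"final"` (last hidden
#'   state).
#' @param dropout Dropout rate on the dense layer during training.
#' @param weight_decay Decoupled (AdamW-style) L2 decay applied to weight
#'   matrices each optimizer step; keeps convolutional filters focused on
#'   discriminative motifs, which sharpens Grad-CAM maps.
#' @param learning_rate,batch_size,epochs Adam training hyperparameters.
#' @param train_fraction Fraction of records in the training split.
#' @param split_seed,init_seed Seeds for the train/test split and for
#'   parameter initialization / minibatch order.
#' @param restarts Maximum number of deterministic re-initializations (with
#'   derived seeds) when training stalls at chance accuracy.
#' @return An object of class `cf_model_config`.
#' @export
model_config <- function(embedding = 16L,
                         conv_filters = c(32L, 32L),
                         conv_kernel = c(7L, 3L),
                         conv_pool = c(2L, 8L),
                         lstm_units = 32L,
                         dense_units = 16L,
                         lstm_readout = c("mean", "mean_max", "sum", "max", "final"),
                         dropout = 0,
                         weight_decay = 1e-4,
                         learning_rate = 2e-3,
                         batch_size = 32L,
                         epochs = 40L,
                         train_fraction = 0.8,
                         split_seed = 1L,
                         init_seed = 1L,
                         restarts = 3L) {
  nb <- length(conv_filters)
  if (nb < 1) stop("at least one conv block is required", call. = FALSE)
  if (length(conv_kernel) != nb || length(conv_pool) != nb) {
    stop("`conv_filters`, `conv_kernel`, `conv_pool` must have equal length",
         call. = FALSE)
  }
  if (any(c(embedding, conv_filters, conv_pool, lstm_units, dense_units) < 1)) {
    stop("all layer widths must be positive", call. = FALSE)
  }
  if (any(conv_kernel %% 2 == 0)) {
    stop("conv kernel widths must be odd", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  lstm_readout <- match.arg(lstm_readout)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (weight_decay < 0) stop("`weight_decay` must be >= 0", call. = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  structure(
    list(embedding = as.integer(embedding),
         conv_filters = as.integer(conv_filters),
         conv_kernel = as.integer(conv_kernel),
         conv_pool = as.integer(conv_pool),
         lstm_units = as.integer(lstm_units),
         dense_units = as.integer(dense_units),
         lstm_readout = lstm_readout,
         dropout = dropout,
         weight_decay = weight_decay,
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         train_fraction = train_fraction,
         split_seed = as.integer(split_seed),
         init_seed = as.integer(init_seed),
         restarts = as.integer(restarts)),
    class = "cf_model_config"
  )
}

cpp_config <- function(config, spec) {
  list(vocab = spec$vocab, embedding = config$embedding,
       conv_filters = config$conv_filters, conv_kernel = config$conv_kernel,
       conv_pool = config$conv_pool, lstm_units = config$lstm_units,
       lstm_readout = config$lstm_readout,
       dense_units = config$dense_units, learning_rate = config$learning_rate,
       dropout = config$dropout, weight_decay = config$weight_decay,
       batch_size = config$batch_size,
       epochs = config$epochs, pad_index = spec$pad_index)
}

#' Stratified train/test split
#'
#' @param dataset A labeled sequence tibble (`id`, `residues`, `label`).
#' @param train_fraction Fraction of each class assigned to the training set.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return A list with tibbles `train` and `test` (disjoint, union = input).
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  check_seq_tbl(dataset, require_label = TRUE, arg = "dataset")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  counts <- table(factor(dataset$label, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop("each class needs at least 2 records to split", call. = FALSE)
  }
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(c(0, 1), function(lb) {
      idx <- which(dataset$label == lb)
      sample(idx, round(train_fraction * length(idx)))
    }))
  })
  list(train = dataset[sort(train_idx), , drop = FALSE],
       test = dataset[sort(setdiff(seq_len(nrow(dataset)), train_idx)), ,
                      drop = FALSE])
}

#' Train the CNN-LSTM Cas9 classifier
#'
#' Combines positives and negatives, makes a stratified train/test split,
#' trains with binary cross-entropy and Adam, and evaluates on the held-out
#' test split at the 0.5 cutoff. All randomness is seeded through the config.
#'
#' @param positives,negatives Sequence tibbles (`id`, `residues`); a `label`
#'   column, if absent, is added as 1 and 0 respectively.
#' @param config A [model_config()].
#' @param spec An [encoder_spec()].
#' @return An object of class `cas_classifier` with elements `params`,
#'   `config`, `spec`, `history` (per-epoch loss/accuracy tibble) and `eval`
#'   (a one-row metrics tibble, see [evaluate_scores()], plus
#'   `train_accuracy`).
#' @export
train_classifier <- function(positives, negatives, config = model_config(),
                             spec = encoder_spec()) {
  stopifnot(inherits(config, "cf_model_config"), inherits(spec, "cf_encoder_spec"))
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    stop("both `positives` and `negatives` must be non-empty", call. = FALSE)
  }
  if (!"label" %in% names(positives)) positives <- label_sequences(positives, 1)
  if (!"label" %in% names(negatives)) negatives <- label_sequences(negatives, 0)
  dataset <- dplyr::bind_rows(positives, negatives)
  check_seq_tbl(dataset, require_label = TRUE, arg = "positives+negatives")

  split <- split_train_test(dataset, config$train_fraction, config$split_seed)
  enc_train <- encode_sequences(split$train, spec)

  if (config$epochs > 0) {
    # The mean-over-time readout occasionally fails to break symmetry from
    # an unlucky initialization (training accuracy stuck at chance). Restart
    # from a deterministically derived init seed, at most `restarts` times.
    attempt <- 0L
    repeat {
      seed_a <- config$init_seed + attempt * 10000L
      fit <- cpp_train(enc_train$tokens, enc_train$lengths,
                       as.numeric(split$train$label),
                       cpp_config(config, spec), seed_a)
      attempt <- attempt + 1L
      converged <- utils::tail(fit$accuracy, 1) >= 0.6
      if (converged || attempt > config$restarts) break
      message(sprintf("training stalled at chance accuracy; restarting (attempt %d, init seed %d)",
                      attempt + 1L, config$init_seed + attempt * 10000L))
    }
    params <- fit$params
    history <- tibble(epoch = seq_len(config$epochs),
                      loss = fit$loss, accuracy = fit$accuracy)
    attr(history, "attempts") <- attempt
  } else {
    params <- cpp_init_params(cpp_config(config, spec), config$init_seed)
    history <- tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  }

  model <- structure(
    list(params = params, config = config, spec = spec, history = history,
         n_train = nrow(split$train), n_test = nrow(split$test)),
    class = "cas_classifier"
  )

  train_scores <- predict(model, split$train)$score
  test_scores <- predict(model, split$test)$score
  ev <- evaluate_scores(tibble(score = test_scores, label = split$test$label))
  ev <- dplyr::mutate(
    ev,
    train_accuracy = mean((train_scores > 0.5) == (split$train$label == 1)),
    test_accuracy = .data$accuracy,
    .before = 1
  )
  model$eval <- dplyr::select(ev, -"accuracy")
  model
}

#' Score sequences with a trained classifier
#'
#' Deterministic in evaluation mode; record order is preserved. Records with
#' residues outside the alphabet are skipped with a warning and get an `NA`
#' score.
#'
#' @param object A `cas_classifier`.
#' @param newdata A tibble with columns `id` and `residues`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `length`, `score` in `[0, 1]`.
#' @export
predict.cas_classifier <- function(object, newdata, ...) {
  if (!is.data.frame(newdata) || !all(c("id", "residues") %in% names(newdata))) {
    stop("`newdata` must have columns `id` and `residues`", call. = FALSE)
  }
  n <- nrow(newdata)
  out <- tibble(id = newdata$id, length = nchar(newdata$residues),
                score = rep(NA_real_, n))
  if (n == 0) return(out)
  ok <- nzchar(newdata$residues) & grepl(AA_REGEX, newdata$residues)
  if (any(!ok)) {
    warning(sprintf("skipping %d record(s) with residues outside the alphabet: %s",
                    sum(!ok), paste(head(newdata$id[!ok], 3), collapse = ", ")),
            call. = FALSE)
  }
  if (any(ok)) {
    enc <- encode_sequences(newdata[ok, c("id", "residues")], object$spec)
    out$score[ok] <- cpp_predict(object$params, enc$tokens, enc$lengths,
                                 cpp_config(object$config, object$spec))
  }
  out
}

#' @export
print.cas_classifier <- function(x, ...) {
  cat(sprintf("<cas_classifier> CNN-LSTM (%s conv block(s), %d LSTM units), %d epoch(s)\n",
              length(x$config$conv_filters), x$config$lstm_units,
              x$config$epochs))
  if (!is.null(x$eval)) {
    cat(sprintf("  test accuracy %.3f, AUC %.3f (n_train=%d, n_test=%d)\n",
                x$eval$test_accuracy, x$eval$auc, x$n_train, x$n_test))
  }
  invisible(x)
}

#' Confusion counts and threshold metrics for binary scores
#'
#' Predictions are positive when `score > cutoff` (matching a ">50 percent"
#' reporting convention at the default cutoff). AUC is the Mann-Whitney rank
#' statistic with ties counted 0.5.
#'
#' @param data A data frame with numeric columns `score` (in `[0, 1]`) and
#'   `label` (0/1).
#' @param cutoff Score threshold for the confusion counts.
#' @return A one-row tibble of class `cas_eval` with columns `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @examples
#' evaluate_scores(data.frame(score = c(.9, .8, .7, .1), label = c(1, 1, 0, 0)))
#' @export
evaluate_scores <- function(data, cutoff = 0.5) {
  if (!is.data.frame(data) || !all(c("score", "label") %in% names(data))) {
    stop("`data` must have columns `score` and `label`", call. = FALSE)
  }
  score <- data$score
  label <- data$label
  if (anyNA(score) || anyNA(label)) {
    stop("`score` and `label` must not contain NA", call. = FALSE)
  }
  if (!all(label %in% c(0, 1))) stop("`label` must be 0/1", call. = FALSE)
  if (length(unique(label)) < 2) {
    stop("AUC is undefined: both classes must be present", call. = FALSE)
  }
  pred <- score > cutoff
  tp <- sum(pred & label == 1)
  fp <- sum(pred & label == 0)
  tn <- sum(!pred & label == 0)
  fn <- sum(!pred & label == 1)
  if (tp + fp == 0) {
    warning("no predicted positives; precision reported as 0", call. = FALSE)
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  r <- rank(score)
  auc <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(
    tibble(tp = tp, fp = fp, tn = tn, fn = fn,
           accuracy = (tp + tn) / length(label),
           precision = precision, recall = recall, f1 = f1, auc = auc),
    class = c("cas_eval", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
glance.cas_classifier <- function(x, ...) {
  if (is.null(x$eval)) return(tibble())
  dplyr::mutate(x$eval, n_train = x$n_train, n_test = x$n_test,
                epochs = x$config$epochs)
}

#' @export
tidy.cas_classifier <- function(x, ...) x$history

#' @export
autoplot.cas_classifier <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                                   names_to = "metric")
  ggplot2::ggplot(hist_long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Save / load a trained classifier
#'
#' The model directory stores the fitted parameters (`params.rds`) plus the
#' encoder and model configurations as a machine-readable JSON sidecar.
#'
#' @param model A `cas_classifier`.
#' @param dir Model directory (created if needed).
#' @return `save_classifier` returns `dir` invisibly; `load_classifier`
#'   returns the `cas_classifier`.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "cas_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  sidecar <- list(
    encoder = unclass(model$spec),
    model = unclass(model$config),
    n_train = model$n_train, n_test = model$n_test,
    history = as.list(model$history),
    eval = if (is.null(model$eval)) NULL else as.list(model$eval)
  )
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  spec <- encoder_spec(max_len = sidecar$encoder$max_len)
  config <- do.call(model_config,
                    sidecar$model[setdiff(names(sidecar$model), character())])
  model <- structure(
    list(params = readRDS(file.path(dir, "params.rds")),
         config = config, spec = spec,
         history = tibble::as_tibble(sidecar$history),
         n_train = sidecar$n_train, n_test = sidecar$n_test),
    class = "cas_classifier"
  )
  if (!is.null(sidecar$eval)) model$eval <- tibble::as_tibble(sidecar$eval)
  model
}
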