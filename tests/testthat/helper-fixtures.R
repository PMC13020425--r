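# Shared fixtures. Trained models are memoized in a session-level cache so
# that tests exercising the same study conditions share one training run.

.cf_cache <- new.env(parent = emptyenv())

# The synthetic study conditions: 400 positives of 800-1200 residues with
# three planted width-12 motifs; negatives are partial shuffles of these.
cf_fixture_positives <- function() {
  if (is.null(.cf_cache$pos)) {
    .cf_cache$pos <- make_positive_set(n = 400L, seed = 101L)
  }
  .cf_cache$pos
}

cf_fixture_model <- function(threshold, seed) {
  key <- sprintf("model_%03d_%d", round(threshold * 100), seed)
  if (is.null(.cf_cache[[key]])) {
    pos <- cf_fixture_positives()
    neg <- build_negative_dataset(pos, threshold,
                                  seed = round(threshold * 100) * 1000L + seed)
    .cf_cache[[key]] <- train_classifier(
      pos, neg,
      model_config(split_seed = 10L + seed, init_seed = 20L + seed),
      encoder_spec(max_len = 1200L)
    )
  }
  .cf_cache[[key]]
}

# A quickly trained model on short sequences for unit-level tests.
cf_tiny_positives <- function() {
  if (is.null(.cf_cache$tiny_pos)) {
    .cf_cache$tiny_pos <- make_positive_set(
      n = 60L, length_range = c(100L, 140L),
      motif_rel_pos = c(0.2, 0.5, 0.8), jitter = 5L, seed = 301L
    )
  }
  .cf_cache$tiny_pos
}

cf_tiny_model <- function() {
  if (is.null(.cf_cache$tiny_model)) {
    pos <- cf_tiny_positives()
    neg <- build_negative_dataset(pos, 1.0, seed = 302L)
    .cf_cache$tiny_model <- train_classifier(
      pos, neg,
      model_config(epochs = 10L, batch_size = 16L,
                   split_seed = 31L, init_seed = 32L),
      encoder_spec(max_len = 140L)
    )
  }
  .cf_cache$tiny_model
}

# Independent brute-force AUC oracle: mean pairwise concordance with ties
# counted one half.
cf_auc_brute <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Independent brute-force mutation-ranking oracle: ranks by counting
# strictly larger Diff values (ties share the minimum rank).
cf_rank_brute <- function(x) vapply(x, function(v) sum(x > v) + 1L, integer(1))
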