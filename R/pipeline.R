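cf_default_pipeline_config <- function() {
  list(
    n_positives = 60L,
    length_range = c(300L, 400L),
    motif_rel_pos = c(0.2, 0.5, 0.8),
    jitter = 15L,
    shuffle_threshold = 0.8,
    epochs = 12L,
    batch_size = 16L,
    max_len = 400L,
    n_fingerprints = 5L,
    n_homologs = 30L,
    sub_rate = 0.1,
    min_support = 2L,
    core_quantile = 0.75,
    total_cutoff = 30L
  )
}

#' Run the end-to-end synthetic pipeline
#'
#' Orchestrates synth -> shuffle -> train -> fingerprint -> design, writing
#' every stage's artifacts plus a manifest (config snapshot, seeds, package
#' version, input checksums) under `out_dir`. Config keys are validated
#' before any compute; unknown keys or out-of-range values abort the run.
#' Defaults are deliberately small so a full run takes seconds.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list overriding entries of the default configuration
#'   (see `casforge:::cf_default_pipeline_config()` for keys).
#' @param seed Global seed; all stage seeds derive from it.
#' @return Invisibly, a list with the trained model, the design table, and
#'   the artifact paths.
#' @export
run_pipeline <- function(out_dir, config = list(), seed = 1L) {
  defaults <- cf_default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown pipeline config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$shuffle_threshold <= 0 || cfg$shuffle_threshold > 1) {
    stop("pipeline pre-flight: `shuffle_threshold` must be in (0, 1]",
         call. = FALSE)
  }
  if (cfg$n_positives < 4) {
    stop("pipeline pre-flight: `n_positives` must be >= 4", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # stage 1: synthetic positives
  pos <- make_positive_set(n = cfg$n_positives,
                           length_range = cfg$length_range,
                           motif_rel_pos = cfg$motif_rel_pos,
                           jitter = cfg$jitter,
                           seed = derive_seed(seed, "synth"))
  paths$positives <- file.path(out_dir, "positives.fasta")
  write_fasta(pos, paths$positives)
  readr::write_tsv(motif_spans(pos), file.path(out_dir, "motif_spans.tsv"))

  # stage 2: shuffled negatives
  neg <- build_negative_dataset(pos, cfg$shuffle_threshold,
                                derive_seed(seed, "shuffle"))
  paths$negatives <- file.path(out_dir, "negatives.fasta")
  write_fasta(neg, paths$negatives)

  # stage 3: train + evaluate
  spec <- encoder_spec(max_len = cfg$max_len)
  mcfg <- model_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                       split_seed = derive_seed(seed, "split"),
                       init_seed = derive_seed(seed, "init"))
  model <- train_classifier(pos, neg, mcfg, spec)
  paths$model <- file.path(out_dir, "model")
  save_classifier(model, paths$model)
  readr::write_tsv(glance(model), file.path(out_dir, "evaluation.tsv"))
  scores <- predict(model, dplyr::bind_rows(pos, neg))
  paths$scores <- file.path(out_dir, "scores.tsv")
  readr::write_tsv(scores, paths$scores)

  # stage 4: fingerprints of the first few positives
  fp <- compute_fingerprints(model, head(pos, cfg$n_fingerprints)) |>
    detect_peaks()
  paths$fingerprints <- file.path(out_dir, "fingerprints.tsv")
  readr::write_tsv(as_tibble(fp), paths$fingerprints)

  # stage 5: homolog family + mutation design on the first positive
  aln <- make_homolog_family(pos[1, ], n = cfg$n_homologs,
                             sub_rate = cfg$sub_rate,
                             seed = derive_seed(seed, "homologs"))
  cm <- characteristic_matrix(model, aln, ref_id = pos$id[1],
                              min_support = cfg$min_support,
                              core_quantile = cfg$core_quantile)
  pm <- psap(aln, ref_id = pos$id[1])
  designs <- rank_mutations(cm, pm, pos$residues[1],
                            total_cutoff = cfg$total_cutoff)
  paths$designs <- file.path(out_dir, "designs.tsv")
  report_designs(designs, paths$designs)

  manifest <- list(
    package = "casforge",
    version = as.character(utils::packageVersion("casforge")),
    seed = as.integer(seed),
    config = cfg,
    checksums = as.list(tools::md5sum(unlist(
      paths[c("positives", "negatives")]
    )))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(model = model, designs = designs, paths = paths))
}
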