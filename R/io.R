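# Readers and writers for the package's interchange formats (all plain
# text): word2vec-style embeddings, annotation TSV, event CSV, matrix TSV
# with a JSON metadata sidecar, trial-log JSON-lines and decoder JSON.

#' Write an embedding in word2vec text format
#'
#' First line `n_tokens D`, then one line per token: the token followed by
#' D floats.
#'
#' @param embedding An [embedding_table()].
#' @param path Output file.
#' @export
write_embedding <- function(embedding, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(embedding), ncol(embedding)), con)
  for (i in seq_len(nrow(embedding))) {
    writeLines(paste(c(rownames(embedding)[i],
                       formatC(embedding[i, ], format = "g", digits = 17)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a word2vec text embedding
#'
#' @param path Input file.
#' @return An [embedding_table()].
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop_invalid("%s: malformed word2vec header", path)
  n <- hdr[1]; D <- hdr[2]
  vecs <- matrix(NA_real_, n, D)
  toks <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != D + 1)
      stop_invalid("%s line %d: expected %d values, found %d",
                   path, i + 1, D, length(parts) - 1)
    toks[i] <- parts[1]
    vecs[i, ] <- as.numeric(parts[-1])
  }
  rownames(vecs) <- toks
  embedding_table(vecs)
}

#' Write scene annotations as TSV
#'
#' Columns `scene_id`, `annotator_id`, `text` (token bags joined by
#' spaces), UTF-8.
#'
#' @param annotations List (per scene) of lists (per annotator) of token
#'   bags, as produced by [make_annotated_stimuli()].
#' @param path Output file.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(seq_along(annotations), function(i) {
    do.call(rbind, lapply(seq_along(annotations[[i]]), function(a) {
      data.frame(scene_id = i, annotator_id = a,
                 text = paste(annotations[[i]][[a]], collapse = " "),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read scene annotations from TSV
#'
#' @param path Input file with header `scene_id`, `annotator_id`, `text`.
#' @return List (per scene) of lists (per annotator) of token vectors.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("scene_id", "annotator_id", "text")
  if (!all(need %in% names(tab)))
    stop_invalid("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", "))
  scenes <- sort(unique(tab$scene_id))
  lapply(scenes, function(s) {
    sub <- tab[tab$scene_id == s, ]
    sub <- sub[order(sub$annotator_id), ]
    lapply(sub$text, function(x) strsplit(x, " ")[[1]])
  })
}

#' Write / read a numeric matrix as TSV with a JSON metadata sidecar
#'
#' Lossless text round trip (17 significant digits); metadata (band,
#' sampling rate, compensation provenance, ...) lives in `<path>.json`.
#'
#' @param m Numeric matrix.
#' @param path Output TSV path.
#' @param meta Named list of metadata (optional).
#' @export
write_matrix_tsv <- function(m, path, meta = list()) {
  utils::write.table(format(as.matrix(m), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(c(meta, list(nrow = nrow(m), ncol = ncol(m))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv`: the matrix, with metadata in attribute `meta`.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$nrow) && (nrow(m) != meta$nrow || ncol(m) != meta$ncol))
      stop_invalid("%s: shape does not match sidecar metadata", path)
    attr(m, "meta") <- meta
  }
  m
}

#' Write / read an event table as CSV
#'
#' Columns `onset_sample`, `label`.
#'
#' @param events Data frame with `onset_sample` and `label`.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "label") %in% names(ev)))
    stop_invalid("%s: events need onset_sample and label columns", path)
  ev
}

#' Write / read closed-loop trial logs as JSON-lines
#'
#' One trial per line: target, alpha, selected scene ids and the online
#' vectors.
#'
#' @param logs List of trial logs from [run_trial()].
#' @param path Output path.
#' @export
write_trial_logs <- function(logs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (l in logs) {
    writeLines(jsonlite::toJSON(list(target = l$target, alpha = l$alpha,
                                     selected = l$selected,
                                     v_online = l$V_online),
                                auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    x <- jsonlite::fromJSON(line)
    structure(list(target = x$target, V_online = x$v_online,
                   selected = x$selected, alpha = x$alpha),
              class = "trial_log")
  })
}

#' Serialize / restore a fitted decoder as JSON
#'
#' Full-precision JSON; the round trip reproduces predictions
#' bit-identically.
#'
#' @param model A [semantic_decoder()].
#' @param path Output path.
#' @export
write_decoder <- function(model, path) {
  jsonlite::write_json(list(weights = model$weights,
                            intercepts = model$intercepts,
                            feature_means = model$feature_means,
                            feature_sds = model$feature_sds,
                            kept = model$kept, dropped = model$dropped,
                            lambda = model$lambda, d_out = model$d_out,
                            training_scope = model$training_scope),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = matrix(unlist(x$weights), nrow = length(x$kept)),
                 intercepts = x$intercepts, feature_means = x$feature_means,
                 feature_sds = x$feature_sds, kept = x$kept,
                 dropped = if (length(x$dropped) == 0) integer(0) else x$dropped,
                 lambda = x$lambda, d_out = x$d_out,
                 training_scope = x$training_scope),
            class = "semantic_decoder")
}

#' Read and validate a run configuration (YAML)
#'
#' @param path YAML file; missing fields are filled with package defaults.
#' @return Named list of validated settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(n_scenes = 360, embedding_dim = 100, n_electrodes = 20,
                   n_sources = 10, n_annotators = 5, noise_sd = 0.1,
                   folds = 10, alpha = 0.5, frames_per_trial = 32,
                   n_perm = 1000, seed = 1)
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop_invalid("unknown config field(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  if (out$alpha < 0 || out$alpha > 1) stop_invalid("alpha must be in [0, 1]")
  if (out$n_annotators < 1) stop_invalid("n_annotators must be >= 1")
  if (out$folds < 2) stop_invalid("folds must be >= 2")
  out
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate -> group -> nested-CV decode -> evaluate -> closed-loop session
#' -> imagery analysis -> target-shuffle permutation test, writing every
#' artifact (embedding, annotations, features, events, trial logs and a
#' summary report) under `out_dir`.  Rerunning with the same config and
#' seed reproduces every numeric output.
#'
#' @param config From [read_run_config()] (default config when NULL).
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed when given.
#' @return Invisibly, the summary report list.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("semdecode_run_"),
                         seed = NULL) {
  cfg <- if (is.list(config)) config else read_run_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vocab <- synthetic_vocabulary(embedding_dim = cfg$embedding_dim)
  emb <- make_embedding(vocab, seed = cfg$seed)
  stim <- make_annotated_stimuli(cfg$n_scenes, emb, vocab, seed = cfg$seed + 1,
                                 n_annotators = cfg$n_annotators,
                                 n_sources = cfg$n_sources)
  subj <- subject_model(n_electrodes = cfg$n_electrodes,
                        d_semantic = cfg$embedding_dim,
                        noise_sd = cfg$noise_sd, seed = cfg$seed + 2)
  sim <- simulate_watching_features(stim, subj, seed = cfg$seed + 3)
  comp <- lapply(seq_along(sim$baseline_rest), function(s)
    comp_resting(sim$baseline_rest[[s]], sim$baseline0_rest[[s]]))
  feats <- sim$features
  for (s in seq_along(comp)) {
    idx <- sim$session_of_scene == s
    feats[idx, ] <- compensate_features(feats[idx, , drop = FALSE], comp[[s]])
  }
  plan <- plan_scene_groups(stim$source_of_scene, k = min(cfg$folds,
                                                          cfg$n_sources))
  cv <- nested_cv_decode(feats, stim$V_true, plan)
  cats <- category_vectors(emb)
  pca <- fit_pca(stim$V_true)
  final <- fit_final_decoder(feats, stim$V_true, plan)
  pool <- image_pool(stim$scene_ids, stim$V_true)
  targets <- rep(c("word", "landscape", "face"), length.out = 12)
  logs <- run_feedback_session(final, subj, targets, pool, cats,
                               alpha = cfg$alpha,
                               frames = cfg$frames_per_trial,
                               seed = cfg$seed + 4)
  perm <- target_shuffle_null(logs, cats, "three_choice",
                              n_perm = min(cfg$n_perm, 500),
                              seed = cfg$seed + 5)
  imag <- simulate_imagery_trials(subj, stim$V_true,
                                  word_images = select_category_scenes(stim$V_true, cats$word, 5),
                                  landscape_images = select_category_scenes(stim$V_true, cats$landscape, 5),
                                  seed = cfg$seed + 6)
  imtab <- analyze_imagery(imag, final, cats)
  write_embedding(emb, file.path(out_dir, "embedding.txt"))
  write_annotations(stim$annotations, file.path(out_dir, "annotations.tsv"))
  write_matrix_tsv(feats, file.path(out_dir, "features.tsv"),
                   meta = list(band = "high_gamma", compensated = TRUE))
  write_events(data.frame(onset_sample = stim$scene_ids, label = "scene"),
               file.path(out_dir, "events.csv"))
  write_trial_logs(logs, file.path(out_dir, "trials.jsonl"))
  write_decoder(final, file.path(out_dir, "decoder.json"))
  report <- list(config = cfg,
                 mean_dim_r = mean(cv$dim_r),
                 mean_scene_id_accuracy = mean(scene_id_accuracy(cv$V_inferred, stim$V_true)),
                 three_way_accuracy = classify_categories(
                   cv$V_inferred, cats, stim$dominant_category)$accuracy,
                 three_choice_accuracy = three_choice_accuracy(logs, cats),
                 three_choice_p = perm$p,
                 delta_z = imtab[, c("window", "category", "delta_z", "p")],
                 nonimagery_binary_accuracy = attr(imtab, "binary_accuracy"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
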