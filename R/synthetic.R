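# Synthetic-data generator: embeddings with category structure, annotated
# stimuli, and simulated neural features under a linear-Gaussian encoding
# model with session gain drift, imagery gain, and closed-loop attention.
#
# The generator is first-class, tested code: it defines the statistical
# structure every downstream stage assumes (and is tested against).

#' Synthetic vocabulary specification
#'
#' Tokens grouped into the three named stimulus categories (word, landscape,
#' face) plus fillers.  The face category contains both "human" and "face"
#' so that the category-vector construction has its required tokens.
#'
#' @param categories Named list of character vectors; must contain `word`,
#'   `landscape` and `face`, each with >= 2 tokens.  A `filler` element is
#'   optional.
#' @param embedding_dim Embedding dimension (>= 2). Default 100; the
#'   full-study scale is 1000.
#' @return Object of class `synthetic_vocabulary`.
#' @export
synthetic_vocabulary <- function(categories = NULL, embedding_dim = 100) {
  if (embedding_dim < 2) stop_invalid("invalid config: embedding_dim must be >= 2")
  if (is.null(categories)) {
    categories <- list(
      word = c("word", "letter", "text", "subtitle", "sign", "book"),
      landscape = c("landscape", "mountain", "sea", "forest", "sky", "river"),
      face = c("human", "face", "person", "man", "woman", "smile"),
      filler = c("animal", "food", "car", "music")
    )
  }
  for (k in c("word", "landscape", "face")) {
    if (is.null(categories[[k]]) || length(categories[[k]]) < 2)
      stop_invalid("invalid config: category '%s' needs >= 2 tokens", k)
  }
  tokens <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(tokens)) stop_invalid("invalid config: duplicate tokens")
  category_of_word <- rep(names(categories), lengths(categories))
  names(category_of_word) <- tokens
  structure(list(words = tokens, category_of_word = category_of_word,
                 categories = categories, embedding_dim = embedding_dim),
            class = "synthetic_vocabulary")
}

#' Generate a synthetic embedding with category cluster structure
#'
#' Each category gets an orthonormal cluster center; token vectors are the
#' center plus isotropic Gaussian noise.  With `noise_sd = 0` the
#' within-category cosine similarity is exactly 1 while cross-category
#' cosines vanish; with moderate noise the within/cross ordering still holds.
#'
#' @param vocab A [synthetic_vocabulary()].
#' @param seed Integer seed; the result is a pure function of (vocab, seed).
#' @param noise_sd Isotropic token noise around the cluster center
#'   (default 0.3; the centers are unit vectors).
#' @return An [embedding_table()] with one row per token.
#' @export
make_embedding <- function(vocab, seed, noise_sd = 0.3) {
  if (vocab$embedding_dim < 2) stop_invalid("invalid config: embedding_dim must be >= 2")
  D <- vocab$embedding_dim
  cats <- names(vocab$categories)
  if (length(cats) > D)
    stop_invalid("invalid config: more categories than embedding dimensions")
  with_seed(seed, {
    # random orthonormal centers via QR of a Gaussian matrix
    G <- matrix(stats::rnorm(D * length(cats)), D, length(cats))
    centers <- qr.Q(qr(G))[, seq_along(cats), drop = FALSE]
    colnames(centers) <- cats
    vecs <- t(vapply(vocab$words, function(w) {
      centers[, vocab$category_of_word[[w]]] + noise_sd * stats::rnorm(D)
    }, numeric(D)))
    embedding_table(vecs)
  })
}

#' Subject model for the synthetic encoding of features
#'
#' Ground truth for parameter-recovery tests: linear encoding weights over
#' the concatenated (semantic, low-level visual, low-level auditory) stimulus
#' features, Gaussian electrode noise, per-session multiplicative gains
#' (impedance drift), electrode area labels, and the imagery/attention gains
#' that drive the imagery and closed-loop simulations.
#'
#' @param n_electrodes Number of electrodes (default 20).
#' @param d_semantic,d_visual,d_audio Sizes of the three stimulus-feature
#'   blocks (visual/audio may be 0).
#' @param noise_sd Gaussian noise SD added to every feature (default 0.1).
#' @param session_gains Positive per-session gains (default `c(1, 1.3, 0.8)`).
#' @param areas Character vector of per-electrode area labels in
#'   `{early, higher, other}`; default splits electrodes between early and
#'   higher.
#' @param imagery_gain Either a single nonnegative number or a matrix with
#'   rows `word`/`landscape` and one column per analysis window, giving the
#'   additive imagery drive per (imagined category, window).
#' @param attention_gain Nonnegative weight of the feedback image's semantic
#'   vector in the closed-loop step (default 1).
#' @param imagery_areas Areas whose electrodes carry the imagery drive
#'   (default `"higher"`).
#' @param seed Integer seed for the weight draw.
#' @return Object of class `subject_model`.
#' @export
subject_model <- function(n_electrodes = 20, d_semantic = 100, d_visual = 0,
                          d_audio = 0, noise_sd = 0.1,
                          session_gains = c(1, 1.3, 0.8),
                          areas = NULL, imagery_gain = 1, attention_gain = 1,
                          imagery_areas = "higher", seed = 1) {
  if (any(session_gains <= 0)) stop_invalid("session_gains must be > 0")
  if (any(imagery_gain < 0) || attention_gain < 0)
    stop_invalid("imagery/attention gains must be >= 0")
  if (is.null(areas)) {
    areas <- rep(c("early", "higher"), length.out = n_electrodes)
  }
  stopifnot(length(areas) == n_electrodes)
  P <- d_semantic + d_visual + d_audio
  with_seed(seed, {
    W <- matrix(stats::rnorm(n_electrodes * P, sd = 1 / sqrt(P)), n_electrodes, P)
    baseline_level <- stats::runif(n_electrodes, 0.5, 1.5)
    structure(list(encoding_weights = W,
                   d_semantic = d_semantic, d_visual = d_visual, d_audio = d_audio,
                   noise_sd = noise_sd, session_gains = session_gains,
                   areas = areas, imagery_gain = imagery_gain,
                   attention_gain = attention_gain,
                   imagery_areas = imagery_areas,
                   baseline_level = baseline_level),
              class = "subject_model")
  })
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("Synthetic subject: %d electrodes, %d stimulus dims, noise SD %.3g, %d sessions\n",
              nrow(x$encoding_weights),
              x$d_semantic + x$d_visual + x$d_audio,
              x$noise_sd, length(x$session_gains)))
  invisible(x)
}

semantic_weights <- function(subject) {
  subject$encoding_weights[, seq_len(subject$d_semantic), drop = FALSE]
}

imagery_gain_of <- function(subject, category, window_index) {
  g <- subject$imagery_gain
  if (!is.matrix(g)) return(g[[1]])
  if (category %in% rownames(g)) g[category, min(window_index, ncol(g))] else 0
}

#' Generate annotated synthetic stimuli
#'
#' Emulates the study design: still scenes extracted at 1-s intervals from a
#' set of videos, each annotated by several annotators.  Every annotator
#' writes a token bag whose category composition follows the scene's mixture
#' weights; the scene's true semantic vector is then the two-level average of
#' [build_scene_vector()], so generator and analysis agree by construction.
#' Scenes are assigned to video sources in contiguous runs, subdivided into
#' contiguous clips (the unit of the clip-shuffle permutation test).
#'
#' @param n_scenes Number of scenes (default 360; full scale 3600).
#' @param embedding An [embedding_table()] from [make_embedding()].
#' @param vocab The matching [synthetic_vocabulary()].
#' @param seed Integer seed.
#' @param category_mixture Optional `n_scenes x 3` nonnegative matrix of
#'   (word, landscape, face) weights per scene; default draws one dominant
#'   category per scene with weight 0.8.
#' @param n_annotators Annotators per scene (default 5).
#' @param n_sources Video sources; scenes are split into this many contiguous
#'   runs (default 6).
#' @param tokens_per_annotation Tokens written by each annotator (default 8).
#' @param clip_len Scenes per clip within a source (default 15).
#' @return Object of class `synthetic_stimuli`: `annotations` (list of lists
#'   of token bags), `V_true` (scenes x D), `scene_ids`, `source_of_scene`,
#'   `clip_of_scene`, `category_mixture`, `dominant_category`.
#' @export
make_annotated_stimuli <- function(n_scenes = 360, embedding, vocab, seed,
                                   category_mixture = NULL, n_annotators = 5,
                                   n_sources = 6, tokens_per_annotation = 8,
                                   clip_len = 15) {
  if (n_scenes < 1) stop_invalid("invalid config: n_scenes must be >= 1")
  if (n_annotators < 1) stop_invalid("invalid config: n_annotators must be >= 1")
  cats3 <- c("word", "landscape", "face")
  with_seed(seed, {
    if (is.null(category_mixture)) {
      dom <- sample(cats3, n_scenes, replace = TRUE)
      category_mixture <- t(vapply(dom, function(d) {
        w <- rep(0.1, 3); names(w) <- cats3; w[d] <- 0.8; w
      }, numeric(3)))
    } else {
      category_mixture <- as.matrix(category_mixture)
      if (any(category_mixture < 0)) stop_invalid("mixture weights must be nonnegative")
      colnames(category_mixture) <- cats3
      dom <- cats3[max.col(category_mixture, ties.method = "first")]
    }
    annotations <- vector("list", n_scenes)
    for (i in seq_len(n_scenes)) {
      w <- category_mixture[i, ] / sum(category_mixture[i, ])
      annotations[[i]] <- lapply(seq_len(n_annotators), function(a) {
        cat_draw <- sample(cats3, tokens_per_annotation, replace = TRUE, prob = w)
        vapply(cat_draw, function(cc) sample(vocab$categories[[cc]], 1), character(1))
      })
    }
    V_true <- t(vapply(seq_len(n_scenes), function(i) {
      build_scene_vector(annotations[[i]], embedding, scene_id = i)
    }, numeric(embedding_dim(embedding))))
    source_of_scene <- rep(seq_len(n_sources), length.out = 0)
    # contiguous runs of (nearly) equal length
    sizes <- diff(round(seq(0, n_scenes, length.out = n_sources + 1)))
    source_of_scene <- rep(seq_len(n_sources), times = sizes)
    clip_of_scene <- integer(n_scenes)
    clip_id <- 0
    for (s in seq_len(n_sources)) {
      idx <- which(source_of_scene == s)
      local_clip <- (seq_along(idx) - 1) %/% clip_len
      clip_of_scene[idx] <- clip_id + local_clip + 1
      clip_id <- max(clip_of_scene[idx])
    }
    structure(list(annotations = annotations, V_true = V_true,
                   scene_ids = seq_len(n_scenes),
                   source_of_scene = source_of_scene,
                   clip_of_scene = clip_of_scene,
                   category_mixture = category_mixture,
                   dominant_category = dom),
              class = "synthetic_stimuli")
  })
}

#' @export
print.synthetic_stimuli <- function(x, ...) {
  cat(sprintf("Synthetic stimuli: %d scenes, %d sources, %d clips, D = %d\n",
              length(x$scene_ids), max(x$source_of_scene),
              max(x$clip_of_scene), ncol(x$V_true)))
  invisible(x)
}

# Shared primitive: linear encoding + gain + truncated Gaussian noise.
encode_features <- function(subject, X, gain) {
  E <- nrow(subject$encoding_weights)
  signal <- X %*% t(subject$encoding_weights)       # windows x electrodes
  noise <- matrix(stats::rnorm(length(signal), sd = subject$noise_sd),
                  nrow(signal), E)
  pmax(gain * signal + noise, 0)
}

#' Simulate watching-task features and baselines
#'
#' Per-scene features follow the linear encoding model
#' `feature(scene, e) = session_gain * (w_e . x_scene) + noise`, truncated at
#' zero (band powers are nonnegative).  Baseline windows for both
#' compensation schemes (30 resting windows and 60 image-matched windows per
#' session) are generated under the same session gain, so the ratio-based
#' compensation factors absorb the gain drift.
#'
#' @param stimuli A [make_annotated_stimuli()] result.
#' @param subject A [subject_model()]; its stimulus-feature dimension must
#'   equal `D + d_visual + d_audio`.
#' @param seed Integer seed.
#' @param low_level Optional scenes x (d_visual + d_audio) matrix of low-level
#'   stimulus features; drawn iid N(0,1) when needed and absent.
#' @return List: `features` (scenes x E, raw), `session_of_scene`,
#'   `baseline_rest`/`baseline0_rest` (lists per session of 30 x E),
#'   `baseline_images`/`baseline0_images` (lists per session of 60 x E),
#'   `low_level`, `X` (the full stimulus design).
#' @export
simulate_watching_features <- function(stimuli, subject, seed, low_level = NULL) {
  D <- ncol(stimuli$V_true)
  extra <- subject$d_visual + subject$d_audio
  if (subject$d_semantic != D)
    stop_invalid("shape error: subject expects %d semantic dims, stimuli have %d",
                 subject$d_semantic, D)
  n <- nrow(stimuli$V_true)
  with_seed(seed, {
    if (extra > 0 && is.null(low_level)) {
      low_level <- matrix(stats::rnorm(n * extra), n, extra)
    }
    X <- if (extra > 0) cbind(stimuli$V_true, low_level) else stimuli$V_true
    if (ncol(X) != ncol(subject$encoding_weights))
      stop_invalid("shape error: design has %d columns, weights expect %d",
                   ncol(X), ncol(subject$encoding_weights))
    n_sessions <- length(subject$session_gains)
    session_of_source <- rep(seq_len(n_sessions),
                             length.out = max(stimuli$source_of_scene))
    session_of_scene <- session_of_source[stimuli$source_of_scene]
    features <- matrix(0, n, nrow(subject$encoding_weights))
    for (s in seq_len(n_sessions)) {
      idx <- which(session_of_scene == s)
      if (length(idx) > 0) {
        features[idx, ] <- encode_features(subject, X[idx, , drop = FALSE],
                                           subject$session_gains[s])
      }
    }
    E <- nrow(subject$encoding_weights)
    base_mat <- function(gain, k) {
      lvl <- matrix(rep(subject$baseline_level, each = k), k, E)
      pmax(gain * lvl + matrix(stats::rnorm(k * E, sd = subject$noise_sd), k, E), 0)
    }
    g1 <- subject$session_gains[1]
    baseline_rest <- lapply(subject$session_gains, base_mat, k = 30)
    baseline0_rest <- lapply(subject$session_gains, function(g) base_mat(g1, 30))
    baseline_images <- lapply(subject$session_gains, base_mat, k = 60)
    baseline0_images <- lapply(subject$session_gains, function(g) base_mat(g1, 60))
    list(features = features, session_of_scene = session_of_scene,
         baseline_rest = baseline_rest, baseline0_rest = baseline0_rest,
         baseline_images = baseline_images, baseline0_images = baseline0_images,
         low_level = low_level, X = X)
  })
}

#' Simulate imagery-task trials
#'
#' Protocol: each trial presents a first image for 2 s (nonimagery period,
#' to memorize) and then an image from the other category for 2 s (imagery
#' period) while the subject imagines the first image.  All pairs of the 5
#' word and 5 landscape images in both orders give 50 trials.  During the
#' imagery period the encoding gains an additive term
#' `imagery_gain(imagined category, window) * (w_e . v_imagined)` restricted
#' to electrodes in the subject's imagery areas.
#'
#' @param subject A [subject_model()].
#' @param V_true True semantic matrix of the image pool.
#' @param word_images,landscape_images Scene ids (row indices into `V_true`)
#'   of the images representing each category; default 5 each.
#' @param seed Integer seed.
#' @param windows Character labels of the analysis windows
#'   (default `c("0-1", "0.5-1.5", "1-2")`, seconds after image onset).
#' @return Object of class `imagery_trials`: `index` data frame (trial,
#'   period, window, presented_image, presented_category, imagined_category)
#'   and `features` matrix with one row per index row.
#' @export
simulate_imagery_trials <- function(subject, V_true, word_images,
                                    landscape_images, seed,
                                    windows = c("0-1", "0.5-1.5", "1-2")) {
  if (anyDuplicated(c(word_images, landscape_images)))
    stop_invalid("invalid config: duplicate image ids")
  if (subject$d_visual + subject$d_audio > 0)
    V_pad <- function(v) c(v, rep(0, subject$d_visual + subject$d_audio))
  else V_pad <- identity
  Wsem <- semantic_weights(subject)
  imag_mask <- subject$areas %in% subject$imagery_areas
  pairs <- expand.grid(word = word_images, landscape = landscape_images)
  # both orders: word first then landscape, and landscape first then word
  trials <- rbind(
    data.frame(first = pairs$word, second = pairs$landscape,
               first_cat = "word", second_cat = "landscape"),
    data.frame(first = pairs$landscape, second = pairs$word,
               first_cat = "landscape", second_cat = "word"))
  n_trial <- nrow(trials)
  gain <- subject$session_gains[1]
  with_seed(seed, {
    index <- NULL
    rows <- list()
    for (t in seq_len(n_trial)) {
      for (period in c("nonimagery", "imagery")) {
        presented <- if (period == "nonimagery") trials$first[t] else trials$second[t]
        presented_cat <- if (period == "nonimagery") trials$first_cat[t] else trials$second_cat[t]
        imagined_cat <- if (period == "imagery") trials$first_cat[t] else NA_character_
        v_pres <- V_true[presented, ]
        for (w in seq_along(windows)) {
          x <- matrix(V_pad(v_pres), nrow = 1)
          feat <- drop(encode_features(subject, x, gain))
          if (period == "imagery") {
            g <- imagery_gain_of(subject, imagined_cat, w)
            v_imag <- V_true[trials$first[t], ]
            add <- g * drop(Wsem %*% v_imag)
            feat <- pmax(feat + gain * add * imag_mask, 0)
          }
          rows[[length(rows) + 1]] <- feat
          index <- rbind(index, data.frame(
            trial = t, period = period, window = windows[w],
            presented_image = presented, presented_category = presented_cat,
            imagined_category = imagined_cat, stringsAsFactors = FALSE))
        }
      }
    }
    structure(list(index = index, features = do.call(rbind, rows),
                   windows = windows, n_trials = n_trial),
              class = "imagery_trials")
  })
}

#' @export
print.imagery_trials <- function(x, ...) {
  cat(sprintf("Imagery trials: %d trials x 2 periods x %d windows\n",
              x$n_trials, length(x$windows)))
  invisible(x)
}

#' Simulate one closed-loop feature window
#'
#' One 1-s feature vector of the closed-loop subject: the encoding drive is
#' `imagery_gain * v_target + attention_gain * v_feedback`; a black screen
#' contributes no attention term.
#'
#' @param subject A [subject_model()].
#' @param target_category One of `"word"`, `"landscape"`, `"face"`.
#' @param cats Category vectors from [category_vectors()].
#' @param v_feedback Semantic vector of the currently shown feedback image,
#'   or `NULL` for the black screen.
#' @param seed Integer seed (or `NULL` to consume the current RNG stream).
#' @return Feature vector of length `n_electrodes`.
#' @export
simulate_closed_loop_step <- function(subject, target_category, cats,
                                      v_feedback = NULL, seed = NULL) {
  if (!target_category %in% c("word", "landscape", "face"))
    stop_invalid("invalid argument: unknown category '%s'", target_category)
  v_target <- cats[[target_category]]
  g_im <- imagery_gain_of(subject, target_category, 1)
  drive <- g_im * v_target
  if (!is.null(v_feedback)) drive <- drive + subject$attention_gain * v_feedback
  x <- matrix(c(drive, rep(0, subject$d_visual + subject$d_audio)), nrow = 1)
  run <- function() drop(encode_features(subject, x, subject$session_gains[1]))
  if (is.null(seed)) run() else with_seed(seed, run())
}
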