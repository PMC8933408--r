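# Synthetic generator: embedding cluster structure, stimulus/annotation
# internal consistency, and the encoding model's gain/noise behaviour.

test_that("synthetic embedding is deterministic and clustered by category", {
  vocab <- synthetic_vocabulary(embedding_dim = 30)
  expect_equal(make_embedding(vocab, seed = 5), make_embedding(vocab, seed = 5))
  expect_false(isTRUE(all.equal(make_embedding(vocab, seed = 5),
                                make_embedding(vocab, seed = 6))))
  # zero noise: within-category cosine exactly 1, cross-category < 1
  emb0 <- make_embedding(vocab, seed = 1, noise_sd = 0)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(cosv(emb0["word", ], emb0["letter", ]), 1, tolerance = 1e-12)
  expect_lt(cosv(emb0["word", ], emb0["mountain", ]), 1)
})

test_that("mean within-category cosine exceeds cross-category (all-pairs oracle)", {
  cats <- list(word = paste0("w", 1:10), landscape = paste0("l", 1:10),
               face = c("human", "face", paste0("f", 1:8)))
  vocab <- synthetic_vocabulary(cats, embedding_dim = 50)
  emb <- make_embedding(vocab, seed = 2, noise_sd = 0.1)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- cross <- c()
  toks <- vocab$words
  for (i in seq_along(toks)) for (j in seq_along(toks)) {
    if (j <= i) next
    cs <- cosv(emb[toks[i], ], emb[toks[j], ])
    if (vocab$category_of_word[[toks[i]]] == vocab$category_of_word[[toks[j]]])
      within <- c(within, cs) else cross <- c(cross, cs)
  }
  expect_gt(mean(within), mean(cross))
})

test_that("invalid generator configs are rejected", {
  expect_error(synthetic_vocabulary(embedding_dim = 1), "embedding_dim")
  expect_error(synthetic_vocabulary(list(word = "w", landscape = c("a", "b"),
                                         face = c("c", "d"))), "word")
  w <- make_world()
  expect_error(make_annotated_stimuli(10, w$emb, w$vocab, seed = 1,
                                      n_annotators = 0), "n_annotators")
})

test_that("scene vectors equal the annotation-averaging of the semantic space", {
  w <- make_world()
  recomputed <- t(sapply(seq_along(w$stim$annotations), function(i)
    build_scene_vector(w$stim$annotations[[i]], w$emb)))
  expect_equal(unname(w$stim$V_true), unname(recomputed), tolerance = 1e-12)
})

test_that("scenes fall into contiguous source runs and dominant-category scenes track their category vector", {
  w <- make_world()
  src <- w$stim$source_of_scene
  expect_true(all(diff(src) >= 0))          # contiguous runs
  expect_equal(length(unique(src)), 10)
  # pure word vs pure landscape mixtures, checked exhaustively
  mix <- rbind(matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 1, 0), 10), ncol = 3, byrow = TRUE))
  st <- make_annotated_stimuli(20, w$emb, w$vocab, seed = 9,
                               category_mixture = mix, n_sources = 4)
  for (i in 1:20) {
    r_word <- cor(st$V_true[i, ], w$cats$word)
    r_land <- cor(st$V_true[i, ], w$cats$landscape)
    if (i <= 10) expect_gt(r_word, r_land) else expect_gt(r_land, r_word)
  }
})

test_that("watching features follow the truncated linear-gain encoding model", {
  w <- make_world()
  subj0 <- subject_model(n_electrodes = 8, d_semantic = 50, noise_sd = 0,
                         session_gains = 1, seed = 4)
  sim0 <- simulate_watching_features(w$stim, subj0, seed = 5)
  expect_equal(sim0$features,
               pmax(w$stim$V_true %*% t(subj0$encoding_weights), 0),
               tolerance = 1e-12)
  # reproducibility
  sim0b <- simulate_watching_features(w$stim, subj0, seed = 5)
  expect_identical(sim0$features, sim0b$features)
  # dimension mismatch
  bad <- subject_model(n_electrodes = 4, d_semantic = 12, seed = 1)
  expect_error(simulate_watching_features(w$stim, bad, seed = 1), "shape")
})

test_that("session-gain doubling cancels under matched-baseline compensation", {
  w <- make_world()
  sim <- w$sim
  s <- 2   # a session with gain != 1
  idx <- sim$session_of_scene == s
  comp1 <- comp_resting(sim$baseline_rest[[s]], sim$baseline0_rest[[s]])
  f1 <- compensate_features(sim$features[idx, ], comp1)
  # double the whole session: signal and its baseline
  comp2 <- comp_resting(2 * sim$baseline_rest[[s]], sim$baseline0_rest[[s]])
  f2 <- compensate_features(2 * sim$features[idx, ], comp2)
  expect_equal(f1, f2, tolerance = 1e-10)
  # same for the image-matched scheme
  compa <- comp_images(sim$baseline_images[[s]], sim$baseline0_images[[s]])
  compb <- comp_images(3 * sim$baseline_images[[s]], sim$baseline0_images[[s]])
  expect_equal(compensate_features(sim$features[idx, ], compa),
               compensate_features(3 * sim$features[idx, ], compb),
               tolerance = 1e-10)
})

test_that("imagery trials follow the 5x5x2 protocol and zero gain leaves periods identical", {
  w <- make_world()
  word_img <- select_category_scenes(w$stim$V_true, w$cats$word, 5)
  land_img <- select_category_scenes(w$stim$V_true, w$cats$landscape, 5)
  tr <- simulate_imagery_trials(w$subj, w$stim$V_true, word_img, land_img, seed = 8)
  expect_equal(tr$n_trials, 50)
  expect_equal(nrow(tr$index), 50 * 2 * 3)
  expect_error(simulate_imagery_trials(w$subj, w$stim$V_true,
                                       c(1, 1, 2, 3, 4), land_img, seed = 1),
               "duplicate")
  # gain 0, noise 0: a presentation's features do not depend on the period
  subj0 <- subject_model(n_electrodes = 8, d_semantic = 50, noise_sd = 0,
                         imagery_gain = 0, seed = 4)
  tr0 <- simulate_imagery_trials(subj0, w$stim$V_true, word_img, land_img, seed = 8)
  i_non <- which(tr0$index$period == "nonimagery" & tr0$index$window == "0-1" &
                   tr0$index$presented_image == word_img[1])[1]
  i_img <- which(tr0$index$period == "imagery" & tr0$index$window == "0-1" &
                   tr0$index$presented_image == word_img[1])[1]
  expect_equal(tr0$features[i_non, ], tr0$features[i_img, ], tolerance = 1e-12)
})

test_that("closed-loop step is pure noise at zero gains and reproducible", {
  subj0 <- make_null_subject(noise_sd = 1)
  w <- make_world()
  f1 <- simulate_closed_loop_step(subj0, "word", w$cats, seed = 3)
  f2 <- simulate_closed_loop_step(subj0, "word", w$cats, seed = 3)
  expect_identical(f1, f2)
  fb <- simulate_closed_loop_step(subj0, "landscape", w$cats,
                                  v_feedback = w$stim$V_true[1, ], seed = 3)
  expect_identical(f1, fb)  # gains 0: target and feedback leave no trace
  expect_error(simulate_closed_loop_step(w$subj, "cat", w$cats), "unknown category")
  # zero noise + zero gains: exactly zero features
  subjz <- subject_model(n_electrodes = 8, d_semantic = 50, noise_sd = 0,
                         imagery_gain = 0, attention_gain = 0, seed = 4)
  expect_equal(simulate_closed_loop_step(subjz, "face", w$cats, seed = 1),
               rep(0, 8))
})
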