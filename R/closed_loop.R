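# Closed-loop feedback simulation and evaluation: exponential smoothing of
# the decoded vector, nearest-image selection by correlation, the trial
# protocol, frame-averaged three-choice evaluation, frame-wise accuracy and
# projected correlation against the target vectors.

#' Update the online vector
#'
#' `v_online = alpha * v_inferred + (1 - alpha) * v_online_prev`.  The first
#' frame of a trial uses the black-screen inferred vector directly (handled
#' by [run_trial()]).
#'
#' @param v_prev Previous online vector.
#' @param v_inferred Newly decoded vector.
#' @param alpha Interpolation weight in `[0, 1]`.
#' @return The new online vector.
#' @export
update_online_vector <- function(v_prev, v_inferred, alpha) {
  if (alpha < 0 || alpha > 1) stop_invalid("invalid config: alpha must be in [0, 1]")
  if (length(v_prev) != length(v_inferred)) stop_invalid("dimension mismatch")
  alpha * v_inferred + (1 - alpha) * v_prev
}

#' Image pool for feedback selection
#'
#' @param scene_ids Unique scene identifiers.
#' @param V_true Matching rows of true semantic vectors.
#' @return Object of class `image_pool`.
#' @export
image_pool <- function(scene_ids, V_true) {
  V_true <- as.matrix(V_true)
  if (length(scene_ids) == 0) stop_invalid("pool must be nonempty")
  if (anyDuplicated(scene_ids)) stop_invalid("pool ids must be unique")
  stopifnot(length(scene_ids) == nrow(V_true))
  # rows centered and unit-normalized once, so per-frame correlations are a
  # single matrix-vector product
  Vc <- V_true - rowMeans(V_true)
  nrm <- sqrt(rowSums(Vc^2))
  Vn <- Vc / ifelse(nrm > 0, nrm, 1)
  Vn[nrm == 0, ] <- 0
  structure(list(scene_ids = scene_ids, V_true = V_true, Vn = Vn),
            class = "image_pool")
}

#' Select the feedback image
#'
#' Returns the pool scene whose true semantic vector has the highest Pearson
#' correlation with the online vector; ties break toward the lowest scene
#' id.
#'
#' @param v_online Online vector.
#' @param pool An [image_pool()].
#' @return The selected scene id.
#' @export
select_feedback_image <- function(v_online, pool) {
  vc <- v_online - mean(v_online)
  nv <- sqrt(sum(vc^2))
  if (nv == 0) stop_invalid("degenerate state: constant online vector")
  r <- drop(pool$Vn %*% (vc / nv))
  ord <- order(-r, pool$scene_ids)
  pool$scene_ids[ord[1]]
}

#' Run one closed-loop trial
#'
#' Frame 1 decodes the black-screen window; every subsequent frame decodes a
#' window generated while the previously selected feedback image is on
#' screen, interpolates the online vector, and selects the next image.
#'
#' @param decoder A [semantic_decoder()] trained on the subject's features.
#' @param subject A [subject_model()].
#' @param target Target category (`word`/`landscape`/`face`).
#' @param pool An [image_pool()].
#' @param cats Category vectors from [category_vectors()].
#' @param alpha Interpolation weight (study values 0.4-1.0).
#' @param frames Feedback frames per trial (default 32).
#' @param seed Integer seed (or NULL to consume the caller's RNG stream).
#' @return Object of class `trial_log`: `target`, `V_online`
#'   (frames x D), `selected` (frame scene ids), `alpha`.
#' @export
run_trial <- function(decoder, subject, target, pool, cats, alpha = 0.5,
                      frames = 32, seed = NULL) {
  body <- function() {
    D <- length(cats$word)
    V_online <- matrix(NA_real_, frames, D)
    selected <- rep(pool$scene_ids[1], frames)
    feat <- simulate_closed_loop_step(subject, target, cats, v_feedback = NULL)
    v_online <- drop(predict(decoder, feat))
    for (j in seq_len(frames)) {
      if (j > 1) {
        v_fb <- pool$V_true[match(selected[j - 1], pool$scene_ids), ]
        feat <- simulate_closed_loop_step(subject, target, cats, v_feedback = v_fb)
        v_inf <- drop(predict(decoder, feat))
        v_online <- update_online_vector(v_online, v_inf, alpha)
      }
      V_online[j, ] <- v_online
      selected[j] <- select_feedback_image(v_online, pool)
    }
    structure(list(target = target, V_online = V_online, selected = selected,
                   alpha = alpha), class = "trial_log")
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("Closed-loop trial: target %s, %d frames, alpha %.2f\n",
              x$target, nrow(x$V_online), x$alpha))
  invisible(x)
}

# frames x categories matrix of Fisher-z correlations with category vectors
frame_z_matrix <- function(V_online, cats) {
  R <- cor_cols_safe(t(V_online), category_matrix(cats))
  colnames(R) <- c("word", "landscape", "face")
  fisher_z(R)
}

#' Evaluate one trial as a three-choice task
#'
#' The trial succeeds when the frame-averaged Fisher-z correlation of the
#' online vector with the target's category vector strictly exceeds both
#' non-target averages.  Restricting to two categories gives the pairwise
#' evaluation.
#'
#' @param log A [run_trial()] log.
#' @param cats Category vectors.
#' @param categories Categories in play (default all three).
#' @return List: `success`, `mean_z` (per category), `z` (frames x cats).
#' @export
evaluate_trial_three_choice <- function(log, cats,
                                        categories = c("word", "landscape", "face")) {
  Z <- frame_z_matrix(log$V_online, cats)[, categories, drop = FALSE]
  mean_z <- colMeans(Z)
  others <- setdiff(categories, log$target)
  success <- all(mean_z[log$target] > mean_z[others])
  list(success = success, mean_z = mean_z, z = Z)
}

#' Run a session of closed-loop trials
#'
#' @param decoder,subject,pool,cats,alpha,frames As in [run_trial()].
#' @param targets Character vector of per-trial target categories.
#' @param seed Integer seed for the whole session.
#' @return List of `trial_log`s.
#' @export
run_feedback_session <- function(decoder, subject, targets, pool, cats,
                                 alpha = 0.5, frames = 32, seed = 1) {
  with_seed(seed, {
    lapply(targets, function(tg)
      run_trial(decoder, subject, tg, pool, cats, alpha, frames, seed = NULL))
  })
}

#' Three-choice accuracy over a set of trials
#'
#' @param logs List of trial logs.
#' @param cats Category vectors.
#' @return Fraction of successful trials.
#' @export
three_choice_accuracy <- function(logs, cats) {
  mean(vapply(logs, function(l)
    evaluate_trial_three_choice(l, cats)$success, logical(1)))
}

#' Frame-wise three-choice accuracy curve
#'
#' Per frame, the fraction of trials whose frame-j z-correlation argmax
#' equals the target category.
#'
#' @param logs List of trial logs sharing the frame count.
#' @param cats Category vectors.
#' @return Numeric vector, one accuracy per frame.
#' @export
frame_wise_accuracy <- function(logs, cats) {
  categories <- c("word", "landscape", "face")
  frames <- nrow(logs[[1]]$V_online)
  hits <- sapply(logs, function(l) {
    Z <- frame_z_matrix(l$V_online, cats)
    categories[max.col(Z, ties.method = "first")] == l$target
  })
  rowMeans(matrix(hits, nrow = frames))
}

#' Projected correlation of online vectors with targets
#'
#' Concatenates all frames of all trials; the reference sequence holds each
#' trial's target category vector on every frame.  Returns `PrjR^k`
#' between the two sequences on the requested components of the
#' training-video PCA basis.
#'
#' @param logs List of trial logs.
#' @param pca Reference [fit_pca()] basis.
#' @param cats Category vectors.
#' @param components Component indices (default significant-free `1:2`).
#' @return Named numeric vector of projected correlations.
#' @export
prj_r_online <- function(logs, pca, cats, components = 1:2) {
  V_online <- do.call(rbind, lapply(logs, function(l) l$V_online))
  V_target <- do.call(rbind, lapply(logs, function(l) {
    matrix(cats[[l$target]], nrow(l$V_online), length(cats[[l$target]]),
           byrow = TRUE)
  }))
  out <- vapply(components, function(k)
    prj_r(V_online, V_target, pca, k), numeric(1))
  names(out) <- paste0("PC", components)
  out
}
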