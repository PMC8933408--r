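# Ridge decoding of semantic vectors from band features: leakage-free
# standardization, source-grouped nested cross-validation, and the encoding
# analysis with feature-set weight ablation.
#
# The ridge solution is computed per output dimension with a single shared
# regularization parameter, via one SVD of the standardized design per
# training set (all grid values then cost a diagonal reweighting each).

#' Default regularization grid
#'
#' `10^-8, 10^-7, ..., 10^8`.
#' @return Numeric vector of candidate ridge penalties.
#' @export
default_lambda_grid <- function() 10^seq(-8, 8)

#' Partition scenes into balanced source-grouped folds
#'
#' All scenes from one video source land in the same fold; the imbalance
#' (max minus min fold size) is minimized by first-fit-decreasing assignment
#' followed by pairwise move/swap local search.  Deterministic given its
#' inputs.
#'
#' @param source_of_scene Integer/character vector: source id per scene.
#' @param k Number of folds (default 10).
#' @param seed Accepted for interface stability; the search is deterministic.
#' @return Object of class `group_plan`: `group_of_scene` (length = scenes),
#'   `group_of_source`, `k`.
#' @export
plan_scene_groups <- function(source_of_scene, k = 10, seed = 1) {
  sources <- unique(source_of_scene)
  if (length(sources) < k)
    stop_invalid("invalid config: %d sources cannot fill %d groups",
                 length(sources), k)
  sizes <- as.numeric(table(factor(source_of_scene, levels = sources)))
  ord <- order(-sizes, seq_along(sizes))
  group_sizes <- numeric(k)
  assign_of <- integer(length(sources))
  for (i in ord) {
    g <- which.min(group_sizes)
    assign_of[i] <- g
    group_sizes[g] <- group_sizes[g] + sizes[i]
  }
  imbalance <- function(a) {
    gs <- vapply(seq_len(k), function(g) sum(sizes[a == g]), numeric(1))
    max(gs) - min(gs)
  }
  # local search: single-source moves, then pairwise swaps, until no gain
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    cur <- imbalance(assign_of)
    for (i in seq_along(sources)) {
      for (g in seq_len(k)) {
        if (g == assign_of[i]) next
        cand <- assign_of; cand[i] <- g
        if (min(table(factor(cand, levels = seq_len(k)))) == 0) next
        if (imbalance(cand) < cur) {
          assign_of <- cand; cur <- imbalance(cand); improved <- TRUE
        }
      }
    }
    for (i in seq_along(sources)) {
      for (j in seq_along(sources)) {
        if (assign_of[i] == assign_of[j]) next
        cand <- assign_of
        cand[c(i, j)] <- cand[c(j, i)]
        if (imbalance(cand) < cur) {
          assign_of <- cand; cur <- imbalance(cand); improved <- TRUE
        }
      }
    }
  }
  if (any(tabulate(assign_of, k) == 0)) stop_invalid("internal: empty group")
  group_of_source <- assign_of
  names(group_of_source) <- as.character(sources)
  group_of_scene <- group_of_source[as.character(source_of_scene)]
  structure(list(group_of_scene = unname(group_of_scene),
                 group_of_source = group_of_source, k = k),
            class = "group_plan")
}

#' @export
print.group_plan <- function(x, ...) {
  gs <- table(x$group_of_scene)
  cat(sprintf("Group plan: %d folds, sizes %s (imbalance %d)\n", x$k,
              paste(as.integer(gs), collapse = "/"),
              max(gs) - min(gs)))
  invisible(x)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) == 0) stop_invalid("degenerate input: all features zero-variance")
  list(mean = mu, sd = sdv, keep = keep)
}

standardize_apply <- function(X, st) {
  Xs <- sweep(sweep(X[, st$keep, drop = FALSE], 2, st$mean[st$keep]),
              2, st$sd[st$keep], `/`)
  Xs
}

# SVD-based multi-output ridge on an already-standardized design.
ridge_core <- function(Xs, Yc) {
  sv <- svd(Xs)
  list(u = sv$u, d = sv$d, v = sv$v, uty = crossprod(sv$u, Yc))
}

ridge_weights <- function(core, lambda) {
  shrink <- core$d / (core$d^2 + lambda)
  core$v %*% (shrink * core$uty)
}

#' Fit a ridge semantic decoder
#'
#' The fitting function at the package's core: one ridge regression per
#' output dimension with a shared penalty, on z-scored features.  The
#' standardization statistics are computed on the training data only and
#' frozen into the model; zero-variance features are dropped and recorded.
#'
#' @param X Samples x P feature matrix.
#' @param Y Samples x D response matrix (semantic vectors).
#' @param lambda Ridge penalty (a single value; see [select_lambda()] for
#'   data-driven choice).
#' @param training_scope Free-text provenance note stored in the model.
#' @return Object of class `semantic_decoder` with `weights` (P_kept x D),
#'   `intercepts`, `feature_means`, `feature_sds`, `kept`, `dropped`,
#'   `lambda`.
#' @export
semantic_decoder <- function(X, Y, lambda, training_scope = "full data") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2) stop_invalid("need >= 2 samples")
  if (!all(is.finite(Y))) stop_invalid("Y must be finite")
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  intercepts <- colMeans(Y)
  Yc <- sweep(Y, 2, intercepts)
  W <- ridge_weights(ridge_core(Xs, Yc), lambda)
  structure(list(weights = W, intercepts = intercepts,
                 feature_means = st$mean, feature_sds = st$sd,
                 kept = st$keep,
                 dropped = setdiff(seq_len(ncol(X)), st$keep),
                 lambda = lambda, d_out = ncol(Y),
                 training_scope = training_scope),
            class = "semantic_decoder")
}

#' @export
print.semantic_decoder <- function(x, ...) {
  cat(sprintf("Semantic ridge decoder: %d features -> %d dimensions, lambda = %g\n",
              length(x$kept), x$d_out, x$lambda))
  if (length(x$dropped) > 0)
    cat(sprintf("  (%d zero-variance feature(s) dropped)\n", length(x$dropped)))
  cat(sprintf("  trained on: %s\n", x$training_scope))
  invisible(x)
}

#' @export
coef.semantic_decoder <- function(object, ...) {
  W <- matrix(0, length(object$feature_means), object$d_out)
  W[object$kept, ] <- object$weights
  rbind(`(intercept)` = object$intercepts, W)
}

#' Predict semantic vectors from features
#'
#' New features are standardized with the model's frozen training statistics
#' before applying the per-dimension ridge weights.
#'
#' @param object A [semantic_decoder()].
#' @param newdata Samples x P feature matrix (or a single feature vector).
#' @param ... Unused.
#' @return Samples x D matrix of inferred semantic vectors.
#' @export
predict.semantic_decoder <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_means))
    stop_invalid("shape error: model expects %d features, got %d",
                 length(object$feature_means), ncol(newdata))
  st <- list(mean = object$feature_means, sd = object$feature_sds,
             keep = object$kept)
  Xs <- standardize_apply(newdata, st)
  sweep(Xs %*% object$weights, 2, object$intercepts, `+`)
}

# Grouped CV predictions for every lambda in the grid at once.
# Returns list(pred = list per lambda of n x D matrices, groups).
grouped_cv_predictions <- function(X, Y, group_of_scene, grid) {
  n <- nrow(X)
  groups <- sort(unique(group_of_scene))
  preds <- lapply(grid, function(l) matrix(NA_real_, n, ncol(Y)))
  for (g in groups) {
    test <- which(group_of_scene == g)
    train <- which(group_of_scene != g)
    st <- standardize_fit(X[train, , drop = FALSE])
    Xs_tr <- standardize_apply(X[train, , drop = FALSE], st)
    Xs_te <- standardize_apply(X[test, , drop = FALSE], st)
    intercepts <- colMeans(Y[train, , drop = FALSE])
    Yc <- sweep(Y[train, , drop = FALSE], 2, intercepts)
    core <- ridge_core(Xs_tr, Yc)
    for (li in seq_along(grid)) {
      W <- ridge_weights(core, grid[li])
      preds[[li]][test, ] <- sweep(Xs_te %*% W, 2, intercepts, `+`)
    }
  }
  preds
}

#' Select the ridge penalty by grouped cross-validation
#'
#' For each grid value, out-of-fold predictions are assembled over the
#' grouped folds and scored by the mean dimension-wise correlation with the
#' true vectors; the argmax is returned, ties broken toward the smaller
#' penalty.
#'
#' @param X,Y Feature and response matrices.
#' @param plan A [plan_scene_groups()] result (or an integer group vector).
#' @param grid Candidate penalties (default [default_lambda_grid()]).
#' @return The selected penalty.
#' @export
select_lambda <- function(X, Y, plan, grid = default_lambda_grid()) {
  if (length(grid) == 0) stop_invalid("invalid config: empty grid")
  group <- if (inherits(plan, "group_plan")) plan$group_of_scene else plan
  preds <- grouped_cv_predictions(as.matrix(X), as.matrix(Y), group, grid)
  score <- vapply(preds, function(P) mean(dim_r(P, Y, warn = FALSE)), numeric(1))
  grid[order(-score, grid)[1]]
}

#' Nested cross-validated decoding
#'
#' For each outer fold the decoder is trained on the remaining folds, with
#' the penalty chosen by an inner grouped cross-validation restricted to
#' those training folds, and standardization statistics computed on the
#' outer-training data only; the held-out fold is then predicted.  Every
#' scene is predicted exactly once by a model that never saw it.
#'
#' @param X Scenes x P features.
#' @param V_true Scenes x D true semantic vectors.
#' @param plan A [plan_scene_groups()] result.
#' @param grid Penalty grid.
#' @return Object of class `cv_decode`: `V_inferred`, `lambda_per_fold`,
#'   `dim_r` (per-dimension correlations over all scenes), `plan`.
#' @export
nested_cv_decode <- function(X, V_true, plan, grid = default_lambda_grid()) {
  X <- as.matrix(X); V_true <- as.matrix(V_true)
  group <- plan$group_of_scene
  stopifnot(length(group) == nrow(X))
  V_inferred <- matrix(NA_real_, nrow(X), ncol(V_true))
  lambdas <- numeric(0)
  for (g in sort(unique(group))) {
    test <- which(group == g)
    train <- which(group != g)
    lam <- select_lambda(X[train, , drop = FALSE], V_true[train, , drop = FALSE],
                         group[train], grid)
    model <- semantic_decoder(X[train, , drop = FALSE],
                              V_true[train, , drop = FALSE], lam,
                              training_scope = sprintf("outer fold %s held out", g))
    V_inferred[test, ] <- predict(model, X[test, , drop = FALSE])
    lambdas[as.character(g)] <- lam
  }
  structure(list(V_inferred = V_inferred, lambda_per_fold = lambdas,
                 dim_r = dim_r(V_inferred, V_true, warn = FALSE), plan = plan),
            class = "cv_decode")
}

#' @export
print.cv_decode <- function(x, ...) {
  cat(sprintf("Nested-CV decoding: %d scenes, %d dims, mean DimR = %.4f\n",
              nrow(x$V_inferred), ncol(x$V_inferred), mean(x$dim_r)))
  cat("  lambda per fold:", paste(signif(x$lambda_per_fold, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the final decoder on all data
#'
#' The penalty is chosen by grouped cross-validation over the full plan
#' (source- or recording-day-grouped, per study phase), then a single model
#' is trained on all scenes with full-data standardization statistics.
#'
#' @inheritParams nested_cv_decode
#' @return A [semantic_decoder()].
#' @export
fit_final_decoder <- function(X, V_true, plan, grid = default_lambda_grid()) {
  lam <- select_lambda(X, V_true, plan, grid)
  semantic_decoder(X, V_true, lam,
                   training_scope = sprintf("all %d scenes (lambda by %d-fold grouped CV)",
                                            nrow(as.matrix(X)), plan$k))
}

#' Encoding analysis with feature-set ablation
#'
#' Per electrode, a ridge model predicts its feature from the concatenated
#' (semantic, visual, audio) stimulus blocks under nested grouped CV; for
#' each feature set, out-of-fold predictions are recomputed with the weights
#' of the other two blocks set to zero (intercept retained).  The result is
#' the Pearson correlation between observed and predicted features over all
#' scenes, per electrode and per feature set (plus the full model).
#'
#' @param blocks Named list of scene x dim matrices; names become the
#'   feature-set labels (e.g. `semantic`, `visual`, `audio`).
#' @param y Scenes x electrodes observed features.
#' @param plan A [plan_scene_groups()] result.
#' @param grid Penalty grid.
#' @return Matrix electrodes x (length(blocks) + 1) of correlations, columns
#'   named by block plus `"full"`.
#' @export
encode_features_with_ablation <- function(blocks, y, plan,
                                          grid = default_lambda_grid()) {
  y <- as.matrix(y)
  X <- do.call(cbind, blocks)
  bounds <- cumsum(c(0, vapply(blocks, ncol, numeric(1))))
  block_cols <- lapply(seq_along(blocks), function(b) (bounds[b] + 1):bounds[b + 1])
  names(block_cols) <- names(blocks)
  group <- plan$group_of_scene
  n <- nrow(X); E <- ncol(y)
  pred_full <- matrix(NA_real_, n, E)
  pred_abl <- lapply(blocks, function(b) matrix(NA_real_, n, E))
  for (g in sort(unique(group))) {
    test <- which(group == g)
    train <- which(group != g)
    lam <- select_lambda(X[train, , drop = FALSE], y[train, , drop = FALSE],
                         group[train], grid)
    model <- semantic_decoder(X[train, , drop = FALSE], y[train, , drop = FALSE],
                              lam, training_scope = sprintf("fold %s", g))
    st <- list(mean = model$feature_means, sd = model$feature_sds,
               keep = model$kept)
    Xs_te <- standardize_apply(X[test, , drop = FALSE], st)
    pred_full[test, ] <- sweep(Xs_te %*% model$weights, 2, model$intercepts, `+`)
    for (b in names(blocks)) {
      keep_mask <- model$kept %in% block_cols[[b]]
      Wb <- model$weights
      Wb[!keep_mask, ] <- 0
      pred_abl[[b]][test, ] <- sweep(Xs_te %*% Wb, 2, model$intercepts, `+`)
    }
  }
  out <- sapply(c(pred_abl, list(full = pred_full)), function(P) {
    vapply(seq_len(E), function(e) {
      if (stats::sd(P[, e]) == 0) {
        warning("constant prediction: correlation defined as 0")
        return(0)
      }
      cor_safe(y[, e], P[, e], warn = TRUE)
    }, numeric(1))
  })
  out <- matrix(out, nrow = E,
                dimnames = list(NULL, c(names(blocks), "full")))
  out
}
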