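# Accuracy measures for inferred semantic vectors: dimension-wise and
# PCA-projected correlations, scene-wise correlation, scene identification,
# category classification and AUC.

#' Dimension-wise correlation coefficients
#'
#' One Pearson correlation per semantic dimension between the inferred and
#' true vector sequences over the evaluated scenes.  Zero-variance
#' dimensions correlate 0 (with a warning).
#'
#' @param V_inferred,V_true Scenes x D matrices of matched shape.
#' @param warn Warn on zero-variance dimensions (default TRUE).
#' @return Numeric vector of length D.
#' @export
dim_r <- function(V_inferred, V_true, warn = TRUE) {
  V_inferred <- as.matrix(V_inferred); V_true <- as.matrix(V_true)
  if (!all(dim(V_inferred) == dim(V_true))) stop_invalid("shape mismatch")
  if (nrow(V_true) < 3) stop_invalid("need >= 3 scenes")
  vapply(seq_len(ncol(V_true)), function(k)
    cor_safe(V_inferred[, k], V_true[, k], warn = warn), numeric(1))
}

#' Projected correlation coefficient
#'
#' Both vector sequences are projected onto the k-th PCA direction of the
#' reference semantic space (fitted on the true training vectors); the
#' Pearson correlation of the two score sequences is returned.  Also
#' applicable to online vectors versus per-trial target vectors.
#'
#' @param V_inferred Scenes x D inferred (or online) vectors.
#' @param V_ref Scenes x D reference vectors (true or target).
#' @param pca [fit_pca()] result defining the basis.
#' @param k Component index.
#' @return Correlation of projected scores.
#' @export
prj_r <- function(V_inferred, V_ref, pca, k) {
  s_inf <- pca_project(pca, V_inferred, k)
  s_ref <- pca_project(pca, V_ref, k)
  cor_safe(s_inf, s_ref, warn = FALSE)
}

#' Scene-wise correlation coefficients
#'
#' Per-scene Pearson correlation between the inferred and true semantic
#' vector of the same scene.
#'
#' @param V_inferred,V_true Scenes x D matrices.
#' @return Numeric vector, one correlation per scene.
#' @export
scene_r <- function(V_inferred, V_true) {
  V_inferred <- as.matrix(V_inferred); V_true <- as.matrix(V_true)
  vapply(seq_len(nrow(V_true)), function(i)
    cor_safe(V_inferred[i, ], V_true[i, ], warn = FALSE), numeric(1))
}

#' Scene-identification accuracy
#'
#' For each scene i, the fraction of competitor scenes j whose true vector
#' correlates strictly less with the inferred vector of i than scene i's own
#' true vector does.  Ties score zero (strict inequality).
#'
#' @param V_inferred,V_true Scenes x D matrices (>= 2 scenes).
#' @return Per-scene accuracy in `[0, 1]`.
#' @export
scene_id_accuracy <- function(V_inferred, V_true) {
  V_inferred <- as.matrix(V_inferred); V_true <- as.matrix(V_true)
  n <- nrow(V_true)
  if (n < 2) stop_invalid("need >= 2 scenes")
  # R[i, j] = correlation of inferred_i with true_j
  R <- cor_cols_safe(t(V_inferred), t(V_true))
  vapply(seq_len(n), function(i) {
    own <- R[i, i]
    sum(own > R[i, -i]) / (n - 1)
  }, numeric(1))
}

#' Classify scene categories from inferred vectors
#'
#' Each inferred vector is assigned the category whose vector it correlates
#' with most strongly; ties break by the fixed order word < landscape <
#' face.  Binary mode restricts scenes and candidate categories to the given
#' pair.
#'
#' @param V_inferred Scenes x D matrix.
#' @param cats Category vectors from [category_vectors()].
#' @param true_labels Character vector of presented categories.
#' @param mode `"three-way"` or `"binary"`.
#' @param pair For binary mode, the two categories to restrict to.
#' @return List: `accuracy`, `predicted`, `n`.
#' @export
classify_categories <- function(V_inferred, cats, true_labels,
                                mode = c("three-way", "binary"),
                                pair = c("word", "landscape")) {
  mode <- match.arg(mode)
  all_cats <- c("word", "landscape", "face")
  if (!all(true_labels %in% all_cats))
    stop_invalid("invalid argument: unknown label")
  use_cats <- if (mode == "binary") pair else all_cats
  keep <- true_labels %in% use_cats
  V <- as.matrix(V_inferred)[keep, , drop = FALSE]
  labels <- true_labels[keep]
  C <- category_matrix(cats)[, use_cats, drop = FALSE]
  R <- cor_cols_safe(t(V), C)
  pred <- use_cats[max.col(R, ties.method = "first")]
  list(accuracy = mean(pred == labels), predicted = pred, n = length(labels))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a positive-class score exceeds a negative-class score,
#' ties counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or factor with 2 levels;
#'   the higher level / `TRUE` / `1` is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
  pos <- as.logical(if (is.factor(labels)) labels == levels(labels)[2] else labels)
  if (all(pos) || !any(pos)) stop_invalid("undefined AUC: single-class input")
  r <- rank(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
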