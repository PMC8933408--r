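# Permutation machinery and shared tests: clip-shuffle null for projected
# correlations, target-shuffle null for closed-loop statistics, BH and
# Bonferroni adjustments, one-way ANOVA maps, Welch t.

# Smoothed permutation p-value: p = (1 + #{null as extreme}) / (1 + n_perm).
perm_p <- function(observed, null_sample, sided) {
  if (sided == "greater") {
    hits <- sum(null_sample >= observed)
  } else { # two-sided on distance from the null mean
    mu <- mean(null_sample)
    hits <- sum(abs(null_sample - mu) >= abs(observed - mu))
  }
  (1 + hits) / (1 + length(null_sample))
}

permutation_result <- function(observed, null_sample, sided) {
  structure(list(observed = observed, null_sample = null_sample,
                 p = perm_p(observed, null_sample, sided), sided = sided),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed %.4f, null mean %.4f, p = %.4g (n_perm = %d)\n",
              x$sided, x$observed, mean(x$null_sample), x$p,
              length(x$null_sample)))
  invisible(x)
}

#' Clip-shuffle permutation null for projected correlations
#'
#' The chance distribution preserves the within-clip autocorrelation of the
#' true vector sequence: the sequence is split at the clip boundaries, whole
#' clips are shuffled and re-concatenated, and the statistic (mean Fisher-z
#' projected correlation over the chosen components) is recomputed through
#' the identical code path.
#'
#' @param V_inferred,V_true Scenes x D matrices in presentation order.
#' @param clip_of_scene Integer clip label per scene (contiguous runs).
#' @param pca Reference basis from [fit_pca()].
#' @param components Component indices entering the mean-z statistic.
#' @param n_perm Number of permutations (default 1000; the full-scale
#'   analysis uses many more).
#' @param seed Integer seed.
#' @param sided `"two.sided"` (default) or `"greater"`.
#' @return A `permutation_result`.
#' @export
clip_shuffle_null <- function(V_inferred, V_true, clip_of_scene, pca,
                              components = 1, n_perm = 1000, seed = 1,
                              sided = "two.sided") {
  clips <- unique(clip_of_scene)
  if (length(clips) < 2) stop_invalid("degenerate null: need >= 2 clips")
  idx_of_clip <- lapply(clips, function(cl) which(clip_of_scene == cl))
  stat <- function(order_of_clips) {
    idx <- unlist(idx_of_clip[order_of_clips])
    Vt <- V_true[idx, , drop = FALSE]
    mean(fisher_z(vapply(components, function(k)
      prj_r(V_inferred, Vt, pca, k), numeric(1))))
  }
  observed <- stat(seq_along(clips))
  null_sample <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    stat(sample(seq_along(clips))), numeric(1)))
  permutation_result(observed, null_sample, sided)
}

#' Target-shuffle permutation null for closed-loop statistics
#'
#' Permutes the target categories across trials and recomputes the chosen
#' statistic through the same code path: one-sided for the three-choice
#' accuracy (accuracy is expected to exceed chance under control), two-sided
#' for projected correlations.
#'
#' @param logs List of trial logs from [run_trial()].
#' @param cats Category vectors.
#' @param statistic `"three_choice"` or `"prj_r_online"`.
#' @param pca,components For the projected statistic.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `permutation_result`.
#' @export
target_shuffle_null <- function(logs, cats, statistic = c("three_choice", "prj_r_online"),
                                pca = NULL, components = 1:2,
                                n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  targets <- vapply(logs, function(l) l$target, character(1))
  if (length(unique(targets)) < 2) stop_invalid("need >= 2 distinct targets")
  relabel <- function(ord) {
    lapply(seq_along(logs), function(i) {
      l <- logs[[i]]; l$target <- targets[ord[i]]; l
    })
  }
  stat <- switch(statistic,
    three_choice = function(ls) three_choice_accuracy(ls, cats),
    prj_r_online = function(ls)
      mean(fisher_z(prj_r_online(ls, pca, cats, components))))
  sided <- if (statistic == "three_choice") "greater" else "two.sided"
  observed <- stat(logs)
  null_sample <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    stat(relabel(sample(length(logs)))), numeric(1)))
  permutation_result(observed, null_sample, sided)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()], returning the adjusted
#' p-values and the rejection set at level `q`.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List: `adjusted`, `rejected` (logical).
#' @export
bh_adjust <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' One-way ANOVA map across electrodes
#'
#' Classical one-way ANOVA of category-grouped features per electrode, with
#' partial eta squared = SS_between / (SS_between + SS_within).  Electrodes
#' with zero within-group variance are flagged with infinite F.
#'
#' @param features Scenes x electrodes matrix (e.g. 3 x 50 category scenes).
#' @param groups Factor/character of group labels per row.
#' @return Data frame per electrode: `F`, `p`, `eta_sq`, `infinite`.
#' @export
anova_f_map <- function(features, groups) {
  features <- as.matrix(features)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || min(table(groups)) < 2)
    stop_invalid("need >= 2 groups with >= 2 observations each")
  out <- lapply(seq_len(ncol(features)), function(e) {
    y <- features[, e]
    ssw <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2)))
    if (ssw == 0) {
      ssb <- sum(tapply(y, groups, length) * (tapply(y, groups, mean) - mean(y))^2)
      return(data.frame(F = Inf, p = 0, eta_sq = if (ssb > 0) 1 else NA_real_,
                        infinite = TRUE))
    }
    a <- stats::anova(stats::lm(y ~ groups))
    ssb <- a$`Sum Sq`[1]
    data.frame(F = a$`F value`[1], p = a$`Pr(>F)`[1],
               eta_sq = ssb / (ssb + a$`Sum Sq`[2]), infinite = FALSE)
  })
  do.call(rbind, out)
}

#' Welch's t-test
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite degrees of
#' freedom, via [stats::t.test()].
#'
#' @param a,b Numeric samples (each >= 2 values).
#' @param sided `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @return List: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b, sided = "two.sided") {
  if (length(a) < 2 || length(b) < 2) stop_invalid("each sample needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop_invalid("degenerate input: zero variance in both samples")
  tt <- stats::t.test(a, b, alternative = sided, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
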