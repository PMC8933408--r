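# Imagery-task analysis: per-period correlations of decoded vectors with
# the word/landscape category vectors, the imagery modulation statistic
# (delta Z), per-window AUCs, and nonimagery binary accuracy.

#' Per-presentation category correlations in one analysis window
#'
#' Decodes the window's features of every presentation in both periods and
#' correlates each inferred vector with the word and landscape category
#' vectors.
#'
#' @param trials A [simulate_imagery_trials()] result (or any object with the
#'   same `index`/`features` layout).
#' @param decoder A [semantic_decoder()].
#' @param cats Category vectors from [category_vectors()].
#' @param window Window label (e.g. `"0-1"`).
#' @return Data frame: trial, period, presented_category, imagined_category,
#'   r_word, r_landscape.
#' @export
period_correlations <- function(trials, decoder, cats, window) {
  sel <- trials$index$window == window
  if (!any(sel)) stop_invalid("invalid argument: unknown window '%s'", window)
  V_inf <- predict(decoder, trials$features[sel, , drop = FALSE])
  R <- cor_cols_safe(t(V_inf), cbind(cats$word, cats$landscape))
  out <- trials$index[sel, c("trial", "period", "presented_category",
                             "imagined_category")]
  out$r_word <- R[, 1]
  out$r_landscape <- R[, 2]
  rownames(out) <- NULL
  out
}

#' Imagery modulation of the inferred vector (delta Z)
#'
#' `delta Z_word` is the mean Fisher-z correlation with the word vector over
#' landscape-image presentations in the imagery period (when the subject is
#' imagining a word image) minus the same mean in the nonimagery period;
#' `delta Z_landscape` is the symmetric quantity over word-image
#' presentations.  A one-sided Welch t-test (imagery > nonimagery) is
#' attached.
#'
#' @param pc A [period_correlations()] table.
#' @param category `"word"` or `"landscape"`: the imagined category whose
#'   modulation is measured.
#' @return List: `delta_z`, `t`, `df`, `p` (one-sided), `n_imagery`,
#'   `n_nonimagery`.
#' @export
delta_z <- function(pc, category = c("word", "landscape")) {
  category <- match.arg(category)
  watched <- if (category == "word") "landscape" else "word"
  score <- fisher_z(pc[[paste0("r_", category)]])
  z_im <- score[pc$presented_category == watched & pc$period == "imagery"]
  z_non <- score[pc$presented_category == watched & pc$period == "nonimagery"]
  if (length(z_im) < 2 || length(z_non) < 2)
    stop_invalid("invalid input: need >= 2 presentations per period")
  wt <- welch_t(z_im, z_non, sided = "greater")
  list(delta_z = mean(z_im) - mean(z_non), t = wt$t, df = wt$df, p = wt$p,
       n_imagery = length(z_im), n_nonimagery = length(z_non))
}

#' Nonimagery binary accuracy
#'
#' In the nonimagery period, a presentation counts as correct when the
#' inferred vector correlates more strongly with its own category's vector
#' than with the other category's; ties count as incorrect.
#'
#' @param pc A [period_correlations()] table.
#' @return Fraction correct.
#' @export
nonimagery_binary_accuracy <- function(pc) {
  non <- pc[pc$period == "nonimagery" &
              pc$presented_category %in% c("word", "landscape"), ]
  if (length(unique(non$presented_category)) < 2)
    stop_invalid("both categories must be present")
  own <- ifelse(non$presented_category == "word", non$r_word, non$r_landscape)
  other <- ifelse(non$presented_category == "word", non$r_landscape, non$r_word)
  mean(own > other)
}

#' Full imagery analysis for one subject
#'
#' Runs [period_correlations()] for every window and collects delta Z for
#' both imagined categories, the nonimagery AUC of each category score, and
#' the nonimagery binary accuracy of the first window.
#'
#' @param trials Imagery trials.
#' @param decoder A [semantic_decoder()].
#' @param cats Category vectors.
#' @param windows Window labels (default those present in `trials`).
#' @return Data frame with one row per (window, category): `delta_z`, `t`,
#'   `df`, `p`, `auc`; plus attribute `binary_accuracy`.
#' @export
analyze_imagery <- function(trials, decoder, cats, windows = NULL) {
  windows <- windows %||% trials$windows
  rows <- list()
  binacc <- NA_real_
  for (w in windows) {
    pc <- period_correlations(trials, decoder, cats, w)
    non <- pc[pc$period == "nonimagery", ]
    for (cat in c("word", "landscape")) {
      dz <- delta_z(pc, cat)
      auc <- auc_from_scores(non[[paste0("r_", cat)]],
                             non$presented_category == cat)
      rows[[length(rows) + 1]] <- data.frame(
        window = w, category = cat, delta_z = dz$delta_z, t = dz$t,
        df = dz$df, p = dz$p, auc = auc, stringsAsFactors = FALSE)
    }
    if (w == windows[1]) binacc <- nonimagery_binary_accuracy(pc)
  }
  out <- do.call(rbind, rows)
  attr(out, "binary_accuracy") <- binacc
  out
}

#' Group-level modulation report
#'
#' Aggregates per-subject delta Z values across subjects: one-sided
#' one-sample t-tests against zero per (category, window) cell, with
#' Bonferroni correction over the six tests (two categories times three
#' windows).
#'
#' @param subject_tables List of [analyze_imagery()] tables (one per
#'   subject, same windows).
#' @param alpha Family-wise level before correction (default 0.05).
#' @return Data frame per (window, category): mean delta Z, mean AUC, t, p,
#'   `significant` under the Bonferroni-adjusted level `alpha / 6`.
#' @export
modulation_report <- function(subject_tables, alpha = 0.05) {
  all_tab <- do.call(rbind, lapply(seq_along(subject_tables), function(s) {
    t <- subject_tables[[s]]; t$subject <- s; t
  }))
  cells <- unique(all_tab[, c("window", "category")])
  n_tests <- nrow(cells)
  adj_alpha <- alpha / n_tests
  out <- do.call(rbind, lapply(seq_len(n_tests), function(i) {
    sub <- all_tab[all_tab$window == cells$window[i] &
                     all_tab$category == cells$category[i], ]
    tt <- stats::t.test(sub$delta_z, mu = 0, alternative = "greater")
    data.frame(window = cells$window[i], category = cells$category[i],
               mean_delta_z = mean(sub$delta_z), mean_auc = mean(sub$auc),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < adj_alpha,
               stringsAsFactors = FALSE)
  }))
  attr(out, "adjusted_alpha") <- adj_alpha
  out
}
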