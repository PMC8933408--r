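# Grouped fold planning, the SVD ridge decoder, penalty selection, nested
# CV and the encoding ablation analysis.

test_that("source-grouped fold plan is exact and matches the exhaustive optimum", {
  # 10 equal sources over 10 folds: one source each, imbalance 0
  src <- rep(1:10, each = 7)
  plan <- plan_scene_groups(src, k = 10)
  expect_equal(sort(unname(plan$group_of_source)), 1:10)
  gs <- table(plan$group_of_scene)
  expect_equal(max(gs) - min(gs), 0)
  # constraint: every source's scenes in exactly one group
  expect_true(all(tapply(plan$group_of_scene, src,
                         function(g) length(unique(g))) == 1))
  # sizes [5,5,5,5,2,2] over 3 folds vs exhaustive-search optimum
  sizes <- c(5, 5, 5, 5, 2, 2)
  src2 <- rep(1:6, times = sizes)
  plan2 <- plan_scene_groups(src2, k = 3)
  imb <- function(a) {
    t <- tapply(sizes, a, sum)
    if (length(t) < 3) return(Inf)
    max(t) - min(t)
  }
  best <- min(apply(expand.grid(rep(list(1:3), 6)), 1, imb))
  expect_equal(imb(plan2$group_of_source), best)
  expect_error(plan_scene_groups(rep(1:4, each = 3), k = 10), "cannot fill")
})

test_that("ridge decoder matches a direct linear-system oracle and its limits", {
  set.seed(21)
  n <- 40; P <- 6; D <- 3
  X <- matrix(rnorm(n * P), n, P)
  W_true <- matrix(rnorm(P * D), P, D)
  Y <- X %*% W_true
  # independent oracle: solve() on the normal equations of standardized X
  lam <- 0.7
  mdl <- semantic_decoder(X, Y, lam)
  Xs <- scale(X)[, , drop = TRUE]
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  Yc <- sweep(Y, 2, colMeans(Y))
  W_or <- solve(crossprod(Xs) + lam * diag(P), crossprod(Xs, Yc))
  expect_equal(unname(mdl$weights), unname(W_or), tolerance = 1e-8)
  # tiny penalty on noiseless linear data recovers Y
  mdl2 <- semantic_decoder(X, Y, 1e-8)
  expect_equal(predict(mdl2, X), Y, tolerance = 1e-4)
  # huge penalty shrinks predictions to the training mean
  mdl3 <- semantic_decoder(X, Y, 1e12)
  expect_equal(predict(mdl3, X),
               matrix(colMeans(Y), n, D, byrow = TRUE), tolerance = 1e-6)
  # duplicated feature column: predictions nearly unchanged
  mdl4 <- semantic_decoder(cbind(X, X[, 1]), Y, lam)
  p1 <- predict(mdl, X); p4 <- predict(mdl4, cbind(X, X[, 1]))
  expect_gt(cor(as.numeric(p1), as.numeric(p4)), 0.999)
  expect_error(semantic_decoder(matrix(1, 10, 3), Y[1:10, ]), "zero-variance")
})

test_that("decoder standardization drops constant features and records them", {
  set.seed(22)
  X <- cbind(matrix(rnorm(60), 20, 3), 5)
  Y <- matrix(rnorm(40), 20, 2)
  mdl <- semantic_decoder(X, Y, 1)
  expect_equal(mdl$dropped, 4L)
  expect_equal(nrow(mdl$weights), 3)
  expect_equal(dim(predict(mdl, X)), c(20, 2))
})

test_that("penalty selection maximizes the mean dimension-wise CV correlation", {
  set.seed(23)
  n <- 60; P <- 8; D <- 6
  X <- matrix(rnorm(n * P), n, P)
  Y <- X %*% matrix(rnorm(P * D), P, D)
  group <- rep(1:6, each = 10)
  grid <- 10^seq(-8, 8)
  # noiseless linear: smallest grid value within one step of the argmax
  lam <- select_lambda(X, Y, group, grid)
  expect_lte(lam, grid[2])
  expect_equal(select_lambda(X, Y, group, grid = 42), 42)
  # the returned value attains the maximal score (independent recomputation)
  cv_score <- function(l) {
    pred <- matrix(NA_real_, n, D)
    for (g in 1:6) {
      te <- group == g
      m <- semantic_decoder(X[!te, ], Y[!te, ], l)
      pred[te, ] <- predict(m, X[te, ])
    }
    mean(sapply(1:D, function(k) cor(pred[, k], Y[, k])))
  }
  scores <- sapply(grid, cv_score)
  expect_equal(cv_score(lam), max(scores), tolerance = 1e-10)
})

test_that("nested CV predicts every scene once, without leakage, and recovers linear subjects", {
  w <- make_world()
  cv <- nested_cv_decode(w$sim$features, w$stim$V_true, w$plan,
                         grid = 10^seq(-4, 4))
  expect_false(anyNA(cv$V_inferred))
  expect_equal(length(cv$lambda_per_fold), 10)
  expect_gt(mean(cv$dim_r), 0.8)   # low-noise linear subject
  # leakage guard: deleting a test-fold row leaves that fold's lambda and
  # the predictions of its remaining rows unchanged (the held-out data never
  # enters training statistics or penalty selection)
  g <- w$plan$group_of_scene
  drop_row <- which(g == 1)[1]
  keep <- setdiff(seq_along(g), drop_row)
  plan2 <- w$plan
  plan2$group_of_scene <- g[keep]
  cv2 <- nested_cv_decode(w$sim$features[keep, ], w$stim$V_true[keep, ],
                          plan2, grid = 10^seq(-4, 4))
  expect_identical(cv$lambda_per_fold[["1"]], cv2$lambda_per_fold[["1"]])
  rows1 <- which(g == 1)[-1]
  expect_equal(cv$V_inferred[rows1, ],
               cv2$V_inferred[which(g[keep] == 1), ], tolerance = 1e-12)
})

test_that("nested CV on shuffled responses sits at chance", {
  set.seed(24)
  n <- 60; P <- 8; D <- 8
  src <- rep(1:6, each = 10)
  plan <- plan_scene_groups(src, k = 6)
  means <- replicate(20, {
    X <- matrix(rnorm(n * P), n, P)
    Y <- X %*% matrix(rnorm(P * D), P, D)
    Yshuf <- Y[sample(n), ]
    mean(nested_cv_decode(X, Yshuf, plan, grid = c(1e-2, 1, 1e2))$dim_r)
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("parameter recovery at the stated synthetic scale exceeds DimR 0.8", {
  set.seed(25)
  n <- 360; P <- 20; D <- 20
  V <- matrix(rnorm(n * D), n, D)
  W <- matrix(rnorm(D * P), D, P)
  signal <- V %*% W
  X <- signal + matrix(rnorm(n * P, sd = 0.1 * sd(signal)), n, P)
  plan <- plan_scene_groups(rep(1:12, each = 30), k = 10)
  cv <- nested_cv_decode(X, V, plan)
  expect_gt(mean(cv$dim_r), 0.8)
})

test_that("final decoder overfits no worse than out-of-fold and round-trips", {
  w <- make_world()
  cv <- nested_cv_decode(w$sim$features, w$stim$V_true, w$plan,
                         grid = 10^seq(-4, 4))
  train_pred <- predict(w$final, w$sim$features)
  r_train <- dim_r(train_pred, w$stim$V_true, warn = FALSE)
  r_cv <- cv$dim_r
  expect_true(mean(r_train) >= mean(r_cv))
  path <- tempfile(fileext = ".json")
  write_decoder(w$final, path)
  back <- read_decoder(path)
  expect_identical(predict(back, w$sim$features), train_pred)
})

test_that("encoding ablation recovers which feature block drives an electrode", {
  set.seed(26)
  n <- 360
  sem <- matrix(rnorm(n * 12), n, 12)
  vis <- matrix(rnorm(n * 8), n, 8)
  aud <- matrix(rnorm(n * 6), n, 6)
  w_sem <- rnorm(12)
  y_sem <- sem %*% w_sem + rnorm(n, sd = 0.3 * sd(sem %*% w_sem))
  y_null <- matrix(rnorm(n), n, 1)   # no stimulus drive at all
  y <- cbind(y_sem, y_null)
  plan <- plan_scene_groups(rep(1:12, each = 30), k = 10)
  suppressWarnings(
    res <- encode_features_with_ablation(
      list(semantic = sem, visual = vis, audio = aud), y, plan,
      grid = 10^seq(-2, 4)))
  expect_identical(colnames(res), c("semantic", "visual", "audio", "full"))
  # semantic-only electrode: semantic ablation ~ full, visual ablation low
  expect_lt(abs(res[1, "semantic"] - res[1, "full"]), 0.1)
  expect_lt(res[1, "visual"], 0.2)
  # zero-signal electrode: everything near zero
  expect_true(all(abs(res[2, ]) < 0.15))
})
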