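toy_separable <- function(n = 200, seed = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  # classes separated by a clean margin on f1
  x <- cbind(f1 = runif(n) + 2.5 * y, f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("standardization centers and spreads, constant columns pass", {
  x <- cbind(a = c(0, 10), b = c(7, 7))
  p <- scale_fit(x)
  expect_equal(unname(p$center["a"]), 5)
  expect_equal(unname(p$spread["a"]), 5)  # population sd
  xs <- scale_apply(p, x)
  expect_equal(unname(xs[, "a"]), c(-1, 1))
  expect_equal(unname(xs[, "b"]), c(7, 7))  # unchanged
  set.seed(1)
  big <- matrix(rnorm(200), 50)
  colnames(big) <- paste0("f", 1:4)
  expect_equal(unname(colMeans(scale_apply(scale_fit(big), big))),
               rep(0, 4), tolerance = 1e-12)
})

test_that("a separable toy problem is learned almost perfectly", {
  d <- toy_separable()
  fit <- circ_gbdt(d$x, d$y, n_trees = 50, seed = 1)
  pred <- predict(fit, d$x)
  expect_gte(mean(pred$label == d$y), 0.99)
})

test_that("the first tree splits on the label-determining feature", {
  set.seed(9)
  x <- cbind(sig = c(rnorm(50, -2), rnorm(50, 2)), noise = rnorm(100))
  y <- as.integer(x[, "sig"] > 0)
  # oracle: exhaustive depth-1 split search on the logistic gradient at
  # the 0.5 prior (g = 0.5 - y, h = 0.25) picks the feature with the
  # best achievable gain
  g <- 0.5 - y; h <- rep(0.25, 100)
  gains <- vapply(1:2, function(f) {
    o <- order(x[, f]); gs <- cumsum(g[o]); hs <- cumsum(h[o])
    G <- sum(g); H <- sum(h)
    max(gs[-100]^2 / (hs[-100] + 1) + (G - gs[-100])^2 / (H - hs[-100] + 1))
  }, 1)
  expect_equal(which.max(gains), 1L)
  fit <- circ_gbdt(x, y, n_trees = 5, max_depth = 1, seed = 1)
  expect_equal(fit$trees[[1]]$feature[1], 1L)
})

test_that("training is deterministic given the seed", {
  d <- toy_separable()
  probe <- matrix(rnorm(40), 20, dimnames = list(NULL, c("f1", "f2")))
  f1 <- circ_gbdt(d$x, d$y, n_trees = 30, subsample = 0.8, seed = 42)
  f2 <- circ_gbdt(d$x, d$y, n_trees = 30, subsample = 0.8, seed = 42)
  expect_identical(predict(f1, probe), predict(f2, probe))
  f3 <- circ_gbdt(d$x, d$y, n_trees = 30, subsample = 0.8, seed = 43)
  expect_false(identical(predict(f1, probe)$prob, predict(f3, probe)$prob))
})

test_that("training deviance is non-increasing over iterations", {
  set.seed(31)
  # noisy, non-separable data
  x <- cbind(a = rnorm(120), b = rnorm(120))
  y <- as.integer(x[, 1] + rnorm(120) > 0)
  fit <- circ_gbdt(x, y, n_trees = 80, learning_rate = 0.1, seed = 2)
  expect_true(all(diff(fit$train_loss) <= 1e-10))
})

test_that("an empty ensemble predicts the 0.5 prior", {
  d <- toy_separable(n = 20)
  fit <- circ_gbdt(d$x, d$y, n_trees = 0, seed = 1)
  expect_equal(predict(fit, d$x)$prob, rep(0.5, 20))
})

test_that("degenerate training inputs fail loudly", {
  d <- toy_separable(n = 20)
  expect_error(circ_gbdt(d$x, rep(1, 20)), "single class")
  xbad <- d$x; xbad[3, "f2"] <- NA
  expect_error(circ_gbdt(xbad, d$y), "f2")
})

test_that("predictions are invariant to pre-scaling the features", {
  d <- toy_separable()
  xs <- scale_apply(scale_fit(d$x), d$x)
  colnames(xs) <- colnames(d$x)
  f_raw <- circ_gbdt(d$x, d$y, n_trees = 40, seed = 7)
  f_scl <- circ_gbdt(xs, d$y, n_trees = 40, seed = 7)
  expect_equal(predict(f_raw, d$x)$prob, predict(f_scl, xs)$prob,
               tolerance = 1e-12)
})

test_that("models round-trip exactly through JSON", {
  d <- toy_separable()
  fit <- circ_gbdt(d$x, d$y, n_trees = 25, subsample = 0.9, seed = 5)
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(fit, d$x), predict(back, d$x))
  # truncated file fails
  raw <- readLines(path)
  writeLines(substr(paste(raw, collapse = ""), 1, 50),
             trunc_path <- tempfile())
  expect_error(load_model(trunc_path))
  # version mismatch fails
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$version <- "other-format-9"
  jsonlite::write_json(obj, path2 <- tempfile(), auto_unbox = TRUE)
  expect_error(load_model(path2), "version mismatch")
})

test_that("the feature fingerprint blocks column swaps and drops", {
  d <- toy_separable()
  fit <- circ_gbdt(d$x, d$y, n_trees = 10, seed = 1)
  x22 <- d$x[, 1, drop = FALSE]
  expect_error(predict(fit, x22), "fingerprint")
  swapped <- d$x[, c(2, 1)]
  expect_error(predict(fit, swapped), "fingerprint")
})

test_that("grid search degenerates cleanly and breaks ties to simplicity", {
  d <- toy_separable(n = 60)
  one <- data.frame(n_trees = 10L, learning_rate = 0.1, max_depth = 2L,
                    subsample = 1)
  gs <- grid_search_cv(d$x, d$y, grid = one, folds = 5, seed = 1)
  expect_equal(nrow(gs$cv), 1L)
  expect_equal(gs$best$n_trees, 10L)
  # noise-free, depth-2-generable labels: both depths reach F1 = 1 and
  # the tie breaks to the smaller depth
  set.seed(4)
  x <- cbind(u = rnorm(80), v = rnorm(80))
  y <- as.integer(x[, "u"] > 0 & x[, "v"] > -3)
  grid <- data.frame(n_trees = 20L, learning_rate = 0.3,
                     max_depth = c(2L, 8L), subsample = 1)
  gs2 <- grid_search_cv(x, y, grid = grid, folds = 4, seed = 2)
  expect_equal(gs2$cv$mean_f1[1], gs2$cv$mean_f1[2])
  expect_equal(gs2$best$max_depth, 2L)
})

test_that("grid search selection ignores example order", {
  d <- toy_separable(n = 80)
  grid <- data.frame(n_trees = c(10L, 20L), learning_rate = 0.2,
                     max_depth = 2L, subsample = 1)
  gs1 <- grid_search_cv(d$x, d$y, grid = grid, folds = 4, seed = 6)
  set.seed(99)
  perm <- sample(80)
  gs2 <- grid_search_cv(d$x[perm, ], d$y[perm], grid = grid, folds = 4,
                        seed = 6)
  expect_equal(gs1$best, gs2$best)
  expect_equal(gs1$cv$mean_f1, gs2$cv$mean_f1)
})

test_that("accuracy is comparable to an independent boosting library", {
  skip_if_not_installed("xgboost")
  set.seed(13)
  n <- 300
  y <- rep(0:1, each = n / 2)
  x <- cbind(a = rnorm(n) + 1.5 * y, b = rnorm(n) + 0.5 * y,
             c = rnorm(n))
  tr <- c(1:100, 151:250); te <- setdiff(1:n, tr)
  ours <- circ_gbdt(x[tr, ], y[tr], n_trees = 100, learning_rate = 0.1,
                    max_depth = 3, seed = 1)
  acc_ours <- mean(predict(ours, x[te, ])$label == y[te])
  dtr <- xgboost::xgb.DMatrix(x[tr, ], label = y[tr])
  ref <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          max_depth = 3, eta = 0.1),
                            data = dtr, nrounds = 100)
  p_ref <- predict(ref, xgboost::xgb.DMatrix(x[te, ]))
  acc_ref <- mean(as.integer(p_ref >= 0.5) == y[te])
  expect_gte(acc_ours, acc_ref - 0.05)
})
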