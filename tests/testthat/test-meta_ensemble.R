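# Hand-built trees use the same node-table layout as the grower: a stump
# splitting column `col` at `thr`, with leaf positive-class frequencies qL/qR.
manual_stump <- function(col, thr, qL, qR) {
  list(feature = c(col, NA_integer_, NA_integer_),
       threshold = c(thr, NA_real_, NA_real_),
       left = c(2L, NA_integer_, NA_integer_),
       right = c(3L, NA_integer_, NA_integer_),
       n = c(10L, 5L, 5L), n_pos = c(5L, 0L, 5L), depth = c(0L, 1L, 1L),
       q1 = c(0.5, qL, qR))
}

test_that("voting takes the mode of per-tree argmax with ties to negative", {
  # 3 trees, votes [1, 1, 0] for v = 0.9
  forest3 <- fadel:::new_meta_forest(list(
    manual_stump(1L, 0.5, 0.1, 0.9),
    manual_stump(1L, 0.5, 0.2, 0.8),
    manual_stump(1L, 0.5, 0.9, 0.1)), width = 1L)
  out <- vote(forest3, matrix(0.9))
  expect_identical(out$label, 1L)
  expect_equal(out$score, mean(c(0.9, 0.8, 0.1)))
  # unanimous negative: label 0, score below one half
  out0 <- vote(forest3, matrix(0.1))
  expect_identical(out0$label, 0L)
  expect_lt(out0$score, 0.5)
  # even forest with a 50/50 split: negative class wins the tie
  forest2 <- fadel:::new_meta_forest(list(
    manual_stump(1L, 0.5, 0.1, 0.9),
    manual_stump(1L, 0.5, 0.9, 0.1)), width = 1L)
  expect_identical(vote(forest2, matrix(0.9))$label, 0L)
  # width mismatch is a validation error
  expect_error(vote(forest3, matrix(c(0.1, 0.2), nrow = 1)),
               class = "fadel_validation_error")
})

test_that("a leaf frequency of exactly one half votes negative", {
  forest <- fadel:::new_meta_forest(list(manual_stump(1L, 0.5, 0.5, 0.5)),
                                    width = 1L)
  expect_identical(vote(forest, matrix(0.9))$label, 0L)
})

test_that("tree order never changes labels or scores", {
  set.seed(21)
  M <- matrix(runif(200), ncol = 4)
  y <- rbinom(50, 1, plogis(6 * (M[, 1] - 0.5)))
  f <- fit_meta(M, y, n_trees = 15, seed = 3)
  probe <- matrix(runif(40), ncol = 4)
  base <- vote(f, probe)
  for (s in 1:5) {
    set.seed(s)
    fperm <- fadel:::new_meta_forest(sample(f$trees), seed = f$seed,
                                     mtry = f$mtry, width = f$width)
    out <- vote(fperm, probe)
    expect_identical(out$label, base$label)
    expect_equal(out$score, base$score)
  }
})

test_that("meta forest separates on a single informative column", {
  set.seed(8)
  y <- rep(c(0L, 1L), each = 30)
  M <- cbind(p1 = ifelse(y == 1, runif(60, 0.8, 1), runif(60, 0, 0.2)),
             p2 = runif(60), p3 = runif(60), p4 = runif(60))
  f <- fit_meta(M, y, n_trees = 25, seed = 5)
  out <- vote(f, M)
  expect_identical(out$label, y)                  # training accuracy 1
  expect_error(fit_meta(M, rep(1L, 60)), class = "fadel_fit_error")
  expect_error(fit_meta(M, y, n_trees = 0), class = "fadel_validation_error")
  # T = 1 reduces to that tree's argmax
  f1 <- fit_meta(M, y, n_trees = 1, seed = 9)
  q <- fadel:::.predict_gini_forest(f1$trees, M)
  expect_identical(vote(f1, M)$label, as.integer(q[, 1] > 0.5))
})

test_that("meta forest agrees with a reference forest on held-out ranking", {
  skip_if_not_installed("ranger")
  set.seed(13)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  M <- matrix(runif(4 * n), ncol = 4)
  M[, 1] <- plogis(rnorm(n, ifelse(y == 1, 1.5, -1.5)))
  M[, 2] <- plogis(rnorm(n, ifelse(y == 1, 1, -1)))
  tr <- 1:300; te <- 301:400
  f <- fit_meta(M[tr, ], y[tr], n_trees = 200, seed = 7)
  mine <- vote(f, M[te, ])$score
  rf <- ranger::ranger(y ~ ., data = data.frame(M[tr, ], y = factor(y[tr])),
                       probability = TRUE, num.trees = 200, seed = 7)
  ref <- predict(rf, data.frame(M[te, ]))$predictions[, "1"]
  a1 <- auroc_mw_oracle(y[te], mine)
  a2 <- auroc_mw_oracle(y[te], ref)
  expect_lt(abs(a1 - a2), 0.05)
})

test_that("direct mode equals in-sample probabilities; out-of-fold differs under memorization", {
  ds <- tiny_dataset(n = 60)
  discs <- fit_discretizers(ds, discretizer_config(min_samples_leaf = 2))
  v <- build_views(ds, discs)
  amf <- assemble_meta_features(v$nd, v$fd, ds$y, mode = "direct", seed = 5)
  expect_equal(amf$meta,
               base_probabilities(amf$learners, v$nd, v$fd))
  # determinism
  amf2 <- assemble_meta_features(v$nd, v$fd, ds$y, mode = "direct", seed = 5)
  expect_identical(amf$meta, amf2$meta)
  oof <- assemble_meta_features(v$nd, v$fd, ds$y, mode = "out_of_fold",
                                k = 3, seed = 5)
  oof2 <- assemble_meta_features(v$nd, v$fd, ds$y, mode = "out_of_fold",
                                 k = 3, seed = 5)
  expect_identical(oof$meta, oof2$meta)
  # the boosted slots memorize the training rows, so in-sample and
  # out-of-fold probabilities must part ways
  expect_gt(mean(abs(oof$meta - amf$meta)), 0.01)
  # fold assignment needs >= k members per class
  y_rare <- c(rep(0L, 58), 1L, 1L)
  expect_error(assemble_meta_features(v$nd, v$fd, y_rare, k = 3, seed = 1),
               class = "fadel_stratification_error")
})

test_that("separable scenario reaches full recall end to end", {
  ds <- generate(scenario_config("separable", n = 2000, prevalence = 0.05,
                                 seed = 7))
  sp <- stratified_split(ds, 0.8, seed = 7)
  model <- fit_fadel(sp$train, fadel_config(seed = 7))
  pred <- predict(model, sp$test)
  cc <- confusion(sp$test$y, pred$label)
  expect_equal(cc$TP / (cc$TP + cc$FN), 1.0)
  expect_gte(cc$TN / (cc$TN + cc$FP), 0.99)
  # predicting the training rows is consistent
  ptr <- predict(model, sp$train)
  cct <- confusion(sp$train$y, ptr$label)
  expect_equal(cct$TP / (cct$TP + cct$FN), 1.0)
  # single row in, single (label, score) out
  one <- predict(model, sp$test$X[1, , drop = FALSE])
  expect_equal(nrow(one), 1)
  # far out-of-range values are absorbed by the virtual boundaries
  far <- sp$test$X[1, , drop = FALSE]
  far[1, ] <- far[1, ] * 1e6
  expect_silent(predict(model, far))
  # schema errors name the missing column
  expect_error(predict(model, sp$test$X[, -1, drop = FALSE]),
               regexp = "marker_a", class = "fadel_validation_error")
})

test_that("null scenario yields no exploitable signal", {
  ds <- generate(scenario_config("null", n = 2000, prevalence = 0.05,
                                 seed = 19))
  sp <- stratified_split(ds, 0.8, seed = 19)
  model <- fit_fadel(sp$train, fadel_config(seed = 19, n_trees = 50))
  pred <- predict(model, sp$test)
  cc <- confusion(sp$test$y, pred$label)
  sens <- cc$TP / (cc$TP + cc$FN)
  spec <- cc$TN / (cc$TN + cc$FP)
  expect_lte(g_mean(sens, spec), 0.6)
})

test_that("the full pipeline is a pure function of data, config and seeds", {
  ds <- generate(scenario_config("clinical_like", n = 600, prevalence = 0.05,
                                 seed = 3))
  probe <- generate(scenario_config("clinical_like", n = 100,
                                    prevalence = 0.05, seed = 4))
  m1 <- fit_fadel(ds, fadel_config(seed = 23))
  m2 <- fit_fadel(ds, fadel_config(seed = 23))
  p1 <- predict(m1, probe)
  p2 <- predict(m2, probe)
  expect_identical(p1, p2)
})

test_that("a perfect oracle meta-feature drives test G-mean to one", {
  # all four base columns replaced by a single perfect probability column
  set.seed(31)
  y <- rep(c(0L, 1L), 100)
  M <- matrix(rep(ifelse(y == 1, 0.95, 0.05), 4), ncol = 4)
  f <- fit_meta(M[1:150, ], y[1:150], n_trees = 50, seed = 2)
  out <- vote(f, M[151:200, ])
  cc <- confusion(y[151:200], out$label)
  expect_equal(g_mean(cc$TP / (cc$TP + cc$FN), cc$TN / (cc$TN + cc$FP)), 1.0)
})

test_that("datasets without flagged features fail fast", {
  X <- cbind(a = c(0, 1, 0, 1, 0, 1), b = c(1, 1, 0, 0, 1, 0))
  sch <- data.frame(name = c("a", "b"), kind = "categorical",
                    discretize = FALSE, stringsAsFactors = FALSE)
  ds <- tabular_dataset(X, c(0L, 1L, 0L, 1L, 0L, 1L), sch)
  expect_error(fit_fadel(ds), class = "fadel_configuration_error")
})
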