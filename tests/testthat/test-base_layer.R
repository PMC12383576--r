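test_that("views share row order and split columns by type", {
  ds <- tiny_dataset()
  discs <- fit_discretizers(ds, discretizer_config(min_samples_leaf = 2))
  v <- build_views(ds, discs)
  expect_identical(v$nd$tag, "ND")
  expect_identical(v$fd$tag, "FD")
  expect_identical(colnames(v$nd$matrix), c("x1", "x2", "flag"))
  expect_identical(colnames(v$fd$matrix), c("x1", "x2", "flag"))
  expect_equal(nrow(v$nd$matrix), nrow(v$fd$matrix))
  # row order identity via a shared row-id probe column
  ds2 <- ds
  ds2$X <- cbind(ds$X, rowid = seq_len(nrow(ds$X)))
  ds2$schema <- rbind(ds$schema,
                      data.frame(name = "rowid", kind = "categorical",
                                 discretize = FALSE))
  ds2 <- tabular_dataset(ds2$X, ds$y, ds2$schema)
  v2 <- build_views(ds2, discs)
  expect_identical(v2$nd$matrix[, "rowid"], v2$fd$matrix[, "rowid"])
  # FD interval columns take integer values inside 1..K
  for (nm in c("x1", "x2"))
    expect_true(all(v$fd$matrix[, nm] %in%
                    seq_len(discs[[nm]]$n_intervals)))
})

test_that("target encoding matches hand evaluation and never leaks own label", {
  # first occurrence encodes to the prior
  te1 <- target_encode_fit_transform("A", 1, a = 1, p = 0.5,
                                     order = "dataset")
  expect_equal(te1$encoded, 0.5)
  # running means in dataset order
  te2 <- target_encode_fit_transform(c("A", "A", "A"), c(1, 0, 0),
                                     a = 1, p = 0.5, order = "dataset")
  expect_equal(te2$encoded[3], (1 + 0 + 0.5) / 3)
  te3 <- target_encode_fit_transform(c("A", "A", "A"), c(1, 1, 0),
                                     a = 1, p = 0.5, order = "dataset")
  expect_equal(te3$encoded[3], (2 + 0.5) / 3)
  # leave-one-out: flipping sample i's label leaves its own encoding fixed
  set.seed(4)
  codes <- sample(letters[1:3], 40, replace = TRUE)
  y <- rbinom(40, 1, 0.4)
  for (i in c(1, 17, 40)) {
    y2 <- y; y2[i] <- 1 - y2[i]
    e1 <- target_encode_fit_transform(codes, y, p = 0.4,
                                      order_seed = 9)$encoded
    e2 <- target_encode_fit_transform(codes, y2, p = 0.4,
                                      order_seed = 9)$encoded
    expect_equal(e1[i], e2[i])
  }
  # encodings bounded between 0 and 1 for p in [0,1]
  expect_true(all(te2$encoded >= 0 & te2$encoded <= 1))
  # a = 0 first occurrence falls back to the prior with a warning
  expect_warning(
    te0 <- target_encode_fit_transform(c("A", "A"), c(1, 0), a = 0, p = 0.3,
                                       order = "dataset"),
    regexp = "prior")
  expect_equal(te0$encoded[1], 0.3)
  # unseen category at apply time encodes to the prior
  expect_equal(target_encode_apply(te2$state, "ZZZ"), 0.5)
})

test_that("adaboost round reproduces the hand-worked reweighting", {
  rd <- adaboost_round(rep(0.25, 4), c(1, 1, 1, 0), c(1, 1, 1, 1))
  expect_equal(rd$epsilon, 0.25)
  expect_equal(rd$alpha, 0.5 * log(3))
  expect_equal(rd$w_next, c(1/6, 1/6, 1/6, 1/2))
  expect_equal(sum(rd$w_next), 1, tolerance = 1e-12)
  # epsilon = 0.5 is the log(1) fixed point
  rd2 <- adaboost_round(c(0.5, 0.5), c(1, 0), c(0, 0))
  expect_equal(rd2$epsilon, 0.5)
  expect_equal(rd2$alpha, 0)
  expect_equal(rd2$w_next, c(0.5, 0.5))
  # perfect learner: clipped alpha
  rd3 <- adaboost_round(rep(0.25, 4), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(rd3$epsilon, 0)
  expect_equal(rd3$alpha, 0.5 * log((1 - 1e-10) / 1e-10))
  # misclassified sample's weight strictly grows past 1/2 > 1/4
  expect_gt(rd$w_next[4], 0.25)
  expect_equal(rd$w_next[4], 0.5)
})

test_that("adaboost trainer conserves weights and halts sensibly", {
  set.seed(11)
  X <- cbind(a = sample(1:4, 80, TRUE), b = sample(1:3, 80, TRUE))
  y <- rbinom(80, 1, plogis(X[, 1] - 2.5))
  model <- fadel:::fit_adaboost(X, y, n_rounds = 50)
  expect_lte(length(model$alphas), 50)
  expect_true(all(model$epsilons < 0.5))
  # weight conservation is internal; re-run the rounds manually
  w <- rep(1 / 80, 80)
  for (t in seq_along(model$stumps)) {
    h <- fadel:::stump_predict(model$stumps[[t]], X)
    rd <- adaboost_round(w, h, y)
    expect_equal(sum(rd$w_next), 1, tolerance = 1e-12)
    w <- rd$w_next
  }
  # separable single-column data: one stump suffices, training recall 1
  Xs <- cbind(z = c(1, 1, 2, 5, 6, 7))
  ys <- c(0, 0, 0, 1, 1, 1)
  ms <- fadel:::fit_adaboost(Xs, ys, n_rounds = 50)
  expect_equal(ms$epsilons[1], 0)
  s <- fadel:::adaboost_score(ms, Xs)
  expect_equal(as.integer(plogis(s) > 0.5), ys)
})

test_that("routing is enforced and probabilities respect the sigmoid contract", {
  ds <- tiny_dataset(n = 80)
  discs <- fit_discretizers(ds, discretizer_config(min_samples_leaf = 2))
  v <- build_views(ds, discs)
  # swapped views raise a tag mismatch, no silent cross-feeding
  expect_error(fit_base_models(v$fd, v$nd, ds$y),
               class = "fadel_view_mismatch_error")
  learners <- fit_base_models(v$nd, v$fd, ds$y, seed = 2)
  expect_length(learners, 4)
  expect_identical(vapply(learners, function(l) l$view_tag, character(1)),
                   c("ND", "ND", "FD", "FD"))
  P <- base_probabilities(learners, v$nd, v$fd)
  expect_equal(dim(P), c(80L, 4L))
  expect_true(all(P > 0 & P < 1))
  # probability = sigmoid(raw score) for every slot
  for (m in 1:4) {
    view <- if (learners[[m]]$view_tag == "ND") v$nd else v$fd
    expect_equal(P[, m], plogis(learner_raw_score(learners[[m]], view)),
                 tolerance = 1e-12)
  }
  # a learner refuses the wrong view
  expect_error(learner_probability(learners[[1]], v$fd),
               class = "fadel_view_mismatch_error")
})

test_that("logistic contract stub: zero scores give probability one half", {
  v <- make_view("ND", cbind(x = c(-1, 1)))
  lrn <- structure(list(kind = "logistic", view_tag = "ND", slot = 1L,
                        state = list(coef = c(`(Intercept)` = 0, x = 0)),
                        columns = "x"), class = "fadel_learner")
  expect_equal(learner_probability(lrn, v), c(0.5, 0.5))
  lrn$state$coef <- c(`(Intercept)` = log(3), x = 0)
  expect_equal(learner_probability(lrn, v), c(0.75, 0.75))
})

test_that("separable data trains every slot to full recall; shuffled labels do not", {
  set.seed(5)
  n <- 1000
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(u = rnorm(n, ifelse(y == 1, 6, 0)),
             v = rnorm(n, ifelse(y == 1, -6, 0)))
  ds <- tabular_dataset(X, y)
  discs <- fit_discretizers(ds)
  vw <- build_views(ds, discs)
  learners <- fit_base_models(vw$nd, vw$fd, y, seed = 3)
  P <- base_probabilities(learners, vw$nd, vw$fd)
  for (m in 1:4)
    expect_equal(sum(P[y == 1, m] > 0.5), n / 2)
  # permutation null: mean class-1 probability tracks prevalence
  set.seed(6)
  ysh <- sample(y)
  dsh <- tabular_dataset(X, ysh)
  dsc <- fit_discretizers(dsh)
  vsh <- build_views(dsh, dsc)
  lsh <- fit_base_models(vsh$nd, vsh$fd, ysh, seed = 3)
  Psh <- base_probabilities(lsh, vsh$nd, vsh$fd)
  expect_lt(abs(mean(Psh) - mean(ysh)), 0.05)
})

test_that("refits with identical seeds serialize identically", {
  ds <- tiny_dataset(n = 100)
  discs <- fit_discretizers(ds, discretizer_config(min_samples_leaf = 2))
  v <- build_views(ds, discs)
  l1 <- fit_base_models(v$nd, v$fd, ds$y, seed = 17)
  l2 <- fit_base_models(v$nd, v$fd, ds$y, seed = 17)
  for (m in 1:4)
    expect_identical(
      jsonlite::toJSON(fadel:::learner_to_json_obj(l1[[m]]), auto_unbox = TRUE,
                       digits = NA),
      jsonlite::toJSON(fadel:::learner_to_json_obj(l2[[m]]), auto_unbox = TRUE,
                       digits = NA))
})
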