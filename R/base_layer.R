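#' Build the raw (ND) and discretized (FD) feature views
#'
#' The ND view carries the raw continuous columns plus categorical columns;
#' the FD view carries the 1-based interval indices of the flagged columns
#' plus the same categorical columns unchanged (categoricals have one natural
#' form and are passed to both views). Row order is identical across views.
#'
#' @param ds a [tabular_dataset()].
#' @param discretizers named list of fitted `feature_discretizer`s covering
#'   every flagged column.
#' @return list with `nd` and `fd`, each a `feature_view` (fields `tag`,
#'   `matrix`).
#' @export
build_views <- function(ds, discretizers) {
  dv <- transform_dataset(ds, discretizers)
  cat_cols <- ds$schema$name[ds$schema$kind == "categorical"]
  nd_mat <- ds$X
  fd_mat <- dv$Z
  if (length(cat_cols)) {
    fd_mat <- cbind(fd_mat, ds$X[, cat_cols, drop = FALSE])
  }
  storage.mode(fd_mat) <- "double"
  list(
    nd = structure(list(tag = "ND", matrix = nd_mat), class = "feature_view"),
    fd = structure(list(tag = "FD", matrix = fd_mat), class = "feature_view")
  )
}

check_view <- function(view, expected_tag) {
  if (!inherits(view, "feature_view") || !identical(view$tag, expected_tag))
    fadel_error(sprintf("expected a '%s' feature view, got '%s'",
                        expected_tag,
                        if (inherits(view, "feature_view")) view$tag
                        else class(view)[1]),
                "fadel_view_mismatch_error")
  invisible(view)
}

#' Default base-learner routing plan
#'
#' Four ordered slots, each a learner kind bound to one feature view. The
#' slot order is fixed and defines the layout of the meta-feature vector:
#' two gradient-boosted learners on the raw view (depthwise and leaf-wise
#' histogram growth), an ordered-target-encoded booster on the interval
#' view, and AdaBoost decision stumps on the interval view.
#'
#' @return list of class `routing_plan`; each slot has `kind`, `view` and
#'   `params`.
#' @export
default_routing_plan <- function() {
  structure(list(
    list(kind = "gbdt", view = "ND", params = list(variant = "depthwise")),
    list(kind = "gbdt", view = "ND", params = list(variant = "lossguide")),
    list(kind = "target_encoded_gbdt", view = "FD", params = list()),
    list(kind = "adaboost", view = "FD", params = list())
  ), class = "routing_plan")
}

# ---------------------------------------------------------------------------
# Ordered target encoding (smoothed running mean of the label over strictly
# preceding samples of the same category)

#' Ordered target encoding of one categorical column
#'
#' Encodes each sample as
#' `(sum of labels of preceding same-category samples + a * p) /
#'  (count of preceding same-category samples + a)`,
#' where "preceding" refers to a seeded random traversal order (ordered-
#' boosting style) or, optionally, the dataset order. A sample's own label
#' never contributes to its encoding; the first occurrence of a category
#' encodes to exactly the prior `p` when `a > 0`. With `a = 0` a first
#' occurrence is 0/0 and returns `p` by convention (with a warning).
#'
#' @param codes vector of category codes (finite values or characters).
#' @param y binary labels (0/1).
#' @param a nonnegative smoothing parameter.
#' @param p prior probability in `[0, 1]`.
#' @param order_seed integer seed for the traversal permutation.
#' @param order `"permutation"` (default) or `"dataset"`.
#' @return list with `encoded` (numeric vector) and `state` (a
#'   `target_encoder_state` holding full-data per-category statistics for
#'   encoding new samples).
#' @export
target_encode_fit_transform <- function(codes, y, a = 1, p = mean(y),
                                        order_seed = 1L,
                                        order = c("permutation", "dataset")) {
  order <- match.arg(order)
  if (a < 0) validation_error("smoothing parameter a must be >= 0")
  if (anyNA(codes)) validation_error("codes must be finite/non-missing")
  n <- length(codes)
  if (n != length(y)) validation_error("codes and y lengths differ")
  key <- as.character(codes)
  if (order == "permutation") {
    set.seed(order_seed)
    perm <- sample.int(n)
  } else {
    perm <- seq_len(n)
  }
  encoded <- numeric(n)
  warned <- FALSE
  for (lev in unique(key)) {
    idx <- perm[key[perm] == lev]           # rows of this level, in traversal order
    prior_sum <- c(0, cumsum(y[idx]))[seq_along(idx)]
    prior_cnt <- seq_along(idx) - 1
    denom <- prior_cnt + a
    val <- ifelse(denom == 0, p, (prior_sum + a * p) / denom)
    if (any(denom == 0) && !warned && a == 0) {
      warning("a = 0: first category occurrences encode to the prior p")
      warned <- TRUE
    }
    encoded[idx] <- val
  }
  stats_tab <- tapply(y, key, function(v) c(sum = sum(v), count = length(v)))
  state <- structure(list(
    a = a, p = p, order = order, order_seed = as.integer(order_seed),
    categories = names(stats_tab),
    sum_y = vapply(stats_tab, `[[`, numeric(1), "sum"),
    count = vapply(stats_tab, `[[`, numeric(1), "count")
  ), class = "target_encoder_state")
  list(encoded = encoded, state = state)
}

#' Apply a fitted target encoder to new codes
#'
#' Uses the full-training-data per-category statistics; unseen categories
#' encode to the prior `p`.
#'
#' @param state a `target_encoder_state` from [target_encode_fit_transform()].
#' @param codes vector of category codes.
#' @return numeric vector of encodings.
#' @export
target_encode_apply <- function(state, codes) {
  key <- as.character(codes)
  i <- match(key, state$categories)
  s <- ifelse(is.na(i), 0, state$sum_y[i])
  cnt <- ifelse(is.na(i), 0, state$count[i])
  denom <- cnt + state$a
  ifelse(denom == 0, state$p, (s + state$a * state$p) / denom)
}

# ---------------------------------------------------------------------------
# AdaBoost with depth-1 stumps on the FD view

#' One AdaBoost reweighting round
#'
#' Given simplex weights `w`, weak-learner 0/1 predictions and 0/1 labels,
#' computes the weighted error `epsilon = sum(w * [h != y])`, the learner
#' weight `alpha = 0.5 * log((1 - epsilon) / epsilon)` and the renormalized
#' next weights `w * exp(-alpha * yt * ht)` with labels and predictions
#' mapped to -1/+1. A perfect round (`epsilon = 0`) has its alpha clipped at
#' `0.5 * log((1 - 1e-10) / 1e-10)`; `epsilon >= 0.5` signals that boosting
#' should stop (the round is discarded by the trainer).
#'
#' @param w numeric weights summing to 1.
#' @param h_pred 0/1 predictions of the weak learner.
#' @param y 0/1 labels.
#' @return list with `epsilon`, `alpha`, `w_next`.
#' @export
adaboost_round <- function(w, h_pred, y) {
  if (abs(sum(w) - 1) > 1e-8)
    validation_error("weights must sum to 1")
  if (!all(h_pred %in% c(0, 1)) || !all(y %in% c(0, 1)))
    validation_error("predictions and labels must be 0/1")
  eps_min <- 1e-10
  epsilon <- sum(w * (h_pred != y))
  if (epsilon <= 0) {
    alpha <- 0.5 * log((1 - eps_min) / eps_min)
  } else {
    alpha <- 0.5 * log((1 - epsilon) / epsilon)
  }
  yt <- 2 * y - 1
  ht <- 2 * h_pred - 1
  w_next <- w * exp(-alpha * yt * ht)
  w_next <- w_next / sum(w_next)
  list(epsilon = epsilon, alpha = alpha, w_next = w_next)
}

# Best weighted decision stump over the columns of X: predicts 1 on one side
# of a threshold. Candidates are midpoints between consecutive distinct
# values per column; both polarities are tried; ties keep the first
# candidate (columns ascending, thresholds ascending, 'greater' polarity
# first).
best_stump <- function(X, y, w) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2L) next
    thrs <- xs[-length(xs)] + diff(xs) / 2
    for (thr in thrs) {
      pred_gt <- as.integer(X[, j] > thr)    # polarity: 1 above threshold
      err_gt <- sum(w * (pred_gt != y))
      for (pol in c("greater", "lesser")) {
        err <- if (pol == "greater") err_gt else 1 - err_gt
        if (is.null(best) || err < best$err - 1e-12) {
          best <- list(col = j, threshold = thr, polarity = pol, err = err)
        }
      }
    }
  }
  best
}

stump_predict <- function(stump, X) {
  gt <- X[, stump$col] > stump$threshold
  if (stump$polarity == "greater") as.integer(gt) else as.integer(!gt)
}

fit_adaboost <- function(X, y, n_rounds = 50L, learning_rate = 1) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  epsilons <- numeric(0)
  for (t in seq_len(n_rounds)) {
    st <- best_stump(X, y, w)
    if (is.null(st)) break                  # no splittable column
    h <- stump_predict(st, X)
    rd <- adaboost_round(w, h, y)
    if (rd$epsilon >= 0.5) break            # discard round, stop boosting
    alphas <- c(alphas, learning_rate * rd$alpha)
    epsilons <- c(epsilons, rd$epsilon)
    stumps[[length(stumps) + 1L]] <- st
    if (rd$epsilon <= 0) break              # perfect learner, halt
    w <- rd$w_next
  }
  structure(list(stumps = stumps, alphas = alphas, epsilons = epsilons,
                 n_rounds = n_rounds, learning_rate = learning_rate,
                 columns = colnames(X)),
            class = "adaboost_state")
}

adaboost_score <- function(model, X) {
  s <- numeric(nrow(X))
  for (t in seq_along(model$stumps)) {
    ht <- 2 * stump_predict(model$stumps[[t]], X) - 1
    s <- s + model$alphas[t] * ht
  }
  s
}

# ---------------------------------------------------------------------------
# Learner contract: every fitted learner exposes raw_score() in R and
# probability() = sigmoid(raw_score). Learners that natively emit
# probabilities report raw_score = logit(p).

default_gbdt_params <- function(variant = "depthwise") {
  if (variant == "lossguide") {
    list(nrounds = 100L, eta = 0.1, max_depth = 0L, max_leaves = 31L,
         gamma = 0, lambda = 1, tree_method = "hist",
         grow_policy = "lossguide")
  } else {
    list(nrounds = 100L, eta = 0.1, max_depth = 6L, max_leaves = 0L,
         gamma = 0, lambda = 1, tree_method = "exact",
         grow_policy = "depthwise")
  }
}

fit_xgb <- function(X, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      eta = params$eta, max_depth = params$max_depth,
      max_leaves = params$max_leaves,
      gamma = params$gamma, lambda = params$lambda,
      tree_method = params$tree_method, grow_policy = params$grow_policy,
      nthread = 1L, seed = seed
    ),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
}

xgb_prob <- function(bst, X) {
  p <- predict(bst, xgboost::xgb.DMatrix(X))
  pmin(pmax(p, 1e-15), 1 - 1e-15)
}

#' Fit one base learner slot
#'
#' Learner kinds: `"gbdt"` (gradient-boosted trees on the raw view;
#' `variant` `"depthwise"` or `"lossguide"` selects exact depthwise or
#' histogram leaf-wise growth), `"target_encoded_gbdt"` (ordered target
#' encoding of every FD column followed by a boosted learner with 100
#' iterations, learning rate 0.1, depth 6), `"adaboost"` (50 depth-1 stumps)
#' and `"logistic"` (a plain logistic model; a lightweight stand-in used to
#' exercise the contract in tests).
#'
#' @param kind learner kind.
#' @param view a `feature_view` matching the slot's routing.
#' @param y binary labels.
#' @param params kind-specific parameter list (merged over defaults).
#' @param seed integer seed.
#' @param slot slot index recorded in the fitted learner.
#' @return a fitted `fadel_learner`.
#' @export
fit_learner <- function(kind, view, y, params = list(), seed = 1L,
                        slot = NA_integer_) {
  if (!inherits(view, "feature_view"))
    validation_error("view must be a feature_view")
  X <- view$matrix
  if (ncol(X) == 0L)
    fadel_error(sprintf("slot %s (%s): routed view '%s' has no columns",
                        slot, kind, view$tag), "fadel_configuration_error")
  if (nrow(X) != length(y)) validation_error("view/label length mismatch")
  if (length(unique(y)) < 2L)
    fadel_error("both classes required to fit a base learner",
                "fadel_fit_error")
  state <- switch(kind,
    gbdt = {
      pp <- modifyList(default_gbdt_params(params$variant %||% "depthwise"),
                       params[setdiff(names(params), "variant")])
      list(booster = fit_xgb(X, y, pp, seed), params = pp)
    },
    target_encoded_gbdt = {
      a <- params$a %||% 1
      p <- params$p %||% mean(y)
      fd_as <- params$fd_as %||% "categorical"
      if (fd_as == "categorical") {
        enc_states <- list()
        E <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
        for (j in seq_len(ncol(X))) {
          te <- target_encode_fit_transform(
            X[, j], y, a = a, p = p,
            order_seed = derive_seed(seed, paste0("te", j)))
          E[, j] <- te$encoded
          enc_states[[j]] <- te$state
        }
      } else {
        enc_states <- NULL
        E <- X
      }
      pp <- modifyList(list(nrounds = 100L, eta = 0.1, max_depth = 6L,
                            max_leaves = 0L, gamma = 0, lambda = 1,
                            tree_method = "exact",
                            grow_policy = "depthwise"),
                       params[intersect(names(params),
                                        c("nrounds", "eta", "max_depth"))])
      list(booster = fit_xgb(E, y, pp, seed), encoders = enc_states,
           fd_as = fd_as, params = pp)
    },
    adaboost = {
      fit_adaboost(X, y, n_rounds = params$n_rounds %||% 50L,
                   learning_rate = params$learning_rate %||% 1)
    },
    logistic = {
      df <- as.data.frame(X)
      names(df) <- paste0("v", seq_len(ncol(X)))
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial()))
      cf <- stats::coef(fit)
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    validation_error(sprintf("unknown learner kind '%s'", kind))
  )
  structure(list(kind = kind, view_tag = view$tag, slot = slot,
                 seed = as.integer(seed), state = state,
                 columns = colnames(X)),
            class = "fadel_learner")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raw score and probability of a fitted base learner
#'
#' `learner_probability()` always equals `sigmoid(learner_raw_score())`:
#' learners that natively emit probabilities report `raw_score = logit(p)`.
#'
#' @param learner a fitted `fadel_learner`.
#' @param view a `feature_view` whose tag matches the learner's routing.
#' @return numeric vector (one value per row).
#' @export
learner_raw_score <- function(learner, view) {
  check_view(view, learner$view_tag)
  X <- view$matrix[, learner$columns, drop = FALSE]
  switch(learner$kind,
    gbdt = qlogis(xgb_prob(learner$state$booster, X)),
    target_encoded_gbdt = {
      if (identical(learner$state$fd_as, "categorical")) {
        E <- X
        for (j in seq_len(ncol(X)))
          E[, j] <- target_encode_apply(learner$state$encoders[[j]], X[, j])
      } else E <- X
      qlogis(xgb_prob(learner$state$booster, E))
    },
    adaboost = adaboost_score(learner$state, X),
    logistic = unname(drop(cbind(1, X) %*% learner$state$coef))
  )
}

#' @rdname learner_raw_score
#' @export
learner_probability <- function(learner, view) {
  sigmoid(learner_raw_score(learner, view))
}

#' Fit all base-model slots of a routing plan
#'
#' @param nd_view,fd_view the `feature_view`s from [build_views()].
#' @param y binary labels.
#' @param plan a routing plan, default [default_routing_plan()].
#' @param seed master seed; each slot derives its own stream.
#' @param slot_params optional list of per-slot parameter overrides.
#' @return list of fitted `fadel_learner`s in slot order.
#' @export
fit_base_models <- function(nd_view, fd_view, y,
                            plan = default_routing_plan(), seed = 1L,
                            slot_params = NULL) {
  check_view(nd_view, "ND")
  check_view(fd_view, "FD")
  if (nrow(nd_view$matrix) != nrow(fd_view$matrix))
    fadel_error("ND and FD views disagree on row count",
                "fadel_internal_error")
  lapply(seq_along(plan), function(m) {
    slot <- plan[[m]]
    view <- if (slot$view == "ND") nd_view else fd_view
    params <- modifyList(slot$params %||% list(),
                         (slot_params[[m]] %||% list()))
    fit_learner(slot$kind, view, y, params = params,
                seed = derive_seed(seed, paste0("slot", m)), slot = m)
  })
}

#' Probability matrix of the base layer
#'
#' Column `m` holds slot `m`'s predicted probabilities (all in (0,1)),
#' in routing-plan order.
#'
#' @param learners list of fitted `fadel_learner`s.
#' @param nd_view,fd_view the `feature_view`s of the rows to score.
#' @return N x M numeric matrix.
#' @export
base_probabilities <- function(learners, nd_view, fd_view) {
  check_view(nd_view, "ND")
  check_view(fd_view, "FD")
  cols <- lapply(learners, function(lrn) {
    view <- if (lrn$view_tag == "ND") nd_view else fd_view
    learner_probability(lrn, view)
  })
  P <- do.call(cbind, cols)
  colnames(P) <- paste0("p", seq_along(learners))
  P
}
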