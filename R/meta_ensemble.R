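#' FADEL configuration
#'
#' Collects every tunable of the pipeline: the discretizer constraints, the
#' base-layer settings, the meta-forest size and the meta-feature mode.
#' Defaults: depth-3 / 8-leaf discretization trees, the four-slot routing
#' plan, a 100-tree meta-forest, out-of-fold meta-features with k = 5
#' (in-sample `"direct"` mode is available and recorded in the model).
#'
#' @param discretizer a [discretizer_config()].
#' @param n_trees meta-forest size.
#' @param meta_mode `"out_of_fold"` (default) or `"direct"`.
#' @param k folds for out-of-fold meta-features.
#' @param seed master integer seed; every random stream derives from it.
#' @param slot_params optional per-slot base-learner overrides.
#' @param mtry features tried per meta-forest split.
#' @return list of class `fadel_config`.
#' @export
fadel_config <- function(discretizer = discretizer_config(),
                         n_trees = 100L,
                         meta_mode = c("out_of_fold", "direct"),
                         k = 5L, seed = 1L, slot_params = NULL,
                         mtry = 2L) {
  meta_mode <- match.arg(meta_mode)
  if (n_trees < 1L) validation_error("n_trees must be >= 1")
  structure(list(discretizer = discretizer, n_trees = as.integer(n_trees),
                 meta_mode = meta_mode, k = as.integer(k),
                 seed = as.integer(seed), slot_params = slot_params,
                 mtry = as.integer(mtry)),
            class = "fadel_config")
}

#' Assemble the base-layer probability meta-features
#'
#' In `"direct"` mode the base learners are fitted on all rows and the
#' meta-features are their in-sample probabilities. In `"out_of_fold"` mode
#' rows are split into k stratified folds and row i's probability vector
#' comes from learners not trained on row i's fold, which removes the
#' memorization leak of the direct reading; the returned learners are then
#' refit on all rows for deployment.
#'
#' @param nd_view,fd_view `feature_view`s of the training rows.
#' @param y binary labels.
#' @param plan routing plan.
#' @param mode `"direct"` or `"out_of_fold"`.
#' @param k folds (out-of-fold mode), `>= 2`, with at least k members per
#'   class.
#' @param seed integer seed.
#' @param slot_params optional per-slot overrides.
#' @return list with `meta` (N x 4 matrix) and `learners` (final learners
#'   fitted on all rows).
#' @export
assemble_meta_features <- function(nd_view, fd_view, y,
                                   plan = default_routing_plan(),
                                   mode = c("out_of_fold", "direct"),
                                   k = 5L, seed = 1L, slot_params = NULL) {
  mode <- match.arg(mode)
  learners <- fit_base_models(nd_view, fd_view, y, plan,
                              seed = derive_seed(seed, "final"),
                              slot_params = slot_params)
  if (mode == "direct") {
    meta <- base_probabilities(learners, nd_view, fd_view)
    return(list(meta = meta, learners = learners))
  }
  folds <- stratified_folds(y, k, derive_seed(seed, "folds"))
  meta <- matrix(NA_real_, length(y), length(plan))
  for (f in seq_len(k)) {
    hold <- folds == f
    nd_tr <- structure(list(tag = "ND",
                            matrix = nd_view$matrix[!hold, , drop = FALSE]),
                       class = "feature_view")
    fd_tr <- structure(list(tag = "FD",
                            matrix = fd_view$matrix[!hold, , drop = FALSE]),
                       class = "feature_view")
    fold_learners <- fit_base_models(nd_tr, fd_tr, y[!hold], plan,
                                     seed = derive_seed(seed, paste0("fold", f)),
                                     slot_params = slot_params)
    nd_ho <- structure(list(tag = "ND",
                            matrix = nd_view$matrix[hold, , drop = FALSE]),
                       class = "feature_view")
    fd_ho <- structure(list(tag = "FD",
                            matrix = fd_view$matrix[hold, , drop = FALSE]),
                       class = "feature_view")
    meta[hold, ] <- base_probabilities(fold_learners, nd_ho, fd_ho)
  }
  colnames(meta) <- paste0("p", seq_along(plan))
  list(meta = meta, learners = learners)
}

new_meta_forest <- function(trees, seed = NA_integer_, mtry = 2L,
                            width = NA_integer_) {
  structure(list(trees = trees, n_trees = length(trees),
                 seed = as.integer(seed), mtry = as.integer(mtry),
                 width = as.integer(width)),
            class = "meta_forest")
}

#' Fit the random-forest meta-model
#'
#' Grows `n_trees` Gini trees on bootstrap resamples of the meta-feature
#' rows with `mtry` random feature candidates per split; trees grow until
#' leaves are pure or hold fewer than 2 samples, and each leaf stores the
#' class-frequency pair of its training samples.
#'
#' @param meta_features N x M numeric matrix of base-layer probabilities.
#' @param y binary labels (both classes required).
#' @param n_trees number of trees (default 100).
#' @param seed integer seed.
#' @param mtry features tried per split (default 2 of the 4 columns).
#' @return a `meta_forest`.
#' @export
fit_meta <- function(meta_features, y, n_trees = 100L, seed = 1L,
                     mtry = 2L) {
  if (n_trees < 1L) validation_error("n_trees must be >= 1")
  meta_features <- as.matrix(meta_features)
  n <- nrow(meta_features)
  if (n < 2L) validation_error("need at least 2 rows")
  if (length(unique(y)) < 2L)
    fadel_error("both classes required to fit the meta-forest",
                "fadel_fit_error")
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- .grow_gini_tree(meta_features, as.integer(y), boot,
                                  max_depth = 100000L, max_leaves = n,
                                  min_leaf = 1L, min_split = 2L,
                                  mtry = as.integer(mtry))
  }
  new_meta_forest(trees, seed = seed, mtry = mtry,
                  width = ncol(meta_features))
}

#' Majority-vote prediction of the meta-forest
#'
#' Each tree routes the probability vector to a leaf and votes for the
#' class with the larger stored frequency (a 50/50 leaf votes negative);
#' the label is the modal vote, with an even-split tie going to the
#' negative class. The continuous score is the mean over trees of the leaf
#' frequency of the positive class, suitable for ROC/PR curves.
#'
#' @param forest a `meta_forest`.
#' @param v a probability vector (length = training width) or an N x M
#'   matrix of probability vectors.
#' @return data frame with `label` (0/1 integer) and `score` in `[0, 1]`.
#' @export
vote <- function(forest, v) {
  V <- if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  if (!is.na(forest$width) && ncol(V) != forest$width)
    validation_error(sprintf("probability vector has %d columns, forest expects %d",
                             ncol(V), forest$width))
  Q <- .predict_gini_forest(forest$trees, V)     # N x T leaf q(y=1)
  votes1 <- rowSums(Q > 0.5)                     # per-tree argmax, ties -> 0
  label <- as.integer(votes1 > forest$n_trees / 2)
  score <- rowMeans(Q)
  data.frame(label = label, score = score)
}

#' Fit the full FADEL model
#'
#' End-to-end training on a labelled dataset: fits one CART discretizer per
#' flagged continuous feature, builds the raw and interval views, fits the
#' four routed base learners, assembles the probability meta-features
#' (out-of-fold by default) and fits the random-forest meta-model.
#'
#' @param ds a [tabular_dataset()] with at least one flagged continuous
#'   feature and both classes present.
#' @param config a [fadel_config()].
#' @return a `fadel_model` holding discretizers, routing plan, fitted base
#'   learners, meta-forest, config and seeds; [predict.fadel_model()] is a
#'   pure function of (model, rows).
#' @export
fit_fadel <- function(ds, config = fadel_config()) {
  if (!inherits(ds, "tabular_dataset"))
    validation_error("ds must be a tabular_dataset")
  if (!any(ds$schema$discretize))
    fadel_error("at least one feature must be flagged for discretization",
                "fadel_configuration_error")
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "fadel_error")) stop(e)
      fadel_error(sprintf("[%s] %s", name, conditionMessage(e)),
                  "fadel_stage_error")
    })
  }
  discretizers <- stage("discretize",
    fit_discretizers(ds, config$discretizer))
  views <- stage("views", build_views(ds, discretizers))
  plan <- default_routing_plan()
  mf <- stage("base_layer",
    assemble_meta_features(views$nd, views$fd, ds$y, plan,
                           mode = config$meta_mode, k = config$k,
                           seed = derive_seed(seed, "base"),
                           slot_params = config$slot_params))
  forest <- stage("meta",
    fit_meta(mf$meta, ds$y, n_trees = config$n_trees,
             seed = derive_seed(seed, "meta"), mtry = config$mtry))
  structure(list(
    format_version = "1",
    discretizers = discretizers,
    plan = plan,
    learners = mf$learners,
    meta_forest = forest,
    config = config,
    schema = ds$schema
  ), class = "fadel_model")
}

#' @export
print.fadel_model <- function(x, ...) {
  ks <- vapply(x$discretizers, function(d) d$n_intervals, integer(1))
  cat(sprintf(
    "<fadel_model> %d discretized features (K: %s), %d base slots, %d-tree meta-forest, meta_mode=%s\n",
    length(x$discretizers), paste(ks, collapse = "/"),
    length(x$learners), x$meta_forest$n_trees, x$config$meta_mode))
  invisible(x)
}

#' Predict with a fitted FADEL model
#'
#' Applies the stored discretizers (values outside the training range are
#' absorbed by the unbounded end intervals), computes the four base-learner
#' probabilities and aggregates them by meta-forest majority vote.
#'
#' @param object a `fadel_model`.
#' @param newdata a [tabular_dataset()] (labels ignored if present) or a
#'   numeric matrix/data frame with the model's feature columns.
#' @param ... unused.
#' @return data frame with one row per input row: `label` (0/1) and `score`
#'   in `[0, 1]`.
#' @export
predict.fadel_model <- function(object, newdata, ...) {
  M <- if (inherits(newdata, "tabular_dataset")) newdata$X
       else as.matrix(newdata)
  missing <- setdiff(object$schema$name, colnames(M))
  if (length(missing))
    validation_error(sprintf("input is missing model column(s): %s",
                             paste(missing, collapse = ", ")))
  M <- M[, object$schema$name, drop = FALSE]
  ds <- tabular_dataset(M, rep(0L, nrow(M)), object$schema)
  views <- build_views(ds, object$discretizers)
  P <- base_probabilities(object$learners, views$nd, views$fd)
  vote(object$meta_forest, P)
}
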