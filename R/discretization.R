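#' Discretizer configuration
#'
#' Constraints on the per-feature CART tree used for supervised
#' discretization. The defaults are the package defaults for clinical-like
#' tabular data: maximum depth 3, at most 8 leaf nodes, at least 5 samples
#' per leaf, at least 2 samples to split, Gini impurity. With depth `D` and
#' leaf budget `L` the number of intervals `K` obeys `K <= min(2^D, L)`.
#'
#' @param max_depth positive integer, maximum tree depth.
#' @param max_leaf_nodes positive integer >= 2, leaf-node budget (best-first
#'   growth: the pending split with the largest impurity decrease is realized
#'   first).
#' @param min_samples_leaf positive integer.
#' @param min_samples_split positive integer.
#' @return list of class `discretizer_config`.
#' @export
discretizer_config <- function(max_depth = 3L, max_leaf_nodes = 8L,
                               min_samples_leaf = 5L,
                               min_samples_split = 2L) {
  if (max_depth < 1L) validation_error("max_depth must be >= 1")
  if (max_leaf_nodes < 2L) validation_error("max_leaf_nodes must be >= 2")
  if (min_samples_leaf < 1L) validation_error("min_samples_leaf must be >= 1")
  if (min_samples_split < 1L) validation_error("min_samples_split must be >= 1")
  structure(list(
    max_depth = as.integer(max_depth),
    max_leaf_nodes = as.integer(max_leaf_nodes),
    min_samples_leaf = as.integer(min_samples_leaf),
    min_samples_split = as.integer(min_samples_split),
    criterion = "gini"
  ), class = "discretizer_config")
}

new_feature_discretizer <- function(feature_name, thresholds, config,
                                    method = "cart") {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) && any(!is.finite(thresholds)))
    fadel_error("thresholds must be finite", "fadel_internal_error")
  if (is.unsorted(thresholds, strictly = TRUE))
    fadel_error("thresholds must be strictly increasing",
                "fadel_internal_error")
  structure(list(
    feature_name = feature_name,
    thresholds = thresholds,
    n_intervals = length(thresholds) + 1L,
    method = method,
    config = config
  ), class = "feature_discretizer")
}

#' @export
print.feature_discretizer <- function(x, ...) {
  cat(sprintf("<feature_discretizer> '%s' (%s): K = %d intervals\n",
              x$feature_name, x$method, x$n_intervals))
  if (length(x$thresholds))
    cat("  thresholds:", paste(format(x$thresholds, digits = 6),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Fit a supervised CART discretizer for one continuous feature
#'
#' Grows a single-feature CART classifier on `(x, y)` under the configured
#' depth, leaf-count and leaf-size constraints (Gini criterion, candidate
#' thresholds at midpoints between consecutive distinct values, equal-gain
#' ties broken toward the smallest threshold), then collects the split values
#' at its internal nodes, deduplicated and sorted ascending. The resulting
#' `K = length(thresholds) + 1` intervals satisfy
#' `K <= min(2^max_depth, max_leaf_nodes)`.
#'
#' A constant feature yields no valid split and returns an empty threshold
#' set (`K = 1`); a single-class label vector is an error.
#'
#' @param x numeric values of one continuous feature.
#' @param y binary labels (0/1), same length, both classes present.
#' @param config a [discretizer_config()].
#' @param feature_name name recorded in the discretizer.
#' @return a `feature_discretizer` with fields `feature_name`, `thresholds`,
#'   `n_intervals`, `config`.
#' @export
fit_feature_discretizer <- function(x, y, config = discretizer_config(),
                                    feature_name = "x") {
  x <- as.numeric(x)
  y <- as.integer(y)
  if (length(x) != length(y) || length(x) < 2L)
    validation_error("x and y must have equal length >= 2")
  if (any(!is.finite(x))) validation_error("x must be finite")
  if (length(unique(y)) < 2L)
    fadel_error("both classes must be present to fit a discretizer",
                "fadel_fit_error")
  tree <- .grow_gini_tree(matrix(x, ncol = 1L), y, seq_along(x),
                          config$max_depth, config$max_leaf_nodes,
                          config$min_samples_leaf, config$min_samples_split,
                          1L)
  thr <- tree$threshold[!is.na(tree$feature)]
  thr <- sort(unique(thr))
  new_feature_discretizer(feature_name, thr, config, method = "cart")
}

#' Fit unsupervised equal-width or equal-frequency bins
#'
#' Baseline discretizers that ignore the labels. Equal-width places
#' `n_bins - 1` thresholds evenly between `min(x)` and `max(x)`;
#' equal-frequency places thresholds at the empirical quantiles `i / n_bins`
#' with duplicated thresholds collapsed (so `K` may shrink below `n_bins`).
#'
#' @param x numeric values.
#' @param n_bins integer >= 2.
#' @param mode `"equal_width"` or `"equal_frequency"`.
#' @param feature_name name recorded in the discretizer.
#' @return a `feature_discretizer`.
#' @export
fit_unsupervised_bins <- function(x, n_bins,
                                  mode = c("equal_width", "equal_frequency"),
                                  feature_name = "x") {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  if (any(!is.finite(x))) validation_error("x must be finite")
  if (n_bins < 2L) validation_error("n_bins must be >= 2")
  if (mode == "equal_width") {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      thr <- numeric(0)
    } else {
      thr <- rng[1] + seq_len(n_bins - 1L) * (rng[2] - rng[1]) / n_bins
    }
  } else {
    thr <- unname(stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                                  type = 7))
    thr <- sort(unique(thr))
  }
  new_feature_discretizer(feature_name, thr, config = NULL, method = mode)
}

#' Map values to interval indices
#'
#' Assigns each finite value `x` the unique 1-based index `k` such that
#' `theta[k-1] < x <= theta[k]`, with virtual boundaries `theta[0] = -Inf`
#' and `theta[K] = +Inf` (intervals are right-closed). Values outside the
#' training range are absorbed by the unbounded end intervals. The mapping is
#' monotone non-decreasing in `x`.
#'
#' @param disc a `feature_discretizer`.
#' @param x numeric vector of finite values.
#' @return integer vector of interval indices in `1..n_intervals`.
#' @export
assign_interval <- function(disc, x) {
  if (any(!is.finite(x)))
    fadel_error("assign_interval requires finite values", "fadel_domain_error")
  if (length(disc$thresholds) == 0L) return(rep(1L, length(x)))
  findInterval(x, disc$thresholds, left.open = TRUE) + 1L
}

#' Discretize the flagged columns of a dataset
#'
#' Applies [assign_interval()] column-wise over all columns flagged for
#' discretization, producing the interval-index (FD) representation. Columns
#' not flagged are excluded (they belong to the raw view).
#'
#' @param ds a [tabular_dataset()].
#' @param discretizers named list of `feature_discretizer`s covering every
#'   flagged column.
#' @return list of class `discretized_view` with `Z` (N x J integer matrix of
#'   1-based interval indices) and `discretizers`.
#' @export
transform_dataset <- function(ds, discretizers) {
  flagged <- ds$schema$name[ds$schema$discretize]
  missing <- setdiff(flagged, names(discretizers))
  if (length(missing))
    fadel_error(sprintf("no discretizer for flagged column(s): %s",
                        paste(missing, collapse = ", ")),
                "fadel_configuration_error")
  Z <- matrix(integer(0), nrow = n_rows(ds), ncol = length(flagged))
  colnames(Z) <- flagged
  for (j in seq_along(flagged)) {
    nm <- flagged[j]
    Z[, j] <- assign_interval(discretizers[[nm]], ds$X[, nm])
  }
  structure(list(Z = Z, discretizers = discretizers[flagged]),
            class = "discretized_view")
}

#' Fit discretizers for all flagged columns of a dataset
#'
#' @param ds a [tabular_dataset()]; both classes must be present.
#' @param config a [discretizer_config()].
#' @return named list of `feature_discretizer`s, one per flagged column.
#' @export
fit_discretizers <- function(ds, config = discretizer_config()) {
  flagged <- ds$schema$name[ds$schema$discretize]
  out <- lapply(flagged, function(nm)
    fit_feature_discretizer(ds$X[, nm], ds$y, config, feature_name = nm))
  names(out) <- flagged
  out
}

# JSON persistence for discretizers. Thresholds are serialized with 17
# significant digits (shortest exact decimal repr of binary64 is at most 17
# digits), so load(save(d)) reproduces them bit-exactly.
discretizer_to_json_obj <- function(disc) {
  list(
    feature = disc$feature_name,
    thresholds = I(sprintf("%.17g", disc$thresholds)),
    n_intervals = disc$n_intervals,
    method = disc$method,
    config = if (is.null(disc$config)) NULL else unclass(disc$config)
  )
}

discretizer_from_json_obj <- function(obj) {
  cfg <- if (is.null(obj$config)) NULL else do.call(
    discretizer_config, obj$config[c("max_depth", "max_leaf_nodes",
                                     "min_samples_leaf", "min_samples_split")])
  new_feature_discretizer(obj$feature, as.numeric(unlist(obj$thresholds)),
                          cfg, method = obj$method)
}

#' Write / read a set of discretizers as JSON
#'
#' @param discretizers named list of `feature_discretizer`s.
#' @param path JSON file path.
#' @return `path` invisibly (write); named list of discretizers (read).
#' @export
write_discretizers <- function(discretizers, path) {
  objs <- lapply(discretizers, discretizer_to_json_obj)
  jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_discretizers
#' @export
read_discretizers <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(objs, discretizer_from_json_obj)
  names(out) <- vapply(out, function(d) d$feature_name, character(1))
  out
}
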