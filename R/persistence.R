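# Model archive: a directory of JSON documents. manifest.json carries the
# format version, routing plan, schema and config; discretizers.json the
# per-feature thresholds; base_<m>.json one state blob per slot;
# meta_forest.json the forest's node tables. All floating-point state is
# serialized with 17 significant digits so a save/load round trip is
# bit-exact and two runs with identical seeds produce byte-identical
# archives.

FADEL_FORMAT_VERSION <- "1"

num17 <- function(x) I(sprintf("%.17g", x))

tree_to_json_obj <- function(tr) {
  list(feature = I(ifelse(is.na(tr$feature), -1L, tr$feature)),
       threshold = I(ifelse(is.na(tr$threshold), "NA",
                            sprintf("%.17g", tr$threshold))),
       left = I(ifelse(is.na(tr$left), -1L, tr$left)),
       right = I(ifelse(is.na(tr$right), -1L, tr$right)),
       n = I(tr$n), n_pos = I(tr$n_pos), depth = I(tr$depth))
}

tree_from_json_obj <- function(obj) {
  feature <- as.integer(unlist(obj$feature))
  thr_chr <- as.character(unlist(obj$threshold))
  n <- as.integer(unlist(obj$n))
  n_pos <- as.integer(unlist(obj$n_pos))
  list(feature = ifelse(feature < 0, NA_integer_, feature),
       threshold = suppressWarnings(
         ifelse(thr_chr == "NA", NA_real_, as.numeric(thr_chr))),
       left = {v <- as.integer(unlist(obj$left)); ifelse(v < 0, NA_integer_, v)},
       right = {v <- as.integer(unlist(obj$right)); ifelse(v < 0, NA_integer_, v)},
       n = n, n_pos = n_pos, depth = as.integer(unlist(obj$depth)),
       q1 = ifelse(n > 0, n_pos / n, 0))
}

learner_to_json_obj <- function(lrn) {
  st <- switch(lrn$kind,
    gbdt = list(
      xgb_json = rawToChar(xgboost::xgb.save.raw(lrn$state$booster,
                                                 raw_format = "json")),
      params = lrn$state$params),
    target_encoded_gbdt = list(
      xgb_json = rawToChar(xgboost::xgb.save.raw(lrn$state$booster,
                                                 raw_format = "json")),
      params = lrn$state$params,
      fd_as = lrn$state$fd_as,
      encoders = lapply(lrn$state$encoders, function(e) list(
        a = e$a, p = unclass(num17(e$p))[1], order = e$order,
        order_seed = e$order_seed, categories = I(e$categories),
        sum_y = I(e$sum_y), count = I(e$count)))),
    adaboost = list(
      stumps = lapply(lrn$state$stumps, function(s) list(
        col = s$col, threshold = unclass(num17(s$threshold))[1],
        polarity = s$polarity)),
      alphas = num17(lrn$state$alphas),
      epsilons = num17(lrn$state$epsilons),
      n_rounds = lrn$state$n_rounds,
      learning_rate = lrn$state$learning_rate,
      columns = I(lrn$state$columns)),
    logistic = list(coef = num17(lrn$state$coef),
                    coef_names = I(names(lrn$state$coef)))
  )
  list(kind = lrn$kind, view_tag = lrn$view_tag, slot = lrn$slot,
       seed = lrn$seed, columns = I(lrn$columns), state = st)
}

learner_from_json_obj <- function(obj) {
  st <- obj$state
  state <- switch(obj$kind,
    gbdt = list(booster = xgboost::xgb.load.raw(charToRaw(st$xgb_json)),
                params = st$params),
    target_encoded_gbdt = list(
      booster = xgboost::xgb.load.raw(charToRaw(st$xgb_json)),
      params = st$params, fd_as = st$fd_as,
      encoders = lapply(st$encoders, function(e) structure(list(
        a = e$a, p = as.numeric(e$p), order = e$order,
        order_seed = e$order_seed,
        categories = as.character(unlist(e$categories)),
        sum_y = as.numeric(unlist(e$sum_y)),
        count = as.numeric(unlist(e$count))
      ), class = "target_encoder_state"))),
    adaboost = structure(list(
      stumps = lapply(st$stumps, function(s) list(
        col = s$col, threshold = as.numeric(s$threshold),
        polarity = s$polarity)),
      alphas = as.numeric(unlist(st$alphas)),
      epsilons = as.numeric(unlist(st$epsilons)),
      n_rounds = st$n_rounds, learning_rate = st$learning_rate,
      columns = as.character(unlist(st$columns))), class = "adaboost_state"),
    logistic = {
      cf <- as.numeric(unlist(st$coef))
      names(cf) <- as.character(unlist(st$coef_names))
      list(coef = cf)
    }
  )
  structure(list(kind = obj$kind, view_tag = obj$view_tag, slot = obj$slot,
                 seed = obj$seed,
                 columns = as.character(unlist(obj$columns)), state = state),
            class = "fadel_learner")
}

#' Save / load a fitted FADEL model archive
#'
#' The archive is a directory of JSON documents (manifest, discretizers, one
#' state blob per base slot, meta-forest). Floating-point state is written
#' with 17 significant digits, so `load_fadel(save_fadel(m))` reproduces the
#' model bit-exactly and archives are byte-identical across reruns with the
#' same seeds. Loading checks the format version strictly.
#'
#' @param model a `fadel_model`.
#' @param path archive directory (created if needed).
#' @return `path` invisibly (save); a `fadel_model` (load).
#' @export
save_fadel <- function(model, path) {
  if (!inherits(model, "fadel_model"))
    validation_error("model must be a fadel_model")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(path, f), auto_unbox = TRUE, pretty = TRUE, digits = NA,
    null = "null")
  cfg <- model$config
  manifest <- list(
    format_version = model$format_version,
    plan = lapply(model$plan, function(s)
      list(kind = s$kind, view = s$view, params = s$params)),
    schema = lapply(seq_len(nrow(model$schema)), function(i) list(
      name = model$schema$name[i], kind = model$schema$kind[i],
      discretize = model$schema$discretize[i])),
    config = list(
      discretizer = unclass(cfg$discretizer),
      n_trees = cfg$n_trees, meta_mode = cfg$meta_mode, k = cfg$k,
      seed = cfg$seed, mtry = cfg$mtry, slot_params = cfg$slot_params)
  )
  wj(manifest, "manifest.json")
  write_discretizers(model$discretizers,
                     file.path(path, "discretizers.json"))
  for (m in seq_along(model$learners))
    wj(learner_to_json_obj(model$learners[[m]]), sprintf("base_%d.json", m))
  wj(list(seed = model$meta_forest$seed, mtry = model$meta_forest$mtry,
          width = model$meta_forest$width,
          n_trees = model$meta_forest$n_trees,
          trees = lapply(model$meta_forest$trees, tree_to_json_obj)),
     "meta_forest.json")
  invisible(path)
}

#' @rdname save_fadel
#' @export
load_fadel <- function(path) {
  rj <- function(f) jsonlite::read_json(file.path(path, f),
                                        simplifyVector = FALSE)
  manifest <- rj("manifest.json")
  if (!identical(manifest$format_version, FADEL_FORMAT_VERSION))
    fadel_error(sprintf("unsupported model format version '%s' (expected '%s')",
                        manifest$format_version, FADEL_FORMAT_VERSION),
                "fadel_format_error")
  cfg <- manifest$config
  config <- fadel_config(
    discretizer = do.call(discretizer_config,
                          cfg$discretizer[c("max_depth", "max_leaf_nodes",
                                            "min_samples_leaf",
                                            "min_samples_split")]),
    n_trees = cfg$n_trees, meta_mode = cfg$meta_mode, k = cfg$k,
    seed = cfg$seed, mtry = cfg$mtry,
    slot_params = cfg$slot_params)
  schema <- do.call(rbind, lapply(manifest$schema, function(s)
    data.frame(name = s$name, kind = s$kind, discretize = s$discretize,
               stringsAsFactors = FALSE)))
  plan <- structure(lapply(manifest$plan, function(s)
    list(kind = s$kind, view = s$view, params = s$params)),
    class = "routing_plan")
  learners <- lapply(seq_along(plan), function(m)
    learner_from_json_obj(rj(sprintf("base_%d.json", m))))
  fj <- rj("meta_forest.json")
  forest <- new_meta_forest(lapply(fj$trees, tree_from_json_obj),
                            seed = fj$seed, mtry = fj$mtry,
                            width = fj$width)
  forest$n_trees <- fj$n_trees
  structure(list(
    format_version = manifest$format_version,
    discretizers = read_discretizers(file.path(path, "discretizers.json")),
    plan = plan, learners = learners, meta_forest = forest,
    config = config, schema = schema
  ), class = "fadel_model")
}
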