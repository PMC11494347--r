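#' Build labeled training pairs from sequence families
#'
#' Positives are all within-family pairs; negatives are cross-family pairs
#' sampled uniformly without replacement at `negative_ratio` times the number
#' of positives (all of them, with a warning, if fewer exist). Sampling is a
#' pure function of `seed`.
#'
#' @param families list of families as produced by [generate_dataset()] (or
#'   any list with elements `family_id` and named character `members`)
#' @param negative_ratio negatives per positive (default 1, balanced)
#' @param seed integer seed
#' @return data.frame with columns `id1`, `id2`, `family1`, `family2`,
#'   `label` (1 = within-family)
#' @export
build_training_pairs <- function(families, negative_ratio = 1, seed = 1) {
  check_families(families)
  ids <- unlist(lapply(families, function(f) names(f$members)), use.names = FALSE)
  fam <- rep(vapply(families, `[[`, "", "family_id"),
             vapply(families, function(f) length(f$members), 1L))
  if (anyDuplicated(ids))
    shark_stop("shark_config_error", "duplicate sequence ids across families")
  pr <- combn(length(ids), 2L)
  same <- fam[pr[1L, ]] == fam[pr[2L, ]]
  pos <- which(same); neg <- which(!same)
  n_neg <- round(negative_ratio * length(pos))
  if (n_neg > length(neg)) {
    warning(sprintf("only %d cross-family pairs available (%d requested)",
                    length(neg), n_neg), call. = FALSE)
    n_neg <- length(neg)
  }
  withr_seed(derive_seed(seed, "training_pairs"))
  keep <- c(pos, sort(sample(neg, n_neg)))
  data.frame(id1 = ids[pr[1L, keep]], id2 = ids[pr[2L, keep]],
             family1 = fam[pr[1L, keep]], family2 = fam[pr[2L, keep]],
             label = as.integer(fam[pr[1L, keep]] == fam[pr[2L, keep]]),
             stringsAsFactors = FALSE)
}

check_families <- function(families) {
  if (!is.list(families) || length(families) < 2L)
    shark_stop("shark_config_error", "need at least 2 families")
  sizes <- vapply(families, function(f) length(f$members), 1L)
  if (any(sizes < 2L))
    shark_stop("shark_config_error", "every family needs at least 2 members")
  invisible(TRUE)
}

# localized seeding that restores the caller's RNG state
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

#' Fit the SHARK-dive ensemble homology classifier
#'
#' Fits an ensemble of `n_submodels` gradient-boosted decision-tree
#' classifiers on family-labeled sequence pairs described by the 10 per-k
#' scores. Cross-validation structure is family-wise: the *families* are
#' shuffled (seeded) and partitioned round-robin into `n_submodels` folds, and
#' submodel i is trained only on pairs both of whose families lie outside
#' fold i, so no family leaks across a submodel's train/held-out boundary.
#' The ensemble probability of a pair is the mean of the submodel
#' probabilities; probabilities at or above `threshold` predict homology.
#'
#' @param pairs data.frame with columns `label`, `family1`, `family2` and the
#'   feature columns `k1` .. `k10` (see [pair_features()])
#' @param n_submodels number of folds/submodels (default 10)
#' @param threshold decision threshold in (0, 1), default 0.5
#' @param hyperparams list with elements `nrounds` (default 200), `max_depth`
#'   (3), `eta` (0.1) and `monotone` (TRUE: constrain each submodel to be
#'   non-decreasing in every similarity feature) for the gradient-boosting
#'   submodels
#' @param feature_map the per-k score map the features were computed with;
#'   archived in the model
#' @param matrix residue similarity matrix used for the features; archived
#' @param seed integer seed controlling fold assignment and submodel fitting
#' @return object of class `shark_dive` with `print()`, `summary()`,
#'   `predict()` and `plot()` methods
#' @examples
#' \donttest{
#' fams <- generate_dataset(n_families = 6, members_range = c(3, 4),
#'                          length_range = c(40, 60), seed = 1)
#' pairs <- build_training_pairs(fams, seed = 1)
#' feats <- pair_features(pairs, dataset_sequences(fams))
#' fit <- shark_dive(feats, n_submodels = 3, seed = 1)
#' fit
#' }
#' @export
shark_dive <- function(pairs, n_submodels = 10, threshold = 0.5,
                       hyperparams = list(), feature_map = default_feature_map(),
                       matrix = build_similarity_matrix(), seed = 1) {
  fn <- feature_names()
  need <- c("label", "family1", "family2", fn)
  if (!all(need %in% names(pairs)))
    shark_stop("shark_config_error",
               sprintf("pairs must contain columns: %s",
                       paste(setdiff(need, names(pairs)), collapse = ", ")))
  if (length(unique(pairs$label)) < 2L)
    shark_stop("shark_config_error", "pairs must contain both labels")
  if (threshold <= 0 || threshold >= 1)
    shark_stop("shark_config_error", "threshold must be in (0, 1)")
  hp <- modifyList(list(nrounds = 200L, max_depth = 3L, eta = 0.1,
                        monotone = TRUE), hyperparams)
  fams <- sort(unique(c(pairs$family1, pairs$family2)))
  if (length(fams) < n_submodels)
    shark_stop("shark_config_error",
               sprintf("only %d families for %d submodels; reduce n_submodels",
                       length(fams), n_submodels))
  withr_seed(derive_seed(seed, "dive_folds"))
  fams <- sample(fams)
  folds <- split(fams, rep_len(seq_len(n_submodels), length(fams)))
  X <- as.matrix(pairs[, fn])
  y <- as.numeric(pairs$label)
  submodels <- vector("list", n_submodels)
  for (i in seq_len(n_submodels)) {
    keep <- !(pairs$family1 %in% folds[[i]]) & !(pairs$family2 %in% folds[[i]])
    if (length(unique(y[keep])) < 2L)
      shark_stop("shark_config_error",
                 sprintf("submodel %d training pairs contain a single label", i))
    d <- xgboost::xgb.DMatrix(X[keep, , drop = FALSE], label = y[keep])
    params <- list(objective = "binary:logistic", max_depth = hp$max_depth,
                   eta = hp$eta, nthread = 1,
                   seed = derive_seed(seed, paste0("submodel_", i)))
    # every feature is a similarity, so the homology probability is
    # constrained to be non-decreasing in each: a self-comparison (all
    # features at their maximum 1) can never be outscored
    if (isTRUE(hp$monotone)) params$monotone_constraints <- rep(1L, 10L)
    bst <- xgboost::xgb.train(params = params, data = d,
                              nrounds = hp$nrounds, verbose = 0)
    submodels[[i]] <- xgboost::xgb.save.raw(bst)
  }
  structure(list(format = "shark_dive", version = "1.0",
                 submodels = submodels, feature_map = feature_map,
                 threshold = threshold, folds = folds, seed = seed,
                 hyperparams = hp, matrix = matrix,
                 n_training_pairs = nrow(pairs)),
            class = "shark_dive")
}

dive_boosters <- function(model) lapply(model$submodels, xgboost::xgb.load.raw)

check_dive <- function(model) {
  if (!inherits(model, "shark_dive") || is.null(model$submodels) ||
      !length(model$submodels))
    shark_stop("shark_model_error", "not a trained shark_dive model")
  invisible(TRUE)
}

#' Predict homology probabilities from a fitted ensemble
#'
#' @param object fitted `shark_dive` model
#' @param newdata matrix or data.frame holding the feature columns
#'   `k1` .. `k10` (e.g. the output of [pair_features()])
#' @param type `"prob"` for the ensemble mean probability, `"label"` for the
#'   thresholded 0/1 call
#' @param ... unused
#' @return numeric vector (probabilities in `[0, 1]`, or 0/1 labels)
#' @export
predict.shark_dive <- function(object, newdata, type = c("prob", "label"), ...) {
  check_dive(object)
  type <- match.arg(type)
  fn <- feature_names()
  if (is.data.frame(newdata)) {
    if (!all(fn %in% names(newdata)))
      shark_stop("shark_config_error", "newdata lacks feature columns k1..k10")
    newdata <- as.matrix(newdata[, fn])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, fn))
  storage.mode(newdata) <- "double"
  d <- xgboost::xgb.DMatrix(newdata)
  P <- vapply(dive_boosters(object), function(b) predict(b, d),
              numeric(nrow(newdata)))
  p <- rowMeans(matrix(P, nrow = nrow(newdata)))
  if (type == "prob") p else as.integer(p >= object$threshold)
}

#' Homology probability for one sequence pair
#'
#' Convenience wrapper computing the feature vector of the pair with the
#' model's archived feature map and similarity matrix, then averaging the
#' submodel probabilities. Symmetric in its arguments because every feature
#' is symmetric.
#'
#' @param model fitted `shark_dive` model
#' @param s1,s2 residue strings
#' @param sanitize drop k-mers containing non-canonical residues
#' @return probability in `[0, 1]`
#' @export
predict_pair <- function(model, s1, s2, sanitize = FALSE) {
  check_dive(model)
  f <- compute_feature_vector(s1, s2, model$feature_map, model$matrix,
                              sanitize = sanitize, quiet = TRUE)
  as.numeric(predict(model, matrix(f, 1L, dimnames = list(NULL, names(f)))))
}

#' Classify a sequence pair as homologous or not
#'
#' @inheritParams predict_pair
#' @param threshold decision threshold in (0, 1); probabilities at or above
#'   it (ties included) are called homologous
#' @return list with `label` (0/1) and `probability`
#' @export
classify <- function(model, s1, s2, threshold = model$threshold,
                     sanitize = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    shark_stop("shark_config_error", "threshold must be in (0, 1)")
  p <- predict_pair(model, s1, s2, sanitize = sanitize)
  list(label = as.integer(p >= threshold), probability = p)
}

#' Per-k feature importance of the ensemble
#'
#' Gain-based importances of each submodel (normalized to sum 1 within each
#' submodel; features never used by a submodel get 0), summarized as mean and
#' standard deviation per k across submodels.
#'
#' @param model fitted `shark_dive` model
#' @return list with `summary` (data.frame: `k`, `mean`, `sd`) and `raw`
#'   (n_submodels x 10 matrix of per-submodel importances)
#' @export
feature_importance <- function(model) {
  check_dive(model)
  fn <- feature_names()
  raw <- t(vapply(dive_boosters(model), function(b) {
    imp <- xgboost::xgb.importance(model = b)
    v <- setNames(numeric(10L), fn)
    v[imp$Feature] <- imp$Gain
    v
  }, numeric(10L)))
  list(summary = data.frame(k = 1:10, mean = colMeans(raw),
                            sd = apply(raw, 2L, sd)),
       raw = raw)
}

#' @export
print.shark_dive <- function(x, ...) {
  cat("SHARK-dive ensemble homology classifier\n")
  cat(sprintf("  submodels: %d gradient-boosted trees (nrounds = %d, depth = %d, eta = %g)\n",
              length(x$submodels), x$hyperparams$nrounds,
              x$hyperparams$max_depth, x$hyperparams$eta))
  cat(sprintf("  trained on %d pairs across %d families; decision threshold %.2f\n",
              x$n_training_pairs, length(unlist(x$folds)), x$threshold))
  alg <- x$feature_map$algorithm
  cat(sprintf("  features: k = 1..10 (%s)\n",
              paste(unique(alg), collapse = ", ")))
  invisible(x)
}

#' @export
summary.shark_dive <- function(object, ...) {
  imp <- feature_importance(object)
  out <- list(model = object, importance = imp$summary)
  class(out) <- "summary.shark_dive"
  out
}

#' @export
print.summary.shark_dive <- function(x, ...) {
  print(x$model)
  cat("\nMean feature importance across submodels (gain):\n")
  print(transform(x$importance, mean = round(mean, 4), sd = round(sd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Plot per-k feature importance
#'
#' Barplot of the mean gain-based importance per k-mer length, with one-SD
#' error bars across the submodels.
#'
#' @param x fitted `shark_dive` model
#' @param ... passed to [graphics::barplot()]
#' @export
plot.shark_dive <- function(x, ...) {
  imp <- feature_importance(x)$summary
  bp <- graphics::barplot(imp$mean, names.arg = imp$k,
                          xlab = "k-mer length", ylab = "mean importance (gain)",
                          ylim = c(0, max(imp$mean + imp$sd) * 1.05), ...)
  graphics::arrows(bp, pmax(imp$mean - imp$sd, 0), bp, imp$mean + imp$sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(imp)
}

#' Save / load a fitted ensemble
#'
#' The archive embeds the submodels (serialized boosters), the feature map,
#' the residue similarity matrix, the decision threshold, the training seed
#' and a format version; loading a file that lacks these, or that is
#' truncated/corrupt, raises an explicit error. A save/load round trip
#' preserves predictions bit-exactly.
#'
#' @param model fitted `shark_dive` model
#' @param path file path (conventionally `.shark`)
#' @return `load_dive_model()` returns the restored `shark_dive` object.
#' @export
save_dive_model <- function(model, path) {
  check_dive(model)
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_dive_model
#' @export
load_dive_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    shark_stop("shark_model_error",
               sprintf("corrupt model archive: %s (%s)", path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "shark_dive"))
    shark_stop("shark_model_error", "not a shark_dive model archive")
  if (!identical(obj$version, "1.0"))
    shark_stop("shark_model_error",
               sprintf("unsupported model archive version: %s", obj$version %||% "<missing>"))
  if (is.null(obj$feature_map) || is.null(obj$submodels))
    shark_stop("shark_model_error", "model archive lacks feature_map/submodels")
  structure(obj, class = "shark_dive")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
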