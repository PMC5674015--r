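# Random-forest training and tree-vote-margin confidence.
#
# The confidence of a prediction is the absolute vote margin over the
# ensemble's N trees, c_i = |sum_j t_j| with t_j in {-1, +1}: 0 at an even
# split (maximal uncertainty), N at unanimity. It is computed from raw
# per-tree votes, never from averaged probabilities, so the invariants
# c_i = |2 * votes_pos - N| and c_i = N (mod 2) hold exactly.

#' Random-forest hyperparameters
#'
#' Defaults follow the standard configuration for histologic object
#' classification: 100 trees, maximum depth 10, and `mtry = round(sqrt(F))`
#' features tried per split (7 for a 48-feature store). `mtry = NULL`
#' defers the square-root rule to training time, when F is known.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param mtry features tried per node split, or `NULL` for
#'   `round(sqrt(F))`.
#' @param seed integer seed controlling tree construction; training is a
#'   pure function of (data, params) given this seed.
#' @return A list of class `forest_params`.
#' @examples
#' forest_params()
#' resolve_mtry(forest_params(), n_features = 48)  # 7
#' @export
forest_params <- function(n_trees = 100L, max_depth = 10L, mtry = NULL,
                          seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, is.null(mtry) || mtry >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' @param params a [forest_params()].
#' @param n_features number of features F in the store.
#' @rdname forest_params
#' @export
resolve_mtry <- function(params, n_features) {
  m <- if (is.null(params$mtry)) as.integer(round(sqrt(n_features)))
       else params$mtry
  if (m < 1 || m > n_features) {
    stop("mtry = ", m, " outside [1, ", n_features, "]", call. = FALSE)
  }
  m
}

#' @export
print.forest_params <- function(x, ...) {
  cat(sprintf("<forest_params> %d trees, depth %d, mtry %s, seed %d\n",
              x$n_trees, x$max_depth,
              if (is.null(x$mtry)) "round(sqrt(F))" else x$mtry, x$seed))
  invisible(x)
}

#' Train a random forest on labeled objects
#'
#' Fits the classification rule on the active (non-ignored) entries of a
#' training label set. Training requires at least one object of each class
#' and is deterministic given `params$seed`. The fitted object records its
#' training snapshot (the exact ids and labels used), so retrained rules
#' are fully auditable.
#'
#' @param store a [feature_store()].
#' @param labels a training [label_set()]; ignore entries are excluded.
#' @param params a [forest_params()].
#' @return An object of class `histo_forest` with elements `model` (the
#'   underlying ensemble), `params`, `n_trees`, `feature_names` and
#'   `training_snapshot`.
#' @export
train_forest <- function(store, labels, params = forest_params()) {
  act <- active_labels(labels)
  if (nrow(act) == 0) stop("no active labels to train on", call. = FALSE)
  idx <- match(act$object_id, store$object_ids)
  if (anyNA(idx)) {
    stop("labeled object_id(s) absent from feature store: ",
         paste(utils::head(act$object_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  y <- factor(ifelse(act$label > 0, "pos", "neg"), levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training labels contain a single class; label at least one ",
         "positive and one negative object before training", call. = FALSE)
  }
  x <- store$features[idx, , drop = FALSE]
  dat <- data.frame(x, check.names = FALSE)
  dat$.label <- y
  mtry <- resolve_mtry(params, ncol(x))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = params$n_trees, max.depth = params$max_depth,
    mtry = mtry, seed = params$seed, num.threads = 1L,
    verbose = FALSE)
  structure(list(model = fit,
                 params = params,
                 n_trees = params$n_trees,
                 mtry = mtry,
                 feature_names = store$feature_names,
                 training_snapshot = data.frame(object_id = act$object_id,
                                                label = act$label)),
            class = "histo_forest")
}

#' @export
print.histo_forest <- function(x, ...) {
  snap <- x$training_snapshot
  cat(sprintf("<histo_forest> %d trees (depth <= %d, mtry %d), trained on %d objects (%d pos / %d neg)\n",
              x$n_trees, x$params$max_depth, x$mtry, nrow(snap),
              sum(snap$label == 1L), sum(snap$label == -1L)))
  invisible(x)
}

#' Per-tree votes for each object
#'
#' Low-level accessor: the K x N matrix of tree votes t_j in `{-1, +1}`.
#' [predict_confidence()] is the user-facing wrapper.
#'
#' @param model a `histo_forest`.
#' @param store a [feature_store()] with the same feature names as at
#'   training.
#' @return Integer K x N matrix with entries -1/+1.
#' @export
tree_votes <- function(model, store) {
  if (!identical(store$feature_names, model$feature_names)) {
    stop("feature dimension/name mismatch between store (",
         ncol(store$features), " features) and model (",
         length(model$feature_names), " features)", call. = FALSE)
  }
  dat <- data.frame(store$features, check.names = FALSE)
  pr <- predict(model$model, data = dat, predict.all = TRUE,
                num.threads = 1L, verbose = FALSE)$predictions
  # class indices into c("neg", "pos") -> votes in {-1, +1}
  v <- matrix(-1L, nrow(pr), ncol(pr))
  v[pr == 2L] <- 1L
  v
}

#' Predict classes with vote-margin confidence
#'
#' Applies a trained forest to every object in a store and reports, per
#' object: the positive-vote count, the hard class (`+1` iff strictly more
#' than half the trees vote positive; an exact tie predicts `-1`, the
#' negative class, since positives are rare in the motivating use), the
#' vote-margin confidence `c = |2 * votes_pos - N|` and its normalized form
#' `c / N` in `[0, 1]`. Minimum confidence 0 occurs at a 50/50 vote split.
#'
#' @param model a `histo_forest` from [train_forest()].
#' @param store a [feature_store()].
#' @return An object of class `prediction_result`: a `data.frame` with
#'   columns `object_id`, `slide_id`, `votes_pos`, `predicted`,
#'   `confidence`, `confidence_norm`, plus attribute `n_trees`.
#' @export
predict_confidence <- function(model, store) {
  v <- tree_votes(model, store)
  n <- model$n_trees
  votes_pos <- as.integer(rowSums(v == 1L))
  confidence <- abs(2L * votes_pos - n)
  res <- data.frame(object_id = store$object_ids,
                    slide_id = store$slide_ids,
                    votes_pos = votes_pos,
                    predicted = ifelse(votes_pos > n / 2, 1L, -1L),
                    confidence = confidence,
                    confidence_norm = confidence / n)
  structure(res, class = c("prediction_result", "data.frame"), n_trees = n)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d objects, %d predicted positive; median confidence_norm %.2f\n",
              nrow(x), sum(x$predicted == 1L), stats::median(x$confidence_norm)))
  invisible(x)
}

#' Continuous classification score
#'
#' The ROC score is the positive vote fraction `votes_pos / N`, a
#' continuous quantity in `[0, 1]`, rather than the hard class.
#'
#' @param pred a `prediction_result`.
#' @return Numeric vector of scores.
#' @export
prediction_score <- function(pred) {
  pred$votes_pos / attr(pred, "n_trees")
}
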