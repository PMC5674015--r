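# The label-update-predict loop.
#
# Each iteration trains the forest on the current labels, predicts the
# whole store, asks the oracle (a labeling callback standing in for the
# expert) to label the k least-confident unlabeled objects, and appends
# the answers. Retraining is from scratch each iteration, which keeps the
# loop a pure function of (store, seed labels, master seed).

#' Select the least-confident unlabeled objects
#'
#' Returns the `k` unlabeled objects with the smallest vote-margin
#' confidence — the instances whose labels are expected to benefit the
#' classifier most. Objects already labeled (including ignore entries)
#' are never returned. Ties in confidence break by ascending `object_id`.
#'
#' @param pred a `prediction_result` from [predict_confidence()].
#' @param labels the current [label_set()] (labeled + ignored ids are
#'   excluded from selection).
#' @param k number of instances to select (the labeling panel size;
#'   default 8).
#' @return Integer vector of at most `k` object ids. If fewer than `k`
#'   objects remain unlabeled, all of them are returned with a warning.
#' @export
select_instances <- function(pred, labels, k = 8L) {
  unlabeled <- !(pred$object_id %in% labels$object_id)
  pool <- pred[unlabeled, , drop = FALSE]
  if (nrow(pool) < k) {
    warning("only ", nrow(pool), " unlabeled objects remain (k = ", k, ")",
            call. = FALSE)
    k <- nrow(pool)
  }
  ord <- order(pool$confidence, pool$object_id)
  pool$object_id[utils::head(ord, k)]
}

#' Fit a classifier by active learning
#'
#' The main fitting function: starting from a small seed label set, runs
#' the label-update-predict cycle. Each iteration (1) retrains the forest
#' on the current labels, (2) predicts class and vote-margin confidence for
#' every object in the labeling pool, (3) selects `k` query objects, (4)
#' obtains their labels from `oracle` and appends them. When a validation
#' label set is supplied, held-out AUC is recorded at every iteration
#' (iteration 0 is the seed-trained rule). The loop stops at
#' `max_iterations`, or earlier once `auc_target` is reached.
#'
#' The selection strategy is `"uncertainty"` (least-confident first, the
#' active-learning rule) or `"random"` (uniform over unlabeled objects, a
#' baseline for measuring the efficiency gained by uncertainty sampling).
#'
#' Reproducibility: one master seed (`params$seed`) fans out to per-
#' iteration forest seeds and to any sampling, so two runs with identical
#' inputs produce identical histories.
#'
#' @param store a [feature_store()] (the labeling pool; typically the
#'   training slides only).
#' @param seed_labels the initial training [label_set()]; must contain at
#'   least one object of each class.
#' @param oracle function `(object_ids) -> integer labels in {+1, -1}`;
#'   stands in for the expert (e.g. [truth_oracle()] on simulated data).
#' @param params a [forest_params()]; `params$seed` is the master seed.
#' @param k labels solicited per iteration.
#' @param max_iterations iteration cap (0 = seed model only).
#' @param auc_target optional early stop: halt once validation AUC reaches
#'   this value. Requires `validation`. At least one of `max_iterations`,
#'   `auc_target` must be given.
#' @param validation optional validation [label_set()] with a matching
#'   `validation_store` (defaults to `store`).
#' @param validation_store [feature_store()] holding validation objects.
#' @param selection query strategy, `"uncertainty"` or `"random"`.
#' @return An object of class `active_learner` with elements `model` (the
#'   final `histo_forest`), `labels` (the accumulated `label_set`),
#'   `history` (one row per iteration: `iteration`, `n_added`,
#'   `train_size`, `auc`, `selected_ids`), `params`, `k`, `selection`.
#' @seealso [summary.active_learner()], [plot.active_learner()],
#'   [predict.active_learner()]
#' @export
active_learn <- function(store, seed_labels, oracle,
                         params = forest_params(), k = 8L,
                         max_iterations = NULL, auc_target = NULL,
                         validation = NULL, validation_store = store,
                         selection = c("uncertainty", "random")) {
  selection <- match.arg(selection)
  if (is.null(max_iterations) && is.null(auc_target)) {
    stop("no stop criterion: supply max_iterations and/or auc_target",
         call. = FALSE)
  }
  if (!is.null(auc_target) && is.null(validation)) {
    stop("auc_target requires a validation label set", call. = FALSE)
  }
  labels <- seed_labels
  history <- list()
  iter <- 0L
  model <- NULL
  repeat {
    it_params <- params
    # fan the master seed out so each retrain gets a distinct, fixed seed
    it_params$seed <- (params$seed + 10007L * iter) %% .Machine$integer.max
    model <- train_forest(store, labels, it_params)
    auc <- if (!is.null(validation)) {
      evaluate_auc(model, validation_store, validation)$auc
    } else NA_real_
    selected <- integer(0)
    stop_now <- (!is.null(max_iterations) && iter >= max_iterations) ||
      (!is.null(auc_target) && !is.na(auc) && auc >= auc_target)
    if (!stop_now) {
      pred <- predict_confidence(model, store)
      selected <- if (selection == "uncertainty") {
        select_instances(pred, labels, k)
      } else {
        pool <- pred$object_id[!(pred$object_id %in% labels$object_id)]
        set.seed((params$seed + 20011L * iter) %% .Machine$integer.max)
        sort(sample(pool, min(k, length(pool))))
      }
      if (length(selected) == 0) stop_now <- TRUE
    }
    history[[iter + 1L]] <- data.frame(
      iteration = iter,
      n_added = length(selected),
      train_size = nrow(active_labels(labels)),
      auc = auc,
      selected_ids = paste(selected, collapse = ";"))
    if (stop_now) break
    labels <- append_labels(labels, selected, oracle(selected),
                            source = "instance", iteration = iter + 1L)
    iter <- iter + 1L
  }
  structure(list(model = model, labels = labels,
                 history = do.call(rbind, history),
                 params = params, k = k, selection = selection),
            class = "active_learner")
}

#' Oracle answering queries from a ground-truth label set
#'
#' Builds the labeling callback [active_learn()] expects from a truth
#' label set (e.g. the simulator's). The oracle is total over the truth
#' set and never answers ignore.
#'
#' @param truth a [label_set()] covering the labeling pool.
#' @return A function mapping object ids to labels in `{+1, -1}`.
#' @export
truth_oracle <- function(truth) {
  force(truth)
  function(object_ids) {
    i <- match(object_ids, truth$object_id)
    if (anyNA(i)) {
      stop("oracle queried for unknown object_id(s): ",
           paste(object_ids[is.na(i)], collapse = ", "), call. = FALSE)
    }
    truth$label[i]
  }
}

#' @export
print.active_learner <- function(x, ...) {
  h <- x$history
  cat(sprintf("<active_learner> %s sampling, %d iterations, %d training labels\n",
              x$selection, nrow(h) - 1L, utils::tail(h$train_size, 1) +
                utils::tail(h$n_added, 1)))
  if (!all(is.na(h$auc))) {
    cat(sprintf("  validation AUC: %.4f (seed) -> %.4f (final)\n",
                h$auc[1], utils::tail(h$auc, 1)))
  }
  invisible(x)
}

#' Summarize an active-learning run
#'
#' @param object an `active_learner`.
#' @param ... unused.
#' @return The history `data.frame` (without the id column), printed with
#'   a header.
#' @export
summary.active_learner <- function(object, ...) {
  h <- object$history[, c("iteration", "n_added", "train_size", "auc")]
  structure(list(history = h, selection = object$selection,
                 k = object$k, params = object$params),
            class = "summary.active_learner")
}

#' @export
print.summary.active_learner <- function(x, ...) {
  cat(sprintf("Active-learning run (%s sampling, k = %d per iteration)\n",
              x$selection, x$k))
  print(x$params)
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Predict with the final model of an active-learning run
#'
#' @param object an `active_learner`.
#' @param store a [feature_store()] to score.
#' @param ... unused.
#' @return A `prediction_result`, as [predict_confidence()].
#' @export
predict.active_learner <- function(object, store, ...) {
  predict_confidence(object$model, store)
}

#' Plot the AUC learning curve
#'
#' Validation AUC against training-set size across loop iterations.
#'
#' @param x an `active_learner` fitted with a validation set.
#' @param ... passed to [plot()].
#' @export
plot.active_learner <- function(x, ...) {
  h <- x$history
  if (all(is.na(h$auc))) stop("run recorded no validation AUC", call. = FALSE)
  plot(h$train_size, h$auc, type = "b", pch = 16,
       xlab = "training labels", ylab = "validation AUC",
       main = sprintf("Learning curve (%s sampling)", x$selection), ...)
  invisible(x)
}

#' Write a loop history CSV
#'
#' Columns: `iteration`, `n_added`, `train_size`, `auc`, `selected_ids`
#' (semicolon-separated). Byte-identical across runs with the same seeds.
#'
#' @param learner an `active_learner`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_history_csv <- function(learner, path) {
  h <- learner$history
  h$auc <- ifelse(is.na(h$auc), "", sprintf("%.6f", h$auc))
  utils::write.csv(h, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
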