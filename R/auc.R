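# ROC / AUC evaluation.
#
# AUC is computed by trapezoidal integration of the ROC curve over all
# score thresholds. With ties handled by grouping equal scores, this equals
# the Mann-Whitney normalization: the probability a random positive
# outscores a random negative, counting ties as 1/2.

#' ROC curve and AUC from continuous scores
#'
#' @param scores numeric vector; larger means more positive.
#' @param labels integer vector in `{+1, -1}` aligned with `scores`.
#' @return A list with `auc` (scalar in `[0, 1]`) and `roc`, a
#'   `data.frame` with columns `threshold`, `fpr`, `tpr` — one row per
#'   distinct score value, thresholds descending, plus the (0,0) corner.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1L
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes in the label vector", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # collapse tied scores into single ROC vertices
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  roc <- data.frame(threshold = c(Inf, s[last_of_group]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

#' Evaluate a forest on a held-out validation label set
#'
#' Scores every validation object with the continuous positive-vote
#' fraction and computes the trapezoidal ROC/AUC against the held-out
#' labels. Ignore entries are excluded; the validation set must contain
#' both classes.
#'
#' @param model a `histo_forest`.
#' @param store a [feature_store()] containing the validation objects.
#' @param validation a validation [label_set()].
#' @return A list with `auc`, `roc` (as in [roc_auc()]), and `n` (number
#'   of validation objects used).
#' @export
evaluate_auc <- function(model, store, validation) {
  act <- active_labels(validation)
  if (nrow(act) == 0) stop("empty validation set", call. = FALSE)
  idx <- match(act$object_id, store$object_ids)
  if (anyNA(idx)) {
    stop("validation object_id(s) absent from feature store", call. = FALSE)
  }
  pred <- predict_confidence(model, subset_store(store, idx))
  out <- roc_auc(prediction_score(pred), act$label)
  out$n <- nrow(act)
  out
}

#' Export a ROC curve as CSV
#'
#' Columns: `threshold`, `fpr`, `tpr`.
#'
#' @param roc the `roc` data.frame from [roc_auc()] or [evaluate_auc()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(roc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
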