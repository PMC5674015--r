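# Instance selection, AUC, label edits and the learning loop.

make_pred <- function(object_ids, confidence, n_trees = 100L) {
  votes_pos <- (confidence + n_trees) / 2  # arbitrary consistent votes
  structure(data.frame(object_id = object_ids,
                       slide_id = "s1",
                       votes_pos = as.integer(votes_pos),
                       predicted = 1L,
                       confidence = as.integer(confidence),
                       confidence_norm = confidence / n_trees),
            class = c("prediction_result", "data.frame"), n_trees = n_trees)
}

test_that("selection returns the k least-confident unlabeled objects", {
  conf <- rep(100L, 50); conf[c(3, 9, 14, 20, 21, 33, 40, 48)] <- 0L
  pred <- make_pred(1:50, conf)
  none <- label_set(integer(0), integer(0))
  expect_equal(sort(select_instances(pred, none, 8)),
               c(3L, 9L, 14L, 20L, 21L, 33L, 40L, 48L))
  # a labeled (or ignored) zero-confidence object is never selected
  labs <- label_set(c(3L, 9L), c(1L, NA))
  sel <- select_instances(pred, labs, 8)
  expect_false(any(c(3L, 9L) %in% sel))
  expect_length(sel, 8)
})

test_that("selection matches a brute-force sort oracle with id tie-break", {
  set.seed(31)
  n <- 10000
  pred <- make_pred(sample.int(5 * n, n), 2L * sample(0:50, n, TRUE))
  labs <- label_set(sample(pred$object_id, 500), 1L)
  sel <- select_instances(pred, labs, 25)
  pool <- pred[!(pred$object_id %in% labs$object_id), ]
  oracle <- pool$object_id[order(pool$confidence, pool$object_id)][1:25]
  expect_identical(sel, oracle)
})

test_that("selection warns and returns everything when k exceeds the pool", {
  pred <- make_pred(1:5, rep(10L, 5))
  labs <- label_set(1:3, rep(1L, 3))
  expect_warning(sel <- select_instances(pred, labs, 8), "2 unlabeled")
  expect_equal(sort(sel), c(4L, 5L))
})

test_that("trapezoidal AUC equals pairwise concordance on random scores", {
  set.seed(17)
  for (rep in 1:8) {
    n <- 200
    labels <- c(rep(1L, 60), rep(-1L, 140))
    scores <- if (rep %% 2 == 0) {
      round(runif(n), 2)  # heavy ties
    } else {
      rnorm(n) + 0.8 * (labels == 1L)
    }
    res <- roc_auc(scores, labels)
    expect_equal(res$auc, concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC hits the degenerate anchors: separation 1, all-ties 0.5", {
  expect_equal(roc_auc(c(5, 4, 2, 1), c(1, 1, -1, -1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(1, -1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1L, 4)), "both classes")
})

test_that("ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(2)
  res <- roc_auc(rnorm(100), sample(c(1L, -1L), 100, TRUE))
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(utils::tail(res$roc$fpr, 1), 1)
  expect_equal(utils::tail(res$roc$tpr, 1), 1)
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_true(all(diff(res$roc$tpr) >= 0))
})

test_that("label edits are idempotent, reversible and order-equivalent", {
  ls <- label_set(1:100, rep(c(1L, -1L), 50))
  flip <- data.frame(object_id = 7L, label = -1L)
  e1 <- apply_label_edits(ls, flip)
  expect_equal(e1$label[e1$object_id == 7L], -1L)
  expect_equal(e1$source[e1$object_id == 7L], "review")
  back <- apply_label_edits(e1, data.frame(object_id = 7L, label = 1L))
  expect_equal(back$label, ls$label)
  # idempotence
  expect_equal(apply_label_edits(e1, flip)$label, e1$label)
  # batch equals sequential application
  set.seed(9)
  edits <- data.frame(object_id = sample(1:100, 100, TRUE),
                      label = sample(c(1L, -1L, NA), 100, TRUE))
  batch <- apply_label_edits(ls, edits)
  seq_ls <- ls
  for (i in seq_len(nrow(edits))) {
    seq_ls <- apply_label_edits(seq_ls, edits[i, , drop = FALSE])
  }
  expect_equal(batch$label, seq_ls$label)
  expect_error(apply_label_edits(ls, data.frame(object_id = 999L, label = 1L)),
               "unknown object_id")
})

test_that("an ignore edit removes the object from training", {
  toy <- make_toy_store(n = 60, sep = 5, seed = 12)
  ids <- c(1:5, 56:60)
  labs <- label_set(ids, toy$truth$label[match(ids, toy$truth$object_id)])
  labs2 <- apply_label_edits(labs, data.frame(object_id = 2L, label = NA))
  model <- train_forest(toy$store, labs2)
  expect_false(2L %in% model$training_snapshot$object_id)
  expect_equal(nrow(model$training_snapshot), 9)
})

test_that("the loop respects its stop criteria and bookkeeping", {
  toy <- make_toy_store(n = 300, sep = 4, seed = 23)
  ids <- c(1:4, 297:300)
  seed_labs <- label_set(ids, toy$truth$label[match(ids, toy$truth$object_id)])
  expect_error(active_learn(toy$store, seed_labs, truth_oracle(toy$truth)),
               "stop criterion")
  fit0 <- active_learn(toy$store, seed_labs, truth_oracle(toy$truth),
                       max_iterations = 0)
  expect_equal(nrow(fit0$history), 1)
  expect_equal(fit0$history$train_size, 8)
  fit3 <- active_learn(toy$store, seed_labs, truth_oracle(toy$truth),
                       max_iterations = 3, k = 8)
  # training-set size after i iterations = seed + i * k
  expect_equal(fit3$history$train_size, c(8, 16, 24, 32))
  expect_true(all(diff(fit3$history$train_size) > 0))
  expect_equal(fit3$history$iteration, 0:3)
})

test_that("two loop runs with one master seed are identical; seeds differ", {
  toy <- make_toy_store(n = 400, sep = 1.2, seed = 29, prevalence = 0.2)
  ids <- c(which(toy$truth$label == 1L)[1:4],
           which(toy$truth$label == -1L)[1:4])
  seed_labs <- label_set(ids, toy$truth$label[match(ids, toy$truth$object_id)])
  val_ids <- setdiff(seq(2, 400, by = 2), ids)
  validation <- label_set(val_ids,
                          toy$truth$label[match(val_ids, toy$truth$object_id)],
                          role = "validation")
  run <- function(seed) {
    active_learn(toy$store, seed_labs, truth_oracle(toy$truth),
                 params = forest_params(seed = seed), k = 5,
                 max_iterations = 4, validation = validation)
  }
  f1 <- run(77); f2 <- run(77); f3 <- run(78)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$labels$label, f2$labels$label)
  expect_false(identical(f1$history, f3$history))
})

test_that("random-selection runs stay reproducible and label only the pool", {
  toy <- make_toy_store(n = 200, sep = 2, seed = 41, prevalence = 0.3)
  ids <- c(which(toy$truth$label == 1L)[1:3],
           which(toy$truth$label == -1L)[1:3])
  seed_labs <- label_set(ids, toy$truth$label[match(ids, toy$truth$object_id)])
  run <- function() {
    active_learn(toy$store, seed_labs, truth_oracle(toy$truth),
                 params = forest_params(seed = 13), k = 6,
                 max_iterations = 3, selection = "random")
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_true(all(f1$labels$object_id %in% toy$store$object_ids))
  expect_equal(nrow(active_labels(f1$labels)), 6 + 3 * 6)
})
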