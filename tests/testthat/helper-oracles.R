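# Independent oracles used across the suite. Each recomputes a quantity by
# a route disjoint from the implementation it checks: brute-force loops,
# pairwise enumeration, per-tree traversal, dense discretization.

# O(K^2) clustering-index oracle: chunked full distance matrix.
brute_force_ci <- function(points, tau, include_self = FALSE) {
  if (inherits(points, "point_pattern")) points <- points$positions
  k <- nrow(points)
  if (k == 0) return(0)
  counts <- integer(k)
  chunk <- 500L
  for (start in seq(1, k, by = chunk)) {
    i <- start:min(start + chunk - 1L, k)
    d2 <- outer(points[i, 1], points[, 1], "-")^2 +
          outer(points[i, 2], points[, 2], "-")^2
    counts[i] <- rowSums(d2 <= tau^2)
  }
  if (!include_self) counts <- counts - 1L
  mean(counts)
}

# O(n^2) AUC oracle: pairwise concordance with ties counted 1/2.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == -1L]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Per-tree vote oracle: traverse each ranger tree by hand
# (rule: value <= splitval descends left) and map leaf classes to
# votes in {-1, +1}.
traverse_tree_votes <- function(model, store) {
  rf <- model$model
  feats <- store$features
  n <- nrow(feats)
  votes <- matrix(NA_integer_, n, model$n_trees)
  for (tr in seq_len(model$n_trees)) {
    ti <- ranger::treeInfo(rf, tr)
    ti <- ti[order(ti$nodeID), ]
    left <- ti$leftChild; right <- ti$rightChild
    splitvar <- match(ti$splitvarName, colnames(feats))
    splitval <- ti$splitval
    terminal <- ti$terminal
    pred_pos <- as.character(ti$prediction) == "pos"
    for (i in seq_len(n)) {
      node <- 1L  # row index of nodeID 0
      while (!terminal[node]) {
        node <- if (feats[i, splitvar[node]] <= splitval[node]) {
          left[node] + 1L
        } else {
          right[node] + 1L
        }
      }
      votes[i, tr] <- if (pred_pos[node]) 1L else -1L
    }
  }
  votes
}

# Dense-sampling projection oracle: nearest of many points sampled along
# the polyline, with its arc-length position.
dense_projection_scores <- function(curve, Z, n_dense = 20000L) {
  v <- curve$vertices
  arc <- curve$arc_length
  total <- max(arc)
  s_grid <- seq(0, total, length.out = n_dense)
  pts <- sapply(seq_len(ncol(v)), function(j) {
    approx(arc, v[, j], xout = s_grid)$y
  })
  t(apply(Z, 1, function(z) {
    d2 <- colSums((t(pts) - z)^2)
    i <- which.min(d2)
    c(score = s_grid[i], dist2 = d2[i])
  }))
}

# Small deterministic feature store: two Gaussian classes separated along
# the first feature, uniform centroids on one slide.
make_toy_store <- function(n = 200, f = 6, sep = 4, seed = 1,
                           slide_id = "s1", prevalence = 0.5) {
  set.seed(seed)
  n_pos <- round(n * prevalence)
  lab <- c(rep(-1L, n - n_pos), rep(1L, n_pos))
  feats <- matrix(rnorm(n * f), n, f)
  feats[lab == 1L, 1] <- feats[lab == 1L, 1] + sep
  store <- feature_store(feats, seq_len(n), rep(slide_id, n),
                         cbind(runif(n, 0, 1000), runif(n, 0, 800)))
  list(store = store,
       truth = label_set(seq_len(n), lab, source = "truth"))
}

make_toy_slide <- function(slide_id = "s1", width = 1024L, height = 1024L,
                           mpp = 0.5) {
  slide_meta(slide_id, width, height, mpp)
}

random_polygon <- function(n_vert = 5, cx = 50, cy = 50, r = 10) {
  th <- sort(runif(n_vert, 0, 2 * pi))
  cbind(cx + r * cos(th), cy + r * sin(th))
}
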