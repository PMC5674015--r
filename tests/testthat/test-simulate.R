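# Synthetic-data generators: determinism, validity, statistical structure.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5, n_slides = 3, n_objects = 500,
                    n_validation_slides = 1, validation_per_class = 30)
  b1 <- simulate_benchmark(cfg)
  b2 <- simulate_benchmark(cfg)
  expect_identical(b1$store$features, b2$store$features)
  expect_identical(b1$store$centroids, b2$store$centroids)
  expect_identical(b1$truth$label, b2$truth$label)
  expect_identical(b1$validation, b2$validation)
  b3 <- simulate_benchmark(sim_config(seed = 6, n_slides = 3,
                                      n_objects = 500,
                                      n_validation_slides = 1,
                                      validation_per_class = 30))
  expect_false(identical(b1$store$features, b3$store$features))
})

test_that("simulated stores pass load-time validation and round-trip", {
  cfg <- sim_config(seed = 2, n_slides = 2, n_objects = 400,
                    n_validation_slides = 1)
  b <- simulate_benchmark(cfg)
  expect_s3_class(validate_feature_store(b$store), "feature_store")
  expect_equal(ncol(b$store$features), 48)
  dir <- withr::local_tempdir()
  save_feature_store(b$store, file.path(dir, "s"))
  back <- load_feature_store(file.path(dir, "s"))
  expect_equal(back$object_ids, b$store$object_ids)
})

test_that("realized positive counts sit in the binomial central interval", {
  n <- 10000
  counts <- vapply(1:20, function(s) {
    sl <- simulate_slide(sim_config(seed = s, n_objects = n,
                                    positive_prevalence = 0.02))
    sum(sl$truth$label == 1L)
  }, numeric(1))
  band <- qbinom(c(0.005, 0.995), n, 0.02)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("positives cluster far above an equal-count uniform pattern", {
  ratios <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_objects = 5000, offspring_sigma_um = 10)
    sl <- simulate_slide(cfg)
    i <- match(sl$store$object_ids, sl$truth$object_id)
    pos <- sl$truth$label[i] == 1L
    um <- sl$store$centroids * cfg$mpp
    ci_pos <- clustering_index(um[pos, , drop = FALSE], 50)
    set.seed(s + 5000)
    unif <- cbind(runif(sum(pos), 0, cfg$slide_width_um),
                  runif(sum(pos), 0, cfg$slide_height_um))
    ci_unif <- clustering_index(unif, 50)
    ci_pos / max(ci_unif, 0.01)
  }, numeric(1))
  expect_true(all(ratios > 2))
})

test_that("zero class separation is unlearnable (AUC near 1/2)", {
  cfg <- sim_config(seed = 9, n_slides = 2, n_objects = 1000,
                    class_separation = 0, positive_prevalence = 0.3,
                    n_validation_slides = 1, validation_per_class = 200)
  b <- simulate_benchmark(cfg)
  labs <- seed_label_set(b, 40, seed = 9)
  model <- train_forest(b$store, labs, forest_params(seed = 9))
  auc <- evaluate_auc(model, b$store, b$validation)$auc
  expect_lt(abs(auc - 0.5), 0.07)
})

test_that("benchmark splits are disjoint and validation is class-balanced", {
  cfg <- sim_config(seed = 3, n_slides = 4, n_objects = 800,
                    positive_prevalence = 0.1, n_validation_slides = 2,
                    validation_per_class = 40)
  b <- simulate_benchmark(cfg)
  expect_length(intersect(b$training_slide_ids, b$validation_slide_ids), 0)
  val_slides <- b$store$slide_ids[match(b$validation$object_id,
                                        b$store$object_ids)]
  expect_true(all(val_slides %in% b$validation_slide_ids))
  expect_equal(sum(b$validation$label == 1L), 40)
  expect_equal(sum(b$validation$label == -1L), 40)
})

test_that("a forest trained on all training labels nearly saturates AUC", {
  # wide separation: the benchmark is then almost noiseless, so an
  # oracle-labeled forest must essentially solve it
  cfg <- sim_config(seed = 4, n_slides = 3, n_objects = 1000,
                    class_separation = 5, positive_prevalence = 0.1,
                    n_validation_slides = 1, validation_per_class = 100)
  b <- simulate_benchmark(cfg)
  on_train <- b$store$slide_ids %in% b$training_slide_ids
  full <- label_set(b$store$object_ids[on_train],
                    b$truth$label[match(b$store$object_ids[on_train],
                                        b$truth$object_id)])
  model <- train_forest(b$store, full, forest_params(seed = 4))
  expect_gte(evaluate_auc(model, b$store, b$validation)$auc, 0.98)
})

test_that("the latent continuum population matches its stated law", {
  cfg <- sim_config(seed = 8,
                    hypertrophy = list(n = 10000L, shape = 4, scale = 1,
                                       noise_sd = 0.05))
  pop <- simulate_hypertrophy_population(cfg)
  # anchors are the latent extremes
  expect_equal(pop$anchors,
               c(which.min(pop$lambda), which.max(pop$lambda)))
  # Kolmogorov-Smirnov distance to Gamma(4) below 0.02 at n = 10,000
  ks <- suppressWarnings(ks.test(pop$lambda, pgamma, shape = 4))
  expect_lt(unname(ks$statistic), 0.02)
  # noiseless population sits exactly on the generating path
  cfg0 <- sim_config(seed = 8,
                     hypertrophy = list(n = 500L, shape = 4, scale = 1,
                                        noise_sd = 0))
  pop0 <- simulate_hypertrophy_population(cfg0)
  expect_equal(pop0$features, pop0$curve_fn(pop0$lambda),
               ignore_attr = TRUE)
})
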