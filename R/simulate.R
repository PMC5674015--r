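# Synthetic whole-slide simulators.
#
# The generators reproduce the statistical structure the learner and the
# phenotype metrics assume, not the appearance of real tissue:
#   * a rare positive class (default prevalence 2%, inside the 0.02-5.6%
#     band observed for vascular endothelial nuclei in real cohorts);
#   * spatial clustering of positives (microvascular hyperplasia) via a
#     Neyman-Scott process: Poisson parents, Gaussian offspring;
#   * class-conditional Gaussian features with a controllable Mahalanobis
#     separation between class means — the learner's behaviour depends on
#     separability, which this parameterizes directly;
#   * a 1-D latent morphologic continuum in (area, eccentricity,
#     perimeter) space for hypertrophy scoring.
# Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' @param seed master seed; every generated quantity is a deterministic
#'   function of it.
#' @param n_slides number of slides in a benchmark.
#' @param n_objects objects (nuclei) per slide.
#' @param positive_prevalence expected fraction of positive objects
#'   (default 0.02, within the observed 0.02-5.6% band for vascular
#'   endothelial nuclei).
#' @param feature_dim number of histomic features F (default 48).
#' @param class_separation Mahalanobis distance between class means
#'   (default 3).
#' @param n_informative features carrying the class separation; the
#'   remainder are pure noise.
#' @param parent_mean_offspring mean positives per cluster parent.
#' @param offspring_sigma_um Gaussian offspring spread (microns) around a
#'   cluster parent (default 10, the scale of a small vessel profile).
#' @param slide_width_um,slide_height_um slide extent in microns.
#' @param mpp microns per pixel of the (virtual) base resolution.
#' @param n_validation_slides slides held out for validation; disjoint
#'   from the training slides.
#' @param validation_per_class validation labels drawn per class
#'   (class-balanced, capped by availability).
#' @param hypertrophy list: `n`, latent Gamma `shape`, `scale`, and
#'   Gaussian `noise_sd` for the morphologic-continuum population.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_slides = 10L,
                       n_objects = 5000L,
                       positive_prevalence = 0.02,
                       feature_dim = 48L,
                       class_separation = 3,
                       n_informative = 8L,
                       parent_mean_offspring = 8,
                       offspring_sigma_um = 10,
                       slide_width_um = 10000,
                       slide_height_um = 8000,
                       mpp = 0.5,
                       n_validation_slides = 3L,
                       validation_per_class = 150L,
                       hypertrophy = list(n = 2000L, shape = 4,
                                          scale = 1, noise_sd = 0.05)) {
  stopifnot(positive_prevalence > 0, positive_prevalence < 1,
            n_objects > 0, n_slides > 0, feature_dim >= n_informative,
            class_separation >= 0, parent_mean_offspring > 0,
            offspring_sigma_um > 0, mpp > 0,
            n_validation_slides < n_slides)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d slides x %d objects, prevalence %.3g, F = %d, separation %.2g, seed %d\n",
              x$n_slides, x$n_objects, x$positive_prevalence,
              x$feature_dim, x$class_separation, x$seed))
  invisible(x)
}

# class-mean offset with Mahalanobis norm = class_separation under
# identity covariance, spread over the informative features
class_mean_shift <- function(config) {
  mu <- numeric(config$feature_dim)
  mu[seq_len(config$n_informative)] <-
    config$class_separation / sqrt(config$n_informative)
  mu
}

#' Simulate one slide
#'
#' Negative-class centroids follow a homogeneous (binomial) Poisson
#' process over the slide; positive-class centroids follow a Neyman-Scott
#' cluster process (Poisson parents, Gaussian offspring with spread
#' `offspring_sigma_um`), emulating microvascular clustering. Features are
#' class-conditional Gaussians separated by `class_separation`. The truth
#' label set is returned for oracle use.
#'
#' @param config a [sim_config()].
#' @param slide_index 1-based slide number (also seeds the slide).
#' @return A list with `slide` (single-row slide metadata), `store`
#'   (a [feature_store()] for this slide) and `truth` (a training-role
#'   [label_set()] labeling every object).
#' @export
simulate_slide <- function(config, slide_index = 1L) {
  set.seed((config$seed * 1000L + slide_index) %% .Machine$integer.max)
  sid <- sprintf("sim-%03d", slide_index)
  meta <- slide_meta(sid,
                     width_px = round(config$slide_width_um / config$mpp),
                     height_px = round(config$slide_height_um / config$mpp),
                     mpp = config$mpp,
                     patient_id = sprintf("pat-%03d", slide_index))

  n <- config$n_objects
  n_pos <- stats::rbinom(1, n, config$positive_prevalence)
  if (n * config$positive_prevalence < 1) {
    warning("expected positive count below 1: slide may contain no positives",
            call. = FALSE)
  }
  n_neg <- n - n_pos

  w <- config$slide_width_um; h <- config$slide_height_um
  neg_um <- cbind(runif(n_neg, 0, w), runif(n_neg, 0, h))

  pos_um <- matrix(numeric(0), 0, 2)
  if (n_pos > 0) {
    n_parents <- max(1L, stats::rpois(1, n_pos / config$parent_mean_offspring))
    parents <- cbind(runif(n_parents, 0, w), runif(n_parents, 0, h))
    assign <- sample.int(n_parents, n_pos, replace = TRUE)
    pos_um <- parents[assign, , drop = FALSE] +
      matrix(rnorm(2 * n_pos, sd = config$offspring_sigma_um), n_pos, 2)
    pos_um[, 1] <- pmin(pmax(pos_um[, 1], 0), w - 1e-9)
    pos_um[, 2] <- pmin(pmax(pos_um[, 2], 0), h - 1e-9)
  }

  labels <- c(rep(-1L, n_neg), rep(1L, n_pos))
  cent_px <- rbind(neg_um, pos_um) / config$mpp

  mu <- class_mean_shift(config)
  feats <- matrix(rnorm(n * config$feature_dim), n, config$feature_dim)
  if (n_pos > 0) {
    feats[labels == 1L, ] <- sweep(feats[labels == 1L, , drop = FALSE],
                                   2, mu, "+")
  }

  # shuffle so row order carries no class information
  ord <- sample.int(n)
  object_ids <- slide_index * 1000000L + seq_len(n)
  store <- feature_store(feats[ord, , drop = FALSE],
                         object_ids,
                         rep(sid, n),
                         cent_px[ord, , drop = FALSE],
                         sprintf("f%02d", seq_len(config$feature_dim)))
  truth <- label_set(object_ids, labels[ord], role = "training",
                     source = "truth", iteration = 0L)
  list(slide = meta, store = store, truth = truth)
}

#' Simulate a multi-slide benchmark with a held-out validation set
#'
#' Generates `n_slides` slides, designates the last `n_validation_slides`
#' as validation (training and validation slide sets are disjoint), and
#' samples a class-balanced validation label set from the validation
#' slides. Regeneration with the same config is byte-identical.
#'
#' @param config a [sim_config()].
#' @return A list with `store` (all slides combined), `slides` (metadata
#'   table), `truth` (training-role labels for every object),
#'   `validation` (validation-role class-balanced [label_set()]),
#'   `training_slide_ids`, `validation_slide_ids`.
#' @export
simulate_benchmark <- function(config = sim_config()) {
  sims <- lapply(seq_len(config$n_slides), simulate_slide, config = config)
  store <- bind_stores(lapply(sims, `[[`, "store"))
  slides <- do.call(rbind, lapply(sims, `[[`, "slide"))
  truth_df <- do.call(rbind, lapply(sims, `[[`, "truth"))
  truth <- label_set(truth_df$object_id, truth_df$label, role = "training",
                     source = "truth", iteration = 0L)

  val_ids <- slides$slide_id[seq(config$n_slides - config$n_validation_slides + 1,
                                 config$n_slides)]
  train_ids <- setdiff(slides$slide_id, val_ids)

  on_val <- store$slide_ids %in% val_ids
  set.seed((config$seed * 1000L + 999L) %% .Machine$integer.max)
  pick <- function(class) {
    ids <- store$object_ids[on_val &
                              truth$label[match(store$object_ids,
                                                truth$object_id)] == class]
    sort(sample(ids, min(config$validation_per_class, length(ids))))
  }
  val_obj <- c(pick(1L), pick(-1L))
  validation <- label_set(val_obj,
                          truth$label[match(val_obj, truth$object_id)],
                          role = "validation", source = "truth",
                          iteration = 0L)
  list(store = store, slides = slides, truth = truth,
       validation = validation,
       training_slide_ids = train_ids,
       validation_slide_ids = val_ids)
}

#' Draw a class-balanced seed label set
#'
#' Mimics the manual initialization of the learner: a handful of labeled
#' nuclei, half per class, drawn from the training slides.
#'
#' @param bench a [simulate_benchmark()] result.
#' @param n_seed total seed labels (default 8, half per class).
#' @param seed RNG seed for the draw.
#' @return A training-role [label_set()] with `source = "seed"`.
#' @export
seed_label_set <- function(bench, n_seed = 8L, seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  on_train <- bench$store$slide_ids %in% bench$training_slide_ids
  lab <- bench$truth$label[match(bench$store$object_ids,
                                 bench$truth$object_id)]
  pick <- function(class, m) {
    ids <- bench$store$object_ids[on_train & lab == class]
    sort(sample(ids, min(m, length(ids))))
  }
  ids <- c(pick(1L, ceiling(n_seed / 2)), pick(-1L, floor(n_seed / 2)))
  label_set(ids, bench$truth$label[match(ids, bench$truth$object_id)],
            role = "training", source = "seed", iteration = 0L)
}

#' Simulate a latent morphologic continuum population
#'
#' Draws nuclei along a smooth parametric path `g(lambda)` in
#' (area, eccentricity, perimeter) space: latent positions
#' `lambda ~ Gamma(shape) * scale` (right-skewed, so hypertrophic extremes
#' are rare), observed features `f_i = g(lambda_i) + N(0, noise_sd^2)`
#' per coordinate. Anchors are the rows with minimum and maximum latent
#' position. Used for principal-curve recovery testing; the returned
#' truth (`lambda`) never feeds the fit.
#'
#' @param config a [sim_config()]; only `seed` and the `hypertrophy`
#'   entry (`n`, `shape`, `scale`, `noise_sd`) are used.
#' @return A list with `features` (n x 3), `lambda` (true latent
#'   positions), `anchors` (row indices `c(normal, hypertrophic)`), and
#'   `curve_fn` (the generating path, for reference).
#' @export
simulate_hypertrophy_population <- function(config = sim_config()) {
  hp <- config$hypertrophy
  set.seed((config$seed * 1000L + 777L) %% .Machine$integer.max)
  lam <- stats::rgamma(hp$n, shape = hp$shape) * hp$scale
  g <- function(t) cbind(area = t,
                         eccentricity = 0.15 * t^2,
                         perimeter = 0.6 * t)
  features <- g(lam) + matrix(rnorm(3 * hp$n, sd = hp$noise_sd), hp$n, 3)
  colnames(features) <- c("area", "eccentricity", "perimeter")
  list(features = features,
       lambda = lam,
       anchors = c(which.min(lam), which.max(lam)),
       curve_fn = g)
}
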