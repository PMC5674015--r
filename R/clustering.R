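# Clustering index: a Ripley's K variant for microvascular hyperplasia.
#
# CI(tau) = (1/K) * sum_i |{j != i : ||x_i - x_j|| <= tau}|
#
# i.e. the mean number of positive objects within distance tau of each
# positive object. Unlike the textbook Ripley's K, there is no density
# normalization (hyperplasia *raises* local density — that is the signal)
# and no edge correction (objects are plentiful and rarely near the tissue
# edge). The neighbour search is exact grid bucketing with cell edge tau.

#' Spatial point pattern of positive objects on one slide
#'
#' @param positions K x 2 numeric matrix of coordinates in microns,
#'   per-slide frame.
#' @param slide_id slide identifier.
#' @param object_ids optional source object ids.
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(positions, slide_id = "slide",
                          object_ids = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must be K x 2", call. = FALSE)
  storage.mode(positions) <- "double"
  if (nrow(positions) > 0 && any(!is.finite(positions))) {
    stop("non-finite coordinates in point pattern", call. = FALSE)
  }
  structure(list(slide_id = as.character(slide_id),
                 positions = positions,
                 object_ids = object_ids),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> slide %s: %d points\n",
              x$slide_id, nrow(x$positions)))
  invisible(x)
}

#' Per-point neighbour counts within a radius
#'
#' Exact fixed-radius counts (self excluded by default), the per-nucleus
#' term of the clustering index.
#'
#' @param points a [point_pattern()] or K x 2 matrix in microns.
#' @param tau search radius in microns.
#' @param include_self count the point itself (distance 0) as a neighbour.
#' @return Integer vector of length K.
#' @export
neighbor_counts <- function(points, tau = 50, include_self = FALSE) {
  if (inherits(points, "point_pattern")) points <- points$positions
  points <- as.matrix(points)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (nrow(points) == 0) return(integer(0))
  .neighbor_counts_grid(points[, 1], points[, 2], tau, include_self)
}

#' Clustering index of a point pattern
#'
#' Mean neighbour count within `tau` microns over the pattern's points:
#' `CI(tau) = (1/K) sum_i |{j != i : d_ij <= tau}|`. No density
#' normalization, no edge correction. A fully dispersed pattern (no
#' neighbours within `tau`) yields `CI = 0`; an empty pattern is defined
#' as 0 with a warning. The default radius is 50 microns, the scale of a
#' microvascular structure.
#'
#' @inheritParams neighbor_counts
#' @return Non-negative scalar.
#' @examples
#' clustering_index(rbind(c(0, 0), c(40, 0)))  # 1: each point has 1 neighbour
#' clustering_index(rbind(c(0, 0), c(60, 0)))  # 0
#' @export
clustering_index <- function(points, tau = 50, include_self = FALSE) {
  counts <- neighbor_counts(points, tau, include_self)
  if (length(counts) == 0) {
    warning("empty point pattern: clustering index defined as 0",
            call. = FALSE)
    return(0)
  }
  mean(counts)
}

#' Patient-level clustering index
#'
#' Neighbour counts are computed within each slide separately (coordinate
#' frames are per-slide), then averaged over all the patient's positive
#' nuclei pooled — i.e. a count-weighted mean across slides, so slides
#' contribute in proportion to their positive-object counts.
#'
#' @param patterns list of [point_pattern()]s belonging to one patient.
#' @param tau search radius in microns.
#' @param include_self see [neighbor_counts()].
#' @return Non-negative scalar.
#' @export
patient_clustering_index <- function(patterns, tau = 50,
                                     include_self = FALSE) {
  stopifnot(length(patterns) >= 1)
  counts <- unlist(lapply(patterns, neighbor_counts, tau = tau,
                          include_self = include_self))
  if (length(counts) == 0) {
    warning("no positive objects for patient: clustering index defined as 0",
            call. = FALSE)
    return(0)
  }
  mean(counts)
}

#' Positive-object point patterns from predictions
#'
#' Extracts, per slide, the micron-frame point pattern of objects a
#' classifier called positive — the input to the clustering index.
#'
#' @param pred a `prediction_result`.
#' @param store the matching [feature_store()].
#' @param slides slide metadata (for microns-per-pixel).
#' @return Named list of [point_pattern()]s, one per slide present in the
#'   store (possibly empty patterns).
#' @export
positive_patterns <- function(pred, store, slides) {
  um <- centroids_to_microns(store, slides)
  i <- match(store$object_ids, pred$object_id)
  if (anyNA(i)) stop("predictions missing for store object(s)", call. = FALSE)
  pos <- pred$predicted[i] == 1L
  out <- lapply(unique(store$slide_ids), function(sid) {
    sel <- pos & store$slide_ids == sid
    point_pattern(um[sel, , drop = FALSE], sid,
                  object_ids = store$object_ids[sel])
  })
  names(out) <- unique(store$slide_ids)
  out
}
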