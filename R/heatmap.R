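# Labeling-priority heatmaps and slide ranking.
#
# A heatmap bins a slide into square cells and counts, per cell, the
# objects, the low-confidence objects (confidence_norm <= threshold) and
# the positively classified objects. Hotspots — cells enriched in
# low-confidence objects — tell the annotator where labeling effort pays
# off; the positive channel visualizes the classified density.

#' Build a prediction-confidence heatmap for one slide
#'
#' @param pred a `prediction_result` (may cover several slides; only rows
#'   of `slide$slide_id` are used).
#' @param store the [feature_store()] the predictions came from (supplies
#'   pixel centroids).
#' @param slide single-row slide metadata for the slide to map.
#' @param cell_size_px square cell edge in pixels (default 512 at base
#'   resolution).
#' @param threshold_norm low-confidence cutoff on `confidence_norm`
#'   (default 0.25): objects at or below it count as low-confidence.
#' @return An object of class `confidence_heatmap`: grid matrices
#'   `object_count`, `low_conf_count`, `positive_count` of dimension
#'   `ceiling(height/cell) x ceiling(width/cell)` (rows = y), plus
#'   `slide_id`, `cell_size_px`, `threshold_norm`.
#' @export
build_heatmap <- function(pred, store, slide, cell_size_px = 512L,
                          threshold_norm = 0.25) {
  stopifnot(cell_size_px > 0)
  validate_slide_meta(slide)
  stopifnot(nrow(slide) == 1)
  on_slide <- which(store$slide_ids == slide$slide_id)
  i <- match(store$object_ids[on_slide], pred$object_id)
  if (anyNA(i)) stop("predictions missing for objects on slide ",
                     slide$slide_id, call. = FALSE)
  p <- pred[i, , drop = FALSE]
  xy <- store$centroids[on_slide, , drop = FALSE]
  out_of_bounds <- xy[, 1] < 0 | xy[, 1] >= slide$width_px |
                   xy[, 2] < 0 | xy[, 2] >= slide$height_px
  if (any(out_of_bounds)) {
    stop("object(s) outside slide bounds: ",
         paste(utils::head(p$object_id[out_of_bounds], 5), collapse = ", "),
         call. = FALSE)
  }
  ncol_grid <- as.integer(ceiling(slide$width_px / cell_size_px))
  nrow_grid <- as.integer(ceiling(slide$height_px / cell_size_px))
  col <- floor(xy[, 1] / cell_size_px) + 1L
  row <- floor(xy[, 2] / cell_size_px) + 1L
  cell <- factor((row - 1L) * ncol_grid + col,
                 levels = seq_len(nrow_grid * ncol_grid))
  tab <- function(mask) {
    matrix(as.integer(table(cell[mask])), nrow_grid, ncol_grid, byrow = TRUE)
  }
  structure(list(
    slide_id = slide$slide_id,
    cell_size_px = as.integer(cell_size_px),
    threshold_norm = threshold_norm,
    object_count = tab(rep(TRUE, length(cell))),
    low_conf_count = tab(p$confidence_norm <= threshold_norm),
    positive_count = tab(p$predicted == 1L)
  ), class = "confidence_heatmap")
}

#' @export
print.confidence_heatmap <- function(x, ...) {
  cat(sprintf("<confidence_heatmap> slide %s: %dx%d cells of %d px, %d objects (%d low-confidence @ %.2f, %d positive)\n",
              x$slide_id, nrow(x$object_count), ncol(x$object_count),
              x$cell_size_px, sum(x$object_count), sum(x$low_conf_count),
              x$threshold_norm, sum(x$positive_count)))
  invisible(x)
}

#' Plot a confidence heatmap
#'
#' @param x a `confidence_heatmap`.
#' @param channel which count to display.
#' @param ... passed to [image()].
#' @export
plot.confidence_heatmap <- function(x, channel = c("low_conf_count",
                                                   "object_count",
                                                   "positive_count"), ...) {
  channel <- match.arg(channel)
  m <- x[[channel]]
  # image() draws x right, y up; flip rows so y increases downward
  image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
        col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
        axes = FALSE, main = sprintf("%s: %s", x$slide_id, channel), ...)
  invisible(x)
}

#' Rank slides by labeling priority
#'
#' Orders slides by the fraction of low-confidence objects (descending):
#' the slides where the classifier is least certain, hence where review
#' effort is best spent. Ties break lexically by `slide_id`.
#'
#' @param heatmaps list of `confidence_heatmap` objects.
#' @return A `data.frame` with columns `slide_id`, `n_objects`,
#'   `n_low_conf`, `frac_low_conf`, `n_positive`, ordered by descending
#'   `frac_low_conf`.
#' @export
rank_slides <- function(heatmaps) {
  stopifnot(length(heatmaps) >= 1)
  stats <- do.call(rbind, lapply(heatmaps, function(h) {
    n <- sum(h$object_count)
    data.frame(slide_id = h$slide_id,
               n_objects = n,
               n_low_conf = sum(h$low_conf_count),
               frac_low_conf = if (n > 0) sum(h$low_conf_count) / n else 0,
               n_positive = sum(h$positive_count))
  }))
  stats[order(-stats$frac_low_conf, stats$slide_id), , drop = FALSE]
}

#' Export a heatmap grid as TSV
#'
#' One row per grid cell: `row`, `col` (1-based, row = y band),
#' `object_count`, `low_conf_count`, `positive_count`.
#'
#' @param heatmap a `confidence_heatmap`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_heatmap_tsv <- function(heatmap, path) {
  g <- expand.grid(row = seq_len(nrow(heatmap$object_count)),
                   col = seq_len(ncol(heatmap$object_count)))
  g <- g[order(g$row, g$col), ]
  idx <- cbind(g$row, g$col)
  df <- data.frame(row = g$row, col = g$col,
                   object_count = heatmap$object_count[idx],
                   low_conf_count = heatmap$low_conf_count[idx],
                   positive_count = heatmap$positive_count[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
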