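# Domain types and file formats for slide-level object data.
#
# Coordinate convention (image convention): 0-based pixel coordinates,
# x increasing rightward, y increasing downward. Conversion to microns
# happens only at the clustering-index boundary via the slide's
# microns-per-pixel (mpp).

#' Slide metadata table
#'
#' Builds and validates a slide metadata table, one row per slide. Slide
#' dimensions are in pixels; `mpp` (microns per pixel) converts pixel
#' centroids to physical distances, which the clustering index needs because
#' its search radius is expressed in microns.
#'
#' @param slide_id character vector of unique slide identifiers.
#' @param width_px,height_px positive integer slide dimensions in pixels.
#' @param mpp positive numeric microns-per-pixel scale, one per slide.
#' @param patient_id character vector mapping slides to patients; defaults
#'   to `slide_id` (one slide per patient).
#' @return A `data.frame` with columns `slide_id`, `patient_id`,
#'   `width_px`, `height_px`, `mpp`.
#' @examples
#' slide_meta("s1", 20000, 16000, mpp = 0.5)
#' @export
slide_meta <- function(slide_id, width_px, height_px, mpp,
                       patient_id = slide_id) {
  df <- data.frame(
    slide_id = as.character(slide_id),
    patient_id = as.character(patient_id),
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    mpp = as.numeric(mpp),
    stringsAsFactors = FALSE
  )
  validate_slide_meta(df)
  df
}

validate_slide_meta <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("slide_id", "patient_id", "width_px", "height_px", "mpp")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("slide metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$slide_id)) {
    stop("duplicate slide_id in slide metadata", call. = FALSE)
  }
  if (any(df$width_px <= 0) || any(df$height_px <= 0)) {
    stop("slide dimensions must be positive", call. = FALSE)
  }
  if (any(!is.finite(df$mpp)) || any(df$mpp <= 0)) {
    stop("mpp must be positive and finite", call. = FALSE)
  }
  invisible(df)
}

#' Read and write slide metadata CSV
#'
#' CSV dialect: header `slide_id,patient_id,width_px,height_px,mpp`.
#'
#' @param path file path.
#' @return `read_slide_meta()` returns a validated slide metadata
#'   `data.frame`; `write_slide_meta()` invisibly returns `path`.
#' @export
read_slide_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(slide_id = "character",
                                       patient_id = "character"))
  validate_slide_meta(df)
  df
}

#' @param slides slide metadata `data.frame` as built by [slide_meta()].
#' @rdname read_slide_meta
#' @export
write_slide_meta <- function(slides, path) {
  validate_slide_meta(slides)
  utils::write.csv(
    slides[, c("slide_id", "patient_id", "width_px", "height_px", "mpp")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Boundary files
#
# Dialect (documented; upstream tools store boundaries "text-delimited" but
# print no exact layout): UTF-8, tab-separated, one object per line,
#   slide_id <TAB> object_id <TAB> centroid_x <TAB> centroid_y <TAB> boundary
# where boundary is space-separated "x,y" vertex pairs of a closed polygon
# (the closing edge last->first is implicit). Lines starting with "#" are
# comments. Centroid fields may be "NA"; the vertex mean is then used.

#' Read a nuclear boundary file
#'
#' Parses a tab-separated boundary file into a list of histologic objects.
#' Each line holds `slide_id`, `object_id`, `centroid_x`, `centroid_y` and a
#' boundary polygon as space-separated `"x,y"` vertex pairs; `#` starts a
#' comment line. When the centroid fields are `NA` the centroid is computed
#' as the mean of the polygon vertices.
#'
#' @param path path to the boundary file.
#' @param slide optional single-row slide metadata; when supplied, centroids
#'   are checked against the slide bounds.
#' @return A list of `hist_object` entries, each a list with fields
#'   `slide_id`, `object_id`, `centroid` (length-2 numeric, pixels) and
#'   `boundary` (n x 2 numeric matrix of polygon vertices, n >= 3).
#' @seealso [write_boundary_file()]
#' @export
read_boundary_file <- function(path, slide = NULL) {
  if (!file.exists(path)) stop("boundary file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  objects <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5) {
      stop(sprintf("boundary file %s line %d: expected 5 tab-separated fields, got %d",
                   path, i, length(fields)), call. = FALSE)
    }
    verts <- strsplit(strsplit(trimws(fields[5]), " +")[[1]], ",", fixed = TRUE)
    if (length(verts) < 3) {
      stop(sprintf("boundary file %s line %d: polygon has %d vertices (need >= 3)",
                   path, i, length(verts)), call. = FALSE)
    }
    bnd <- t(vapply(verts, function(v) as.numeric(v[1:2]), numeric(2)))
    if (any(!is.finite(bnd))) {
      stop(sprintf("boundary file %s line %d: non-numeric vertex", path, i),
           call. = FALSE)
    }
    cx <- suppressWarnings(as.numeric(fields[3]))
    cy <- suppressWarnings(as.numeric(fields[4]))
    centroid <- if (is.na(cx) || is.na(cy)) colMeans(bnd) else c(cx, cy)
    obj <- list(slide_id = fields[1],
                object_id = as.integer(fields[2]),
                centroid = unname(centroid),
                boundary = unname(bnd))
    class(obj) <- "hist_object"
    objects[[k]] <- obj
  }
  if (!is.null(slide)) {
    for (obj in objects) {
      if (obj$centroid[1] < 0 || obj$centroid[1] >= slide$width_px ||
          obj$centroid[2] < 0 || obj$centroid[2] >= slide$height_px) {
        stop("object ", obj$object_id, " centroid outside slide bounds",
             call. = FALSE)
      }
    }
  }
  objects
}

#' Write a nuclear boundary file
#'
#' Inverse of [read_boundary_file()]. All objects must belong to the same
#' slide; an empty object list writes a header-only (comment) file.
#'
#' @param objects list of `hist_object` entries.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_boundary_file <- function(objects, path) {
  header <- "# slide_id\tobject_id\tcentroid_x\tcentroid_y\tboundary(x,y ...)"
  if (length(objects) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  slide_ids <- vapply(objects, `[[`, character(1), "slide_id")
  if (length(unique(slide_ids)) > 1) {
    stop("all objects in one boundary file must share a slide_id",
         call. = FALSE)
  }
  lines <- vapply(objects, function(obj) {
    if (nrow(obj$boundary) < 3) {
      stop("object ", obj$object_id, ": polygon has fewer than 3 vertices",
           call. = FALSE)
    }
    poly <- paste(sprintf("%.6g,%.6g", obj$boundary[, 1], obj$boundary[, 2]),
                  collapse = " ")
    sprintf("%s\t%d\t%.6g\t%.6g\t%s", obj$slide_id, obj$object_id,
            obj$centroid[1], obj$centroid[2], poly)
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature store

#' Columnar feature store
#'
#' The feature store is the unit all learning operates on: a K x F feature
#' matrix plus aligned per-object indices (object ids, slide ids, pixel
#' centroids). Boundaries are deliberately not part of the store; they are
#' needed only for export and visualization.
#'
#' @param features numeric K x F matrix; no NA/NaN/Inf allowed.
#' @param object_ids length-K integer vector, unique non-negative ids.
#' @param slide_ids length-K character vector.
#' @param centroids K x 2 numeric matrix of pixel centroids.
#' @param feature_names length-F character vector of unique names.
#' @return An object of class `feature_store`.
#' @examples
#' fs <- feature_store(matrix(rnorm(20), 5, 4), 1:5, rep("s1", 5),
#'                     cbind(runif(5, 0, 100), runif(5, 0, 100)))
#' fs
#' @export
feature_store <- function(features, object_ids, slide_ids, centroids,
                          feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) {
    feature_names <- if (!is.null(colnames(features))) colnames(features)
                     else sprintf("f%02d", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  store <- structure(list(
    features = features,
    object_ids = as.integer(object_ids),
    slide_ids = as.character(slide_ids),
    centroids = centroids,
    feature_names = as.character(feature_names)
  ), class = "feature_store")
  validate_feature_store(store)
  store
}

validate_feature_store <- function(store) {
  k <- nrow(store$features)
  if (length(store$object_ids) != k) {
    stop("feature store length mismatch: object_ids has ",
         length(store$object_ids), " entries for ", k, " feature rows",
         call. = FALSE)
  }
  if (length(store$slide_ids) != k) {
    stop("feature store length mismatch: slide_ids has ",
         length(store$slide_ids), " entries for ", k, " feature rows",
         call. = FALSE)
  }
  if (nrow(store$centroids) != k || ncol(store$centroids) != 2) {
    stop("feature store length mismatch: centroids must be K x 2",
         call. = FALSE)
  }
  if (length(store$feature_names) != ncol(store$features)) {
    stop("feature store length mismatch: ", length(store$feature_names),
         " feature names for ", ncol(store$features), " columns",
         call. = FALSE)
  }
  if (anyDuplicated(store$feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (anyDuplicated(store$object_ids)) {
    stop("object_ids must be unique within a feature store", call. = FALSE)
  }
  if (any(!is.finite(store$features))) {
    stop("non-finite feature values (NA/NaN/Inf) in feature store",
         call. = FALSE)
  }
  invisible(store)
}

#' @export
print.feature_store <- function(x, ...) {
  cat(sprintf("<feature_store> %d objects x %d features, %d slide(s)\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$slide_ids))))
  invisible(x)
}

#' @export
dim.feature_store <- function(x) dim(x$features)

#' Subset a feature store by row
#'
#' @param store a [feature_store()].
#' @param i integer or logical row index.
#' @return A `feature_store` with the selected objects.
#' @export
subset_store <- function(store, i) {
  feature_store(store$features[i, , drop = FALSE],
                store$object_ids[i],
                store$slide_ids[i],
                store$centroids[i, , drop = FALSE],
                store$feature_names)
}

#' Bind feature stores row-wise
#'
#' @param ... `feature_store` objects with identical feature names.
#' @return A single combined `feature_store`.
#' @export
bind_stores <- function(...) {
  stores <- list(...)
  if (length(stores) == 1 && is.list(stores[[1]]) &&
      !inherits(stores[[1]], "feature_store")) {
    stores <- stores[[1]]
  }
  fn <- stores[[1]]$feature_names
  for (s in stores) {
    if (!identical(s$feature_names, fn)) {
      stop("cannot bind stores with differing feature names", call. = FALSE)
    }
  }
  feature_store(do.call(rbind, lapply(stores, `[[`, "features")),
                unlist(lapply(stores, `[[`, "object_ids")),
                unlist(lapply(stores, `[[`, "slide_ids")),
                do.call(rbind, lapply(stores, `[[`, "centroids")),
                fn)
}

#' Save and load a feature store
#'
#' The store is serialized as a directory of plain-text members mirroring
#' its components one-to-one: `features.tsv` (K x F, tab-separated),
#' `objects.tsv` (`object_id`, `slide_id`, `centroid_x`, `centroid_y`) and
#' `feature_names.txt` (one name per line). Loading re-validates the store:
#' missing members, index-length mismatches and non-finite feature values
#' each raise a distinct error rather than being silently repaired.
#'
#' @param store a [feature_store()].
#' @param path directory path for the store.
#' @return `save_feature_store()` invisibly returns `path`;
#'   `load_feature_store()` returns a validated `feature_store`.
#' @export
save_feature_store <- function(store, path) {
  validate_feature_store(store)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(store$feature_names, file.path(path, "feature_names.txt"))
  obj <- data.frame(object_id = store$object_ids,
                    slide_id = store$slide_ids,
                    centroid_x = store$centroids[, 1],
                    centroid_y = store$centroids[, 2])
  utils::write.table(obj, file.path(path, "objects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(format(store$features, digits = 9, trim = TRUE,
                            scientific = NA),
                     file.path(path, "features.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_feature_store
#' @export
load_feature_store <- function(path) {
  if (!dir.exists(path)) {
    stop("feature store not found: ", path, call. = FALSE)
  }
  members <- c("features.tsv", "objects.tsv", "feature_names.txt")
  for (m in members) {
    if (!file.exists(file.path(path, m))) {
      stop("feature store at ", path, " is missing member ", m, call. = FALSE)
    }
  }
  feature_names <- readLines(file.path(path, "feature_names.txt"))
  obj <- utils::read.delim(file.path(path, "objects.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(slide_id = "character"))
  nf <- length(feature_names)
  feats <- matrix(scan(file.path(path, "features.tsv"), what = double(),
                       sep = "\t", quiet = TRUE),
                  ncol = nf, byrow = TRUE)
  feature_store(feats, obj$object_id, obj$slide_id,
                cbind(obj$centroid_x, obj$centroid_y), feature_names)
}

#' Convert store centroids from pixels to microns
#'
#' Multiplies each object's pixel centroid by its slide's microns-per-pixel
#' scale. Coordinates remain in per-slide frames: positions on different
#' slides are never comparable, only distances within one slide are.
#'
#' @param store a [feature_store()].
#' @param slides slide metadata covering every `slide_id` in the store.
#' @return K x 2 numeric matrix of centroids in microns.
#' @export
centroids_to_microns <- function(store, slides) {
  validate_slide_meta(slides)
  idx <- match(store$slide_ids, slides$slide_id)
  if (anyNA(idx)) {
    stop("slide metadata missing slide_id(s): ",
         paste(unique(store$slide_ids[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  store$centroids * slides$mpp[idx]
}
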