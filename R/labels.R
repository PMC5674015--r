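# Expert label sets. Labels are +1 (positive class), -1 (negative class) or
# NA (the "ignore" state: kept for provenance but excluded from all training
# and evaluation). Class encoding matches the tree-vote convention
# t_j in {-1, +1}.

#' Expert label set
#'
#' A label set records expert decisions on individual objects together with
#' provenance: which loop iteration produced each label and through which
#' route (`seed`, `instance`, `heatmap`, `review`, or `truth` for simulated
#' ground truth). A label of `NA` marks the ignore state: the entry is
#' retained but excluded from training and evaluation.
#'
#' @param object_ids integer vector of object ids, unique within the set.
#' @param labels integer vector in `{+1, -1}`, or `NA` for ignore.
#' @param role `"training"` or `"validation"`.
#' @param source character scalar or vector: label provenance.
#' @param iteration integer scalar or vector: loop iteration of origin.
#' @return An object of class `label_set`: a `data.frame` with columns
#'   `object_id`, `label`, `source`, `iteration` and a `role` attribute.
#' @examples
#' label_set(c(1L, 2L, 3L), c(1L, -1L, NA), role = "training")
#' @export
label_set <- function(object_ids, labels, role = c("training", "validation"),
                      source = "seed", iteration = 0L) {
  role <- match.arg(role)
  object_ids <- as.integer(object_ids)
  labels <- as.integer(labels)
  if (anyDuplicated(object_ids)) {
    stop("duplicate object_id in label set", call. = FALSE)
  }
  bad <- !is.na(labels) & !labels %in% c(-1L, 1L)
  if (any(bad)) {
    stop("labels must be +1, -1 or NA (ignore); offending value(s): ",
         paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  }
  ls <- data.frame(object_id = object_ids,
                   label = labels,
                   source = rep_len(as.character(source), length(object_ids)),
                   iteration = rep_len(as.integer(iteration),
                                       length(object_ids)))
  structure(ls, class = c("label_set", "data.frame"), role = role)
}

label_role <- function(labels) attr(labels, "role") %||% "training"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Active (non-ignored) entries of a label set
#'
#' @param labels a [label_set()].
#' @return The subset of entries whose label is +1 or -1, as a `label_set`.
#' @export
active_labels <- function(labels) {
  keep <- !is.na(labels$label)
  structure(labels[keep, , drop = FALSE],
            class = c("label_set", "data.frame"), role = label_role(labels))
}

#' @export
print.label_set <- function(x, ...) {
  act <- x$label[!is.na(x$label)]
  cat(sprintf("<label_set role=%s> %d entries (%d positive, %d negative, %d ignored)\n",
              label_role(x), nrow(x), sum(act == 1L), sum(act == -1L),
              sum(is.na(x$label))))
  invisible(x)
}

#' Append labels to a label set
#'
#' Adds newly acquired labels with their provenance. Re-labeling an object
#' already present replaces its entry (latest decision wins).
#'
#' @param labels a [label_set()].
#' @param object_ids,new_labels ids and labels to add (`NA` = ignore).
#' @param source provenance of the additions.
#' @param iteration loop iteration of the additions.
#' @return The updated `label_set`.
#' @export
append_labels <- function(labels, object_ids, new_labels, source, iteration) {
  add <- label_set(object_ids, new_labels, role = label_role(labels),
                   source = source, iteration = iteration)
  keep <- !(labels$object_id %in% add$object_id)
  out <- rbind(labels[keep, , drop = FALSE], add)
  structure(out, class = c("label_set", "data.frame"),
            role = label_role(labels))
}

#' Apply review edits to a label set
#'
#' Mirrors an expert review pass: each edit relabels an existing entry or
#' moves it to the ignore state. Edits carry `source = "review"` provenance.
#' Applying the same edit twice is a no-op; a batch of edits equals their
#' sequential application.
#'
#' @param labels a [label_set()].
#' @param edits `data.frame` with columns `object_id` and `label`
#'   (+1, -1 or NA for ignore).
#' @param iteration iteration index to record for the edits.
#' @return The edited `label_set`.
#' @export
apply_label_edits <- function(labels, edits, iteration = max(labels$iteration)) {
  unknown <- setdiff(edits$object_id, labels$object_id)
  if (length(unknown)) {
    stop("cannot edit unknown object_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  # last edit for an id wins, matching sequential application
  edits <- edits[!duplicated(edits$object_id, fromLast = TRUE), , drop = FALSE]
  i <- match(edits$object_id, labels$object_id)
  labels$label[i] <- as.integer(edits$label)
  labels$source[i] <- "review"
  labels$iteration[i] <- as.integer(iteration)
  labels
}

#' Read and write label files
#'
#' CSV dialect: header `object_id,label,source,iteration`, label one of
#' `1`, `-1`, `ignore`.
#'
#' @param path file path.
#' @param role role to assign the loaded set.
#' @param store optional [feature_store()]; when given, every labeled
#'   object_id must exist in the store.
#' @return `read_label_file()` returns a [label_set()];
#'   `write_label_file()` invisibly returns `path`.
#' @export
read_label_file <- function(path, role = c("training", "validation"),
                            store = NULL) {
  role <- match.arg(role)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  lab <- ifelse(df$label == "ignore", NA_integer_,
                suppressWarnings(as.integer(df$label)))
  bad <- which(!df$label %in% c("1", "-1", "ignore"))
  if (length(bad)) {
    stop("label file ", path, ": invalid label at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ls <- label_set(df$object_id, lab, role = role,
                  source = df$source %||% "seed",
                  iteration = df$iteration %||% 0L)
  if (!is.null(store)) {
    unknown <- setdiff(ls$object_id, store$object_ids)
    if (length(unknown)) {
      stop("label file references object_id(s) absent from the feature store: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  ls
}

#' @param labels a [label_set()].
#' @rdname read_label_file
#' @export
write_label_file <- function(labels, path) {
  df <- data.frame(object_id = labels$object_id,
                   label = ifelse(is.na(labels$label), "ignore",
                                  as.character(labels$label)),
                   source = labels$source,
                   iteration = labels$iteration)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
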