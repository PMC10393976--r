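# Core data containers: image records and labeled datasets.

#' Abnormality categories
#'
#' The lesion vocabulary used throughout the package.  `"normal"` denotes
#' no finding; the remaining eight values are the detailed abnormality
#' categories.  Binary tasks collapse every non-normal label to
#' "abnormal".
#' @format Character vectors.
#' @name categories
NULL

#' @rdname categories
#' @export
ABNORMALITY_CATEGORIES <- c(
  "disc_space_narrowing", "foraminal_stenosis", "osteophytes",
  "spondylolisthesis", "surgical_implant", "vertebral_collapse",
  "other_lesions"
)

#' @rdname categories
#' @export
PHANTOM_LESIONS <- c(
  "disc_space_narrowing", "spondylolisthesis",
  "surgical_implant", "vertebral_collapse"
)

BINARY_CLASSES <- c("normal", "abnormal")

#' Construct an image record
#'
#' One grayscale image with its identifier, condition label and
#' provenance.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param image_id character scalar, unique within a dataset.
#' @param label condition label (`"normal"`, `"abnormal"`, or a detailed
#'   abnormality category).
#' @param provenance one of `"real"`, `"phantom"`, `"synthetic"`.
#' @return an object of class `image_record`.
#' @export
image_record <- function(pixels, image_id, label,
                         provenance = c("real", "phantom", "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixels must be finite and lie in [0, 1]")
  }
  structure(
    list(pixels = pixels, image_id = as.character(image_id),
         label = as.character(label), provenance = provenance),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s: %dx%d, label=%s, provenance=%s>\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$label,
              x$provenance))
  invisible(x)
}

#' Construct a labeled dataset
#'
#' An ordered collection of [image_record()]s with a declared class
#' inventory and optional train/test split tags.
#'
#' @param records list of `image_record` objects.
#' @param classes character class inventory; defaults to the sorted
#'   unique labels present.
#' @param split optional character vector (`"train"`/`"test"`), one per
#'   record.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(records, classes = NULL, split = NULL) {
  stopifnot(is.list(records))
  labs <- vapply(records, function(r) r$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labs))
  bad <- setdiff(unique(labs), classes)
  if (length(bad)) {
    stop("labels outside the declared class inventory: ",
         paste(bad, collapse = ", "))
  }
  ids <- vapply(records, function(r) r$image_id, character(1))
  if (anyDuplicated(ids)) stop("image ids must be unique")
  if (!is.null(split)) stopifnot(length(split) == length(records))
  structure(list(records = records, classes = classes, split = split),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$records)

#' @export
`[.labeled_dataset` <- function(x, i) {
  labeled_dataset(x$records[i], classes = x$classes,
                  split = if (!is.null(x$split)) x$split[i])
}

#' @export
print.labeled_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<labeled_dataset: %d records, %d classes>\n",
              length(x), length(x$classes)))
  print(table(factor(labs, levels = x$classes)))
  invisible(x)
}

#' Dataset accessors
#'
#' `dataset_labels` returns the per-record labels;
#' `dataset_binary_labels` collapses them to 0 (normal) / 1 (abnormal);
#' `dataset_pixel_matrix` flattens the images into an `n x side^2`
#' matrix (row-per-image, column-major pixel order).
#' @param x a `labeled_dataset`.
#' @return see description.
#' @export
dataset_labels <- function(x) {
  vapply(x$records, function(r) r$label, character(1))
}

#' @rdname dataset_labels
#' @export
dataset_binary_labels <- function(x) {
  as.integer(dataset_labels(x) != "normal")
}

#' @rdname dataset_labels
#' @export
dataset_pixel_matrix <- function(x) {
  if (length(x) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  }
  dims <- dim(x$records[[1L]]$pixels)
  mats <- vapply(x$records, function(r) {
    stopifnot(all(dim(r$pixels) == dims))
    as.numeric(r$pixels)
  }, numeric(prod(dims)))
  t(mats)
}

# collapse known lesion categories to "abnormal" when the target
# inventory is binary; unknown labels are left alone so they fail the
# match below
collapse_binary <- function(labs, classes) {
  if (identical(sort(classes), sort(BINARY_CLASSES))) {
    lesion <- labs %in% c("abnormal", ABNORMALITY_CATEGORIES)
    labs[lesion] <- "abnormal"
  }
  labs
}

# map record labels onto a conditioning class inventory; binary
# inventories absorb every lesion category into "abnormal"
dataset_class_index <- function(x, classes) {
  labs <- collapse_binary(dataset_labels(x), classes)
  idx <- match(labs, classes)
  if (anyNA(idx)) {
    stop("labels not representable in class inventory: ",
         paste(unique(labs[is.na(idx)]), collapse = ", "))
  }
  idx
}

# combine datasets sharing a class inventory
dataset_bind <- function(a, b) {
  labeled_dataset(c(a$records, b$records),
                  classes = union(a$classes, b$classes))
}
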