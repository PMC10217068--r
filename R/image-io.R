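# Images are plain numeric arrays with intensities in [0, 255]:
# a H x W matrix for greyscale or a H x W x 3 array for RGB.

#' Validate an image array
#'
#' Checks that `img` is a non-empty 2-D (grey) or H x W x 3 (RGB) numeric
#' array with finite values.
#'
#' @param img Numeric matrix (grey) or 3-D array (RGB).
#' @param arg Name used in error messages.
#' @return The image, invisibly.
#' @keywords internal
check_image <- function(img, arg = "img") {
  if (!is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric array", arg), call. = FALSE)
  }
  d <- dim(img)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L))) {
    stop(sprintf("`%s` must be a H x W matrix or a H x W x 3 array", arg),
         call. = FALSE)
  }
  if (any(d[1:2] < 1L)) {
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(img)
}

#' Is the image RGB?
#' @param img An image array.
#' @return Logical.
#' @keywords internal
is_rgb <- function(img) length(dim(img)) == 3L

#' Convert an RGB image to luminance
#'
#' Uses the Rec. 601 weights 0.299 R + 0.587 G + 0.114 B. Grey images are
#' returned unchanged.
#'
#' @param img Image array in [0, 255].
#' @return A H x W matrix of luminance values.
#' @export
as_gray <- function(img) {
  check_image(img)
  if (!is_rgb(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Clip intensities to the valid range
#' @param img Numeric array.
#' @param lo,hi Range bounds.
#' @return Array with values clamped to [lo, hi].
#' @keywords internal
clip01 <- function(img, lo = 0, hi = 255) {
  img[img < lo] <- lo
  img[img > hi] <- hi
  img
}

#' Read an image file
#'
#' Reads a PNG or JPEG file into a numeric array scaled to [0, 255].
#' Grey files come back as a matrix, colour files as H x W x 3 (an alpha
#' channel, if present, is dropped).
#'
#' @param path File path; format inferred from the extension.
#' @return Image array in [0, 255].
#' @export
read_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (length(dim(x)) == 3L) {
    x <- x[, , 1]
  }
  x * 255
}

#' Write an image file
#'
#' Writes a [0, 255] image array as PNG or JPEG (format from the extension).
#'
#' @param img Image array in [0, 255].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  x <- clip01(img) / 255
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(x, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(x, path),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read a class-per-subdirectory image folder
#'
#' Expects `root/<class>/<image>.png|jpg`; subdirectory names are the class
#' labels.
#'
#' @param root Folder with one subdirectory per class.
#' @param classes Optional ordered class vector; defaults to the sorted
#'   subdirectory names.
#' @return A labelled image set: `list(images, labels, paths, classes)`.
#' @export
read_image_folder <- function(root, classes = NULL) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (is.null(classes)) classes <- sort(dirs)
  missing <- setdiff(classes, dirs)
  if (length(missing)) {
    stop("missing class subdirectories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  paths <- character(0)
  labels <- character(0)
  for (cl in classes) {
    fs <- list.files(file.path(root, cl),
                     pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                     full.names = TRUE)
    paths <- c(paths, fs)
    labels <- c(labels, rep(cl, length(fs)))
  }
  if (!length(paths)) stop("no images found under ", root, call. = FALSE)
  labeled_image_set(lapply(paths, read_image),
                    factor(labels, levels = classes),
                    paths = paths)
}

#' Construct a labelled image set
#'
#' @param images List of image arrays.
#' @param labels Factor (or character) of class labels, one per image.
#' @param paths Optional source paths.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, paths = NULL) {
  if (!length(images)) stop("empty image set", call. = FALSE)
  labels <- if (is.factor(labels)) labels else factor(labels)
  if (length(images) != length(labels)) {
    stop("images and labels must have equal length", call. = FALSE)
  }
  structure(
    list(images = images, labels = labels,
         classes = levels(labels), paths = paths),
    class = "labeled_image_set"
  )
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat("labeled_image_set:", length(x$images), "images,",
      length(x$classes), "classes\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a labelled image set to a class-per-subdirectory folder
#'
#' @param set A `labeled_image_set`.
#' @param root Destination folder (created if needed).
#' @param format "png" or "jpeg".
#' @return `root`, invisibly.
#' @export
write_image_folder <- function(set, root, format = c("png", "jpeg")) {
  format <- match.arg(format)
  for (cl in set$classes) dir.create(file.path(root, cl),
                                     recursive = TRUE, showWarnings = FALSE)
  idx_in_class <- stats::ave(seq_along(set$labels), set$labels,
                             FUN = seq_along)
  for (i in seq_along(set$images)) {
    fn <- sprintf("%s_%04d.%s", set$labels[i], idx_in_class[i], format)
    write_image(set$images[[i]], file.path(root, as.character(set$labels[i]), fn))
  }
  invisible(root)
}
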