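# Raster image input. All downstream code works on a plain numeric matrix
# in [0,1] with rows increasing downward (image convention), wrapped as a
# `root_image`.

new_root_image <- function(pixels, source_id = "image", path = NA_character_) {
  stopifnot(is.matrix(pixels))
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop_input("image must have at least one pixel")
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      source_id = source_id,
      path = path
    ),
    class = "root_image"
  )
}

#' Construct a root image from a numeric matrix
#'
#' @param pixels numeric matrix of intensities in \[0,1\], rows = image rows
#'   (top to bottom).
#' @param source_id identifier used in outputs; defaults to `"image"`.
#' @return a `root_image` object.
#' @export
as_root_image <- function(pixels, source_id = "image") {
  pixels <- clamp(pixels, 0, 1)
  new_root_image(pixels, source_id = source_id)
}

#' Load a root-crown photograph
#'
#' Reads a PNG, JPEG or TIFF image, converts colour images to grayscale by
#' luminance weighting (0.299 R + 0.587 G + 0.114 B) and rescales 8- or
#' 16-bit data to intensities in \[0,1\].
#'
#' @param path path to a PNG/JPEG/TIFF file.
#' @return a `root_image` whose `source_id` is the file name without
#'   extension.
#' @examples
#' \dontrun{
#' img <- load_image("crown_001.png")
#' }
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file does not exist: ", path),
          class = "rootcrown_format_error")
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      abort(paste0("cannot read image file: ", path, " (", conditionMessage(e), ")"),
            class = "rootcrown_format_error")
    }
  )
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    nch <- dim(dat)[3]
    if (nch >= 3) {
      dat <- 0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  # EBImage stores x (horizontal) in the first dimension; transpose to the
  # row/col matrix convention used throughout.
  px <- t(dat)
  if (length(px) == 0) {
    abort(paste0("zero-size image: ", path), class = "rootcrown_invalid_input")
  }
  px <- clamp(px, 0, 1)
  new_root_image(px,
                 source_id = tools::file_path_sans_ext(basename(path)),
                 path = path)
}

#' Write a grayscale or binary matrix as a PNG image
#'
#' Used for mask artifacts and threshold-sweep inspection images.
#'
#' @param pixels numeric or logical matrix (rows = image rows).
#' @param path output file path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  m <- t(pixels * 1)
  EBImage::writeImage(EBImage::Image(clamp(m, 0, 1)), path)
  invisible(path)
}

#' @export
print.root_image <- function(x, ...) {
  cat(sprintf("<root_image> %s: %d x %d px, intensities [%.3f, %.3f]\n",
              x$source_id, x$height, x$width,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
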