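# Optional IDX (MNIST-style) loader. No bundled data and no test depends on
# the external dataset; tests exercise the format on tiny files they write
# themselves.

#' Read an IDX image or label file
#'
#' Parses the big-endian IDX format used by the MNIST distribution: magic
#' `0x00000803` for unsigned-byte image tensors (images x rows x cols) and
#' `0x00000801` for label vectors.
#'
#' @param path Path to an (uncompressed) IDX file.
#' @return For images, an integer array `c(n, rows, cols)` with values
#'   0-255; for labels, an integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (magic == 0x00000801) {
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    return(as.integer(readBin(con, "integer", n = n, size = 1L,
                              signed = FALSE)))
  }
  if (magic == 0x00000803) {
    dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    raw <- readBin(con, "integer", n = prod(dims), size = 1L,
                   signed = FALSE)
    # stored row-major per image: fill cols fastest
    return(aperm(array(as.integer(raw), dim = rev(dims)), c(3L, 2L, 1L)))
  }
  stop("not an IDX image/label file (magic ", magic, ")", call. = FALSE)
}

#' Load digit images as intensity patterns
#'
#' Reads IDX image and label files, keeps the requested digit classes,
#' removes a frame of `crop` pixels from each border, and rescales raw pixel
#' values linearly so 0 maps to `off_level` and 255 to `on_level`.
#'
#' @param image_file,label_file Paths to IDX files.
#' @param classes Digit classes to keep (default 0-4).
#' @param crop Border width in pixels to remove (default 2: 28x28 becomes
#'   24x24).
#' @param off_level,on_level Target intensity range.
#' @return A list with the `n x N` intensity matrix `x` (rows are flattened
#'   images), integer `label`, and the image `side` length.
#' @export
load_idx_patterns <- function(image_file, label_file, classes = 0:4,
                              crop = 2, off_level = 0.05, on_level = 0.9) {
  imgs <- read_idx(image_file)
  labels <- read_idx(label_file)
  stopifnot(length(dim(imgs)) == 3L, dim(imgs)[1] == length(labels))
  keep <- which(labels %in% classes)
  side <- dim(imgs)[2]
  sel <- (crop + 1L):(side - crop)
  imgs <- imgs[keep, sel, sel, drop = FALSE]
  n <- length(keep)
  x <- matrix(aperm(imgs, c(1L, 3L, 2L)), nrow = n) # row-major flatten
  x <- off_level + (x / 255) * (on_level - off_level)
  list(x = x, label = labels[keep], side = length(sel))
}
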