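# PNG/JPEG input and output. Images are held internally as H x W x 3
# arrays of intensities in [0, 255] (channel order R, G, B); masks as
# H x W matrices in {0, 1}.

#' Read an RGB image
#'
#' Reads an 8-bit PNG or JPEG file and returns intensities scaled to
#' `[0, 255]`. Grayscale files are replicated to three channels; an alpha
#' channel is dropped.
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `H x W x 3` numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop("unsupported image format '.", ext, "' for ", path,
                     call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Read a binary mask
#'
#' Reads a PNG mask and binarizes it at half intensity.
#'
#' @param path PNG file path.
#' @return `H x W` matrix in `{0, 1}`.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  (img[, , 1L] >= 127.5) * 1L
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param path Output PNG path.
#' @export
write_image <- function(image, path) {
  img <- image / 255
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask `H x W` matrix in `{0, 1}`.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as.matrix(mask) * 1.0, path)
  invisible(path)
}

#' Write a score map
#'
#' Writes an 8-bit PNG preview and, alongside it, a lossless plain-text
#' `.tsv` with the full-precision score values (one row per image row).
#'
#' @param score `H x W` matrix in `[0, 1]`.
#' @param path Output PNG path; the text file takes the same name with
#'   `.tsv` appended.
#' @export
write_score_map <- function(score, path) {
  s <- as.matrix(score)
  s[s < 0] <- 0
  s[s > 1] <- 1
  png::writePNG(s, path)
  utils::write.table(s, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a score map written by [write_score_map()]
#'
#' Prefers the lossless `.tsv` companion when present, else falls back to
#' the 8-bit PNG.
#'
#' @param path The PNG path given to [write_score_map()].
#' @return `H x W` matrix in `[0, 1]`.
#' @export
read_score_map <- function(path) {
  tsv <- paste0(path, ".tsv")
  if (file.exists(tsv)) {
    m <- as.matrix(utils::read.table(tsv, sep = "\t"))
    dimnames(m) <- NULL
    return(m)
  }
  img <- read_image(path)
  img[, , 1L] / 255
}
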