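#' Construct an RGB image object
#'
#' An `rgb_image` stores an 8-bit (or other fixed-depth) bright-field RGB
#' image as a 3 x N integer intensity matrix, one row per channel (R, G, B)
#' and one column per pixel. Pixels are stored in R's column-major raster
#' order; all per-pixel operations in the pipeline are order-independent,
#' so the convention only matters when rendering images back to disk.
#'
#' @param pixels 3 x N numeric matrix of intensities in `[0, io_level]`.
#' @param width,height image dimensions; `width * height` must equal N.
#' @param io_level maximum (incident-light) intensity, 255 for 8-bit input.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, width, height, io_level = 255) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != 3L) stop("`pixels` must have 3 rows (R, G, B)")
  n <- ncol(pixels)
  if (n == 0L) stop("empty image: no pixels")
  if (width * height != n) {
    stop("width * height (", width * height, ") != pixel count (", n, ")")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > io_level)) {
    stop("intensities must lie in [0, io_level]")
  }
  structure(
    list(pixels = pixels, width = as.integer(width),
         height = as.integer(height), io_level = io_level),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat("<rgb_image> ", x$width, "x", x$height, " pixels, Io = ", x$io_level,
      "\n", sep = "")
  invisible(x)
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' Alpha channels are dropped with a warning; grayscale input is an error
#' since the method needs two chromatic stains.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param io_level maximum intensity of the stored image (255 for 8-bit).
#' @return An `rgb_image`.
#' @export
read_rgb_image <- function(path, io_level = 255) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(arr)) != 3L) stop("grayscale image: two-stain RGB input required")
  if (dim(arr)[3] == 4L) {
    warning("alpha channel dropped: ", path)
    arr <- arr[, , 1:3, drop = FALSE]
  }
  if (dim(arr)[3] != 3L) stop("expected 3 color channels, got ", dim(arr)[3])
  h <- dim(arr)[1]; w <- dim(arr)[2]
  px <- round(rbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]),
                    as.vector(arr[, , 3])) * io_level)
  rgb_image(px, width = w, height = h, io_level = io_level)
}

#' Write an `rgb_image` to PNG or TIFF
#'
#' @param image an `rgb_image`.
#' @param path destination path (.png, .tif or .tiff).
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- array(0, dim = c(image$height, image$width, 3L))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(image$pixels[ch, ] / image$io_level,
                          nrow = image$height, ncol = image$width)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Beer-Lambert optical-density transform
#'
#' Maps each RGB intensity to relative optical density
#' `OD = -log(I / Io)` (natural log). Intensities are clipped below at
#' `eps_floor` before the log so that zero intensities yield a large but
#' finite OD rather than infinity.
#'
#' @param image an `rgb_image`.
#' @param eps_floor intensity clip floor (default 1, one intensity level).
#' @return A 3 x N matrix of class `od_matrix` with attributes `width`,
#'   `height`, `io_level`.
#' @export
rgb_to_od <- function(image, eps_floor = 1) {
  stopifnot(inherits(image, "rgb_image"))
  if (eps_floor <= 0) stop("eps_floor must be > 0")
  io <- image$io_level
  od <- -log(pmin(pmax(image$pixels, eps_floor), io) / io)
  structure(od, width = image$width, height = image$height,
            io_level = io, class = c("od_matrix", class(od)))
}

#' Render one stain back to RGB intensities
#'
#' Inverse Beer-Lambert transform of a rank-one stain term: intensity
#' `I = round(Io * exp(-w_i * h_n))`, clipped to `[0, Io]`. Used to render
#' the separated hematoxylin / DAB panels.
#'
#' @param w non-negative 3-vector stain color (OD absorbances per channel).
#' @param h non-negative concentration vector, one entry per pixel.
#' @param width,height output image dimensions (`width * height == length(h)`).
#' @param io_level maximum intensity (default 255).
#' @return An `rgb_image`.
#' @export
od_to_rgb <- function(w, h, width, height, io_level = 255) {
  if (length(w) != 3L) stop("`w` must be a 3-vector")
  if (any(w < 0) || any(h < 0)) stop("stain color and concentrations must be non-negative")
  px <- round(io_level * exp(-outer(as.numeric(w), as.numeric(h))))
  px <- pmin(pmax(px, 0), io_level)
  rgb_image(px, width = width, height = height, io_level = io_level)
}

#' Near-white background mask
#'
#' Flags pixels whose OD 1-norm falls strictly below `tau_bg`. Such pixels
#' carry essentially no stain; their planar angle is noise-dominated, so
#' they are excluded from the angular density profile (they still enter
#' deconvolution and the features, where their concentrations are ~0).
#'
#' @param od an `od_matrix` (or any 3 x N non-negative matrix).
#' @param tau_bg OD 1-norm threshold (default 0.05); `tau_bg = 0` disables
#'   the mask (strict inequality).
#' @return Logical vector of length N, `TRUE` for background pixels.
#' @export
background_mask <- function(od, tau_bg = 0.05) {
  if (tau_bg < 0) stop("tau_bg must be >= 0")
  colSums(abs(od)) < tau_bg
}
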