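# Domain types, image I/O and pixel geometry shared by all analysis stages.

#' Fluorescence channel tags
#'
#' Channels recognised by the pipeline: the two reporter expression channels
#' (mCherry or sfGFP) and the cascade-blue-dextran (CBD) tracer channel that
#' marks the droplet-network footprint.
#'
#' @format Character vector of the three channel tags.
#' @export
FLUOR_CHANNELS <- c("expression_mCherry", "expression_sfGFP", "footprint_CBD")

# Micrographs are 12-bit data carried in 16-bit containers; values above
# 4095 indicate corrupted or mis-scaled input and are rejected, never clipped,
# because all intensity thresholds are calibrated to the 0-4095 range.
MAX_INTENSITY <- 4095

#' Construct a single-channel fluorescence micrograph
#'
#' Bundles a 2D pixel-intensity grid (arbitrary units, 12-bit range 0-4095)
#' with its channel tag and physical field of view. Pixels are stored
#' row-major with the origin at the top-left; `pixels[y, x]` is the intensity
#' at row `y`, column `x`. Anisotropic pixels are supported: the per-axis
#' pixel edge lengths are `fov_x_mm / width_px` and `fov_y_mm / height_px`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 4095]` (rows = y,
#'   columns = x).
#' @param channel One of [FLUOR_CHANNELS].
#' @param fov_x_mm,fov_y_mm Physical field of view (mm) spanned by the image
#'   in x (columns) and y (rows); both must be positive.
#' @return An object of class `fluor_image` with fields `pixels`, `channel`,
#'   `fov_x_mm`, `fov_y_mm`.
#' @examples
#' img <- fluor_image(matrix(0, 4, 6), "expression_mCherry", 0.6, 0.4)
#' width_px(img)
#' @export
fluor_image <- function(pixels, channel, fov_x_mm, fov_y_mm) {
  channel <- match.arg(channel, FLUOR_CHANNELS)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels)) {
    stop("'pixels' must be a numeric matrix without missing values")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must contain at least one pixel")
  }
  if (!is.numeric(fov_x_mm) || !is.numeric(fov_y_mm) ||
      fov_x_mm <= 0 || fov_y_mm <= 0) {
    stop("field-of-view dimensions must be positive")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > MAX_INTENSITY) {
    bad <- pixels[which(pixels < 0 | pixels > MAX_INTENSITY)[1]]
    stop(sprintf(
      "pixel value %s outside the 12-bit range [0, %d]", format(bad),
      as.integer(MAX_INTENSITY)
    ))
  }
  structure(
    list(pixels = pixels, channel = channel,
         fov_x_mm = as.numeric(fov_x_mm), fov_y_mm = as.numeric(fov_y_mm)),
    class = "fluor_image"
  )
}

#' @rdname fluor_image
#' @param img A `fluor_image`.
#' @export
width_px <- function(img) ncol(img$pixels)

#' @rdname fluor_image
#' @export
height_px <- function(img) nrow(img$pixels)

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %s, %d x %d px, FOV %.4f x %.4f mm, range [%g, %g] a.u.\n",
    x$channel, width_px(x), height_px(x), x$fov_x_mm, x$fov_y_mm,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Area of a single pixel
#'
#' Physical area (mm^2) of one pixel given the field of view and the image
#' dimensions: `(fov_x_mm / width_px) * (fov_y_mm / height_px)`. At the
#' microscope settings used throughout (1920 x 1440 px spanning
#' 2.4887 x 1.8662 mm) this is 1.68e-6 mm^2.
#'
#' @param fov_x_mm,fov_y_mm Field of view (mm); positive.
#' @param width_px,height_px Image dimensions in pixels; positive.
#' @return Pixel area in mm^2.
#' @examples
#' pixel_area(2.4887, 1.8662, 1920, 1440)
#' @export
pixel_area <- function(fov_x_mm, fov_y_mm, width_px, height_px) {
  args <- c(fov_x_mm, fov_y_mm, width_px, height_px)
  if (!is.numeric(args) || any(args <= 0)) {
    stop("all pixel-geometry arguments must be positive")
  }
  (fov_x_mm / width_px) * (fov_y_mm / height_px)
}

# Pixel area of a fluor_image from its own geometry.
img_pixel_area <- function(img) {
  pixel_area(img$fov_x_mm, img$fov_y_mm, width_px(img), height_px(img))
}

# Per-axis pixel edge lengths (mm): c(x =, y =).
img_pixel_size <- function(img) {
  c(x = img$fov_x_mm / width_px(img), y = img$fov_y_mm / height_px(img))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a grayscale TIFF micrograph
#'
#' Reads a single-channel 16-bit TIFF containing 12-bit data. Values are read
#' as stored (no rescaling); any pixel above 4095 is an error, not clipped.
#' If a JSON sidecar `<path>.json` (as written by [save_image()]) is present,
#' the channel tag and field of view are taken from it; arguments override
#' the sidecar.
#'
#' @param path Path to a grayscale TIFF file.
#' @param channel Channel tag (see [FLUOR_CHANNELS]); required if no sidecar.
#' @param fov_x_mm,fov_y_mm Field of view (mm); required if no sidecar.
#' @return A [fluor_image()].
#' @export
load_image <- function(path, channel = NULL, fov_x_mm = NULL, fov_y_mm = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(channel)) channel <- meta$channel
    if (is.null(fov_x_mm)) fov_x_mm <- meta$fov_x_mm
    if (is.null(fov_y_mm)) fov_y_mm <- meta$fov_y_mm
  }
  if (is.null(channel) || is.null(fov_x_mm) || is.null(fov_y_mm)) {
    stop("channel and field of view must be given (no JSON sidecar found)")
  }
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) != 2L) {
    stop(sprintf("expected grayscale data, got %d channels", dim(raw)[3]))
  }
  if (max(raw) > MAX_INTENSITY) {
    stop(sprintf(
      "pixel value %s outside the 12-bit range [0, %d]",
      format(max(raw)), as.integer(MAX_INTENSITY)
    ))
  }
  fluor_image(raw, channel, fov_x_mm, fov_y_mm)
}

#' Write a micrograph as a 16-bit grayscale TIFF
#'
#' Stores integer intensities bit-exactly in a 16-bit container and writes a
#' JSON sidecar `<path>.json` holding the channel tag and field of view, so
#' that [load_image()] round-trips the full object.
#'
#' @param img A [fluor_image()] with integer-valued pixels.
#' @param path Output TIFF path.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "fluor_image"))
  px <- img$pixels
  if (any(px != round(px))) {
    stop("pixel values must be integers to be stored losslessly in 16-bit TIFF")
  }
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  if (sidecar) {
    jsonlite::write_json(
      list(channel = img$channel, fov_x_mm = img$fov_x_mm,
           fov_y_mm = img$fov_y_mm),
      sidecar_path(path), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Export a binary mask as a 0/255 image
#'
#' @param mask Logical matrix.
#' @param path Output path; `.png` writes an 8-bit PNG, anything else a TIFF.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  m <- mask * 1.0  # writers scale [0,1] to the full container range
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(path)
}
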