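# Core scoring: activation/footprint masks, area decomposition, the
# pattern-fidelity index, activated-pixel intensity statistics, and the
# volume-to-surface-area ratio of a droplet network.

#' Intensity thresholds for mask construction
#'
#' `I_B` is the activation threshold on the expression channel: pixels at or
#' above it are "activated" (induced gene expression). It equals the mean
#' baseline intensity of lawns never exposed to inducer — 179 a.u. for
#' mCherry, 200 a.u. for sfGFP. `I_CBD` is the threshold on the
#' cascade-blue-dextran channel that outlines the droplet-network footprint
#' (500 a.u. at the standard tracer concentration).
#'
#' @param I_B Activation threshold (a.u.), in `(0, 4095]`.
#' @param I_CBD Footprint threshold (a.u.), in `(0, 4095]`.
#' @return An object of class `thresholds`.
#' @seealso [default_thresholds()], [compute_baseline()]
#' @export
thresholds <- function(I_B = 179, I_CBD = 500) {
  for (v in c(I_B = I_B, I_CBD = I_CBD)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > MAX_INTENSITY) {
      stop("thresholds must be single values in (0, 4095]")
    }
  }
  structure(list(I_B = I_B, I_CBD = I_CBD), class = "thresholds")
}

#' @rdname thresholds
#' @param mode Reporter mode: `"mcherry"` (threshold 179 a.u.) or `"sfgfp"`
#'   (threshold 200 a.u.).
#' @export
default_thresholds <- function(mode = c("mcherry", "sfgfp")) {
  mode <- match.arg(mode)
  thresholds(I_B = if (mode == "mcherry") 179 else 200, I_CBD = 500)
}

#' Binary activation mask of an expression image
#'
#' A pixel is activated iff its intensity is greater than or equal to the
#' threshold (the Heaviside convention `H(0) = 1`: a pixel exactly at the
#' baseline counts as induced).
#'
#' @param img Expression-channel [fluor_image()].
#' @param threshold Activation threshold (a.u.) in `(0, 4095]`.
#' @return Logical matrix of the same dimensions as the image.
#' @export
activation_mask <- function(img, threshold) {
  stopifnot(inherits(img, "fluor_image"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > MAX_INTENSITY) {
    stop("activation threshold must lie in (0, 4095]")
  }
  img$pixels >= threshold
}

#' Binary footprint mask of a cascade-blue-dextran image
#'
#' A pixel belongs to the network footprint iff its CBD intensity is greater
#' than or equal to `I_CBD`. "Outside the footprint" is everywhere else (the
#' strict complement), so footprint and non-footprint partition the frame;
#' as a consequence the area identities of [compute_metrics()] hold exactly.
#'
#' @param cbd Footprint-channel [fluor_image()] (channel `footprint_CBD`).
#' @param I_CBD Footprint threshold (a.u.), default 500.
#' @return Logical matrix.
#' @export
footprint_mask <- function(cbd, I_CBD = 500) {
  stopifnot(inherits(cbd, "fluor_image"))
  if (!identical(cbd$channel, "footprint_CBD")) {
    stop(sprintf("footprint mask needs the footprint_CBD channel, got %s",
                 cbd$channel))
  }
  if (!is.numeric(I_CBD) || length(I_CBD) != 1L ||
      I_CBD <= 0 || I_CBD > MAX_INTENSITY) {
    stop("I_CBD must lie in (0, 4095]")
  }
  cbd$pixels >= I_CBD
}

#' Baseline expression intensity from control images
#'
#' The activation threshold `I_B` is the mean of all pixel values over
#' control micrographs of bacterium-laden hydrogels never exposed to
#' arabinose. With no controls supplied, the calibrated constants are used:
#' 179 a.u. (mCherry) or 200 a.u. (sfGFP).
#'
#' @param control_images List of expression-channel [fluor_image()]s sharing
#'   one channel tag; may be empty if `mode` is given.
#' @param mode `"mcherry"` or `"sfgfp"`; only consulted when
#'   `control_images` is empty.
#' @return Baseline intensity (a.u.).
#' @export
compute_baseline <- function(control_images = list(), mode = NULL) {
  if (length(control_images) == 0L) {
    if (is.null(mode)) {
      stop("no control images supplied and no default mode requested")
    }
    return(default_thresholds(mode)$I_B)
  }
  stopifnot(all(vapply(control_images, inherits, logical(1), "fluor_image")))
  ch <- unique(vapply(control_images, `[[`, character(1), "channel"))
  if (length(ch) != 1L) stop("control images must all share one channel")
  mean(unlist(lapply(control_images, `[[`, "pixels")))
}

#' Pattern metrics of an expression / footprint image pair
#'
#' The central quantification. With activation mask `act` (expression pixel
#' \eqn{\ge I_B}) and footprint mask `fp` (CBD pixel \eqn{\ge I_{CBD}}):
#' \itemize{
#'   \item `N_a`: number of activated pixels in the whole frame;
#'   \item `I_T`: sum of the raw intensities of activated pixels (a.u.);
#'   \item `I_M`: `I_T / N_a`, the mean activated intensity (0 when
#'     `N_a = 0`, with a warning);
#'   \item `A_I`: intended-expression area, `A_pix * count(fp)` (mm^2);
#'   \item `A_U`: unintended-expression area, `A_pix * count(act & !fp)`;
#'   \item `A_N`: no-expression area inside the footprint,
#'     `A_pix * count(!act & fp)`;
#'   \item `PF`: the pattern-fidelity index `(A_I - A_U) / A_I`.
#' }
#' `PF` approaches 1 when expression is confined to the footprint, and may be
#' negative when the unintended area exceeds the intended one; it is reported
#' as computed, never clamped. When `A_I = 0` it is `NaN` with a warning.
#'
#' @param expr Expression-channel [fluor_image()].
#' @param cbd Footprint-channel [fluor_image()] of identical dimensions.
#' @param thr A [thresholds()] object.
#' @param A_pix Pixel area (mm^2); defaults to the geometry of `expr`.
#' @return An object of class `pattern_metrics`: a list with fields `A_I`,
#'   `A_U`, `A_N`, `PF`, `I_M`, `I_T`, `N_a`, `A_pix`.
#' @examples
#' fov <- c(0.6, 0.45)
#' fp <- matrix(0, 12, 16); fp[4:9, 5:12] <- 4000
#' ex <- matrix(100, 12, 16); ex[4:9, 5:12] <- 800
#' m <- compute_metrics(
#'   fluor_image(ex, "expression_mCherry", fov[1], fov[2]),
#'   fluor_image(fp, "footprint_CBD", fov[1], fov[2])
#' )
#' m$PF  # 1: expression exactly on the footprint
#' @export
compute_metrics <- function(expr, cbd, thr = default_thresholds(),
                            A_pix = NULL) {
  stopifnot(inherits(expr, "fluor_image"), inherits(thr, "thresholds"))
  if (!identical(dim(expr$pixels), dim(cbd$pixels))) {
    stop(sprintf(
      "image dimensions differ: expression %d x %d vs footprint %d x %d",
      width_px(expr), height_px(expr), width_px(cbd), height_px(cbd)
    ))
  }
  if (is.null(A_pix)) A_pix <- img_pixel_area(expr)
  if (!is.numeric(A_pix) || A_pix <= 0) stop("A_pix must be positive")

  act <- activation_mask(expr, thr$I_B)
  fp <- footprint_mask(cbd, thr$I_CBD)

  N_a <- sum(act)
  # double accumulation: activated-intensity totals exceed 32-bit range
  I_T <- sum(as.numeric(expr$pixels[act]))
  I_M <- if (N_a > 0) I_T / N_a else {
    warning("no activated pixels; I_M reported as 0")
    0
  }
  A_I <- A_pix * sum(fp)
  A_U <- A_pix * sum(act & !fp)
  A_N <- A_pix * sum(!act & fp)
  PF <- if (A_I > 0) (A_I - A_U) / A_I else {
    warning("empty footprint (A_I = 0); PF is undefined (NaN)")
    NaN
  }
  structure(
    list(A_I = A_I, A_U = A_U, A_N = A_N, PF = PF,
         I_M = I_M, I_T = I_T, N_a = N_a, A_pix = A_pix),
    class = "pattern_metrics"
  )
}

#' @export
print.pattern_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<pattern_metrics> PF = %.4f | A_I = %.4g, A_U = %.4g, ",
           "A_N = %.4g mm^2 | I_M = %.1f a.u., I_T = %.4g a.u., N_a = %d\n"),
    x$PF, x$A_I, x$A_U, x$A_N, x$I_M, x$I_T, x$N_a
  ))
  invisible(x)
}

#' @export
as.data.frame.pattern_metrics <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Droplet-count specification of a printed network
#'
#' Layer and droplet counts used to convert a measured footprint area into a
#' network volume for [compute_rvsa()]. For uniform networks
#' `total_droplets = n_layers * droplets_per_layer`.
#'
#' @param n_layers Number of printed layers (>= 1).
#' @param droplets_per_layer Droplets in each layer (>= 1).
#' @param total_droplets Total droplets in the network; defaults to the
#'   uniform product.
#' @return An object of class `rvsa_spec`.
#' @export
rvsa_spec <- function(n_layers, droplets_per_layer,
                      total_droplets = n_layers * droplets_per_layer) {
  counts <- c(n_layers, droplets_per_layer, total_droplets)
  if (!is.numeric(counts) || any(counts < 1) || any(counts != round(counts))) {
    stop("all droplet counts must be integers >= 1")
  }
  structure(
    list(n_layers = as.integer(n_layers),
         droplets_per_layer = as.integer(droplets_per_layer),
         total_droplets = as.integer(total_droplets)),
    class = "rvsa_spec"
  )
}

#' Volume-to-surface-area ratio of a droplet network
#'
#' Measures stored cargo per unit release area (mm). From the measured
#' intended area `A_I` and the droplet counts: the cross-sectional area of a
#' single droplet is `A_I / droplets_per_layer`; its equivalent-circle
#' diameter `d` gives a single-droplet sphere volume `pi d^3 / 6`; the
#' network volume `V` is that times `total_droplets`; the ratio is `V / A_I`.
#' Networks of 4, 8 and 16 layers at fixed footprint double the ratio with
#' each doubling of layers. Droplet truncation by interface bilayers is not
#' modelled: droplets are treated as spheres of the measured cross-section.
#'
#' @param A_I Intended-expression (footprint) area, mm^2; positive.
#' @param spec An [rvsa_spec()].
#' @return The ratio in mm.
#' @examples
#' compute_rvsa(0.36, rvsa_spec(8, 64))  # ~0.45 mm
#' @export
compute_rvsa <- function(A_I, spec) {
  stopifnot(inherits(spec, "rvsa_spec"))
  if (!is.numeric(A_I) || length(A_I) != 1L || A_I <= 0) {
    stop("A_I must be a positive area")
  }
  cross_section <- A_I / spec$droplets_per_layer
  d <- 2 * sqrt(cross_section / pi)
  v_droplet <- pi * d^3 / 6
  spec$total_droplets * v_droplet / A_I
}

#' Equivalent spherical diameter of a droplet volume
#'
#' Diameter (um) of a sphere with the given volume. The ~150 pL droplets
#' produced by the printer correspond to ~66 um, i.e. 65 um at the 5-um
#' printing grain.
#'
#' @param volume_pL Droplet volume in picoliters; positive.
#' @return Diameter in micrometers.
#' @examples
#' droplet_diameter_from_volume(150)
#' @export
droplet_diameter_from_volume <- function(volume_pL) {
  if (!is.numeric(volume_pL) || any(volume_pL <= 0)) {
    stop("droplet volume must be positive")
  }
  v_mm3 <- volume_pL * 1e-6  # 1 pL = 1e-6 mm^3
  1e3 * (6 * v_mm3 / pi)^(1 / 3)
}
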