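# Synthetic two-channel micrographs with exact geometric ground truth, plus
# induction time courses and colony fields. This is the verifiable stand-in
# for raw experimental images: the geometry (footprint, halo, contact holes)
# is deterministic, only pixel intensities are stochastic, and the noise is
# kept on the correct side of every threshold so that ground-truth areas are
# recovered exactly up to rasterization.

# Truncated-normal integers on [lo, hi]. Inverse-CDF sampling of the
# continuous truncated normal, then rounding clamped back into [lo, hi]
# (rounding can otherwise step across a truncation bound). sd = 0 gives the
# clamped mean exactly, which keeps noise-free cases deterministic.
rtrunc_int <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer(0))
  if (sd <= 0) return(rep(as.integer(pmin(pmax(round(mean), lo), hi)), n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
  as.integer(pmin(pmax(round(x), lo), hi))
}

#' Parameters of the synthetic micrograph generator
#'
#' Describes one simulated experiment: the printed release pattern, the frame
#' geometry, the diffusion halo, the droplet-hydrogel contact failures, and
#' the intensity statistics of both channels. Defaults reproduce the imaging
#' conditions of the quantification pipeline: 1920 x 1440 px over
#' 2.4887 x 1.8662 mm, baseline expression just below the 179 a.u. mCherry
#' activation threshold, activated expression centred on 634 a.u., and a
#' 100-um halo of unintended expression beyond the footprint edge.
#'
#' @param map A [printing_map()]; its bottom-layer cargo droplets define the
#'   footprint.
#' @param width_px,height_px,fov_x_mm,fov_y_mm Frame geometry.
#' @param halo_width_um Width of the unintended-expression rim around the
#'   footprint (um, >= 0). Modelled as an exact geometric dilation of the
#'   droplet disks, standing in for unmodelled inducer diffusion.
#' @param hole_fraction Fraction (0-1) of bottom-layer cargo droplets that
#'   fail to form a droplet-hydrogel bilayer; whole droplets fail, producing
#'   non-expressing footprint area.
#' @param bg_mean,bg_sd Background expression intensity (a.u.); `bg_mean`
#'   must be below the activation threshold.
#' @param act_mean,act_sd Activated expression intensity (a.u.); `act_mean`
#'   must be at or above the activation threshold.
#' @param cbd_in,cbd_out,cbd_sd Footprint-channel intensities inside /
#'   outside the footprint; `cbd_in` at or above and `cbd_out` below the
#'   footprint threshold.
#' @param mode Reporter mode, fixes the default thresholds (179 / 200 a.u.).
#' @param thr Optional [thresholds()] overriding the mode defaults.
#' @param seed Optional RNG seed; fixing it makes the whole image pair
#'   reproducible (hole selection and intensity noise).
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(map = builtin_pattern("full"),
                         width_px = 1920, height_px = 1440,
                         fov_x_mm = 2.4887, fov_y_mm = 1.8662,
                         halo_width_um = 100, hole_fraction = 0,
                         bg_mean = 150, bg_sd = 10,
                         act_mean = 634, act_sd = 80,
                         cbd_in = 2000, cbd_out = 100, cbd_sd = 20,
                         mode = c("mcherry", "sfgfp"), thr = NULL,
                         seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(thr)) thr <- default_thresholds(mode)
  stopifnot(inherits(map, "printing_map"), inherits(thr, "thresholds"))
  if (hole_fraction < 0 || hole_fraction > 1) {
    stop("hole_fraction must lie in [0, 1]")
  }
  if (halo_width_um < 0) stop("halo_width_um must be >= 0")
  if (bg_mean >= thr$I_B) {
    stop("background mean must be below the activation threshold")
  }
  if (act_mean < thr$I_B) {
    stop("activated mean must be at or above the activation threshold")
  }
  if (cbd_out >= thr$I_CBD || cbd_in < thr$I_CBD) {
    stop("cbd_out must be below and cbd_in at or above I_CBD")
  }
  structure(
    list(map = map, width_px = width_px, height_px = height_px,
         fov_x_mm = fov_x_mm, fov_y_mm = fov_y_mm,
         halo_width_um = halo_width_um, hole_fraction = hole_fraction,
         bg_mean = bg_mean, bg_sd = bg_sd,
         act_mean = act_mean, act_sd = act_sd,
         cbd_in = cbd_in, cbd_out = cbd_out, cbd_sd = cbd_sd,
         mode = mode, thr = thr, seed = seed),
    class = "synth_params"
  )
}

#' Simulate a two-channel micrograph pair with exact ground truth
#'
#' Generates a footprint (CBD) image and an expression image. The true
#' expression region is the footprint dilated by the halo width, minus the
#' disks of the contact-failure droplets (the tracer is still present in
#' failed droplets, so they remain part of the footprint but not of the
#' expression region). Dilation is exact: the union of droplet disks with
#' radius inflated by the halo width. Intensities are truncated-normal draws
#' kept strictly on the correct side of the relevant threshold, so the
#' ground-truth areas below are exact raster counts, not expectations.
#'
#' @param params A [synth_params()].
#' @return List with elements `cbd` and `expr` (two [fluor_image()]s),
#'   `truth` (class `synthetic_truth`: `PF_true`, `A_I_true`, `A_U_true`,
#'   `A_N_true`, `activated_mask_true`, `footprint` (a `footprint_truth`),
#'   `hole_droplets`), and `params`.
#' @examples
#' p <- synth_params(builtin_pattern("full", n_layers = 4), width_px = 320,
#'                   height_px = 240, halo_width_um = 0, bg_sd = 0,
#'                   act_sd = 0, cbd_sd = 0, seed = 1)
#' sim <- simulate_image_pair(p)
#' compute_metrics(sim$expr, sim$cbd)$PF  # recovers PF_true = 1 exactly
#' @export
simulate_image_pair <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)

  fp <- render_footprint(p$map, p$width_px, p$height_px,
                         p$fov_x_mm, p$fov_y_mm,
                         pattern_name = "synthetic")
  n_cargo <- sum(p$map$layers[[1]] == MAP_STATES[["cargo"]])
  # contact failures: the first k droplets of a seeded permutation, so the
  # failed set is nested as hole_fraction grows under a fixed seed
  n_holes <- round(p$hole_fraction * n_cargo)
  holes <- if (n_cargo > 0L) sample(n_cargo)[seq_len(n_holes)] else integer(0)

  dilated <- render_footprint(p$map, p$width_px, p$height_px,
                              p$fov_x_mm, p$fov_y_mm,
                              dilate_um = p$halo_width_um)
  hole_mask <- if (n_holes > 0L) {
    render_footprint(p$map, p$width_px, p$height_px, p$fov_x_mm, p$fov_y_mm,
                     droplet_subset = holes)$mask
  } else {
    matrix(FALSE, p$height_px, p$width_px)
  }
  act_true <- dilated$mask & !hole_mask

  A_pix <- pixel_area(p$fov_x_mm, p$fov_y_mm, p$width_px, p$height_px)
  A_I <- fp$area_mm2
  A_U <- A_pix * sum(act_true & !fp$mask)
  A_N <- A_pix * sum(!act_true & fp$mask)
  if (A_I == 0) {
    warning("degenerate truth: footprint mask is empty, PF_true undefined")
  }
  PF_true <- if (A_I > 0) (A_I - A_U) / A_I else NaN

  expr_px <- matrix(0L, p$height_px, p$width_px)
  n_act <- sum(act_true)
  expr_px[act_true] <- rtrunc_int(n_act, p$act_mean, p$act_sd,
                                  p$thr$I_B, MAX_INTENSITY)
  expr_px[!act_true] <- rtrunc_int(length(expr_px) - n_act, p$bg_mean,
                                   p$bg_sd, 0, p$thr$I_B - 1)
  cbd_px <- matrix(0L, p$height_px, p$width_px)
  n_fp <- sum(fp$mask)
  cbd_px[fp$mask] <- rtrunc_int(n_fp, p$cbd_in, p$cbd_sd,
                                p$thr$I_CBD, MAX_INTENSITY)
  cbd_px[!fp$mask] <- rtrunc_int(length(cbd_px) - n_fp, p$cbd_out,
                                 p$cbd_sd, 0, p$thr$I_CBD - 1)

  channel <- if (p$mode == "mcherry") "expression_mCherry" else
    "expression_sfGFP"
  list(
    cbd = fluor_image(cbd_px, "footprint_CBD", p$fov_x_mm, p$fov_y_mm),
    expr = fluor_image(expr_px, channel, p$fov_x_mm, p$fov_y_mm),
    truth = structure(
      list(PF_true = PF_true, A_I_true = A_I, A_U_true = A_U,
           A_N_true = A_N, activated_mask_true = act_true,
           footprint = fp, hole_droplets = holes),
      class = "synthetic_truth"
    ),
    params = p
  )
}

#' Simulate a switch-like induction time course
#'
#' Total expression intensity over time. Under the `"full"` condition
#' (inducer plus pore) the curve is flat near baseline, rises rapidly around
#' the onset and is flat again after the plateau time — the all-or-nothing
#' behaviour of an arabinose-inducible promoter, with fluorescence first
#' detected around 10 h and saturating around 18 h. Without pore
#' (`"no_pore"`) or without inducer (`"no_signal"`) the series stays at
#' baseline. The deterministic profile is a logistic centred midway between
#' onset and plateau with scale `(plateau - onset) / 8`, so that the signal
#' is below ~1 percent of the amplitude at the onset and above ~98 percent at
#' the plateau.
#'
#' @param times_h Sampling times (h, non-negative).
#' @param onset_h,plateau_h Rise onset and saturation times (h);
#'   `onset_h < plateau_h`.
#' @param amplitude Plateau total intensity above baseline (a.u.).
#' @param baseline Baseline total intensity (a.u.).
#' @param condition `"full"`, `"no_pore"` or `"no_signal"`.
#' @param noise_sd Gaussian noise on each point; defaults to 1 percent of the
#'   amplitude.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `time_h`, `I_T`.
#' @export
simulate_timecourse <- function(times_h = seq(0, 24, by = 0.5),
                                onset_h = 10, plateau_h = 18,
                                amplitude = 1.4e8, baseline = 1e6,
                                condition = c("full", "no_pore", "no_signal"),
                                noise_sd = 0.01 * amplitude, seed = NULL) {
  condition <- match.arg(condition)
  if (any(times_h < 0) || onset_h < 0 || plateau_h < 0) {
    stop("times must be non-negative")
  }
  if (onset_h >= plateau_h) stop("onset must precede the plateau")
  if (!is.null(seed)) set.seed(seed)
  mid <- (onset_h + plateau_h) / 2
  scale <- (plateau_h - onset_h) / 8
  amp <- if (condition == "full") amplitude else 0
  y <- baseline + amp * stats::plogis((times_h - mid) / scale)
  if (noise_sd > 0) y <- y + stats::rnorm(length(times_h), 0, noise_sd)
  data.frame(time_h = times_h, I_T = y)
}

#' Simulate a field of fluorescent micro-colonies
#'
#' Places `n_colonies` bright disks at rejection-sampled centers on a noisy
#' background. Centers keep a minimum separation of one diameter plus
#' `margin_um`, so at the default margin distinct colonies never share or
#' touch pixels; colony pixels are drawn at or above `threshold` and
#' background pixels below it.
#'
#' @param n_colonies Number of colonies (>= 0).
#' @param radius_um Colony radius (um).
#' @param width_px,height_px,fov_x_mm,fov_y_mm Frame geometry; the default
#'   640 x 480 px frame spans the standard field of view.
#' @param margin_um Minimum edge-to-edge spacing between colonies (um).
#' @param intensity_mean,intensity_sd Colony intensity statistics (a.u.).
#' @param bg_mean,bg_sd Background intensity statistics (a.u.).
#' @param threshold Intensity threshold separating colonies from background.
#' @param seed Optional RNG seed.
#' @param max_tries Rejection-sampling attempts per colony before giving up.
#' @return List with `image` (a [fluor_image()]), `n_true`, `mask_true`
#'   (noiseless colony mask) and `centers` (data frame, mm).
#' @export
simulate_colony_field <- function(n_colonies, radius_um = 15,
                                  width_px = 640, height_px = 480,
                                  fov_x_mm = 2.4887, fov_y_mm = 1.8662,
                                  margin_um = 20,
                                  intensity_mean = 1000, intensity_sd = 50,
                                  bg_mean = 100, bg_sd = 20,
                                  threshold = 500, seed = NULL,
                                  max_tries = 5000L) {
  if (n_colonies < 0 || n_colonies != round(n_colonies)) {
    stop("n_colonies must be a non-negative integer")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- radius_um / 1000
  sep <- 2 * r + margin_um / 1000
  # feasibility: disks of diameter `sep` must fit loosely in the frame
  usable <- max(0, fov_x_mm - 2 * r) * max(0, fov_y_mm - 2 * r)
  if (n_colonies > 0 && n_colonies * sep^2 > 0.7 * usable) {
    stop(sprintf(
      "cannot pack %d colonies of radius %g um into a %g x %g mm frame",
      n_colonies, radius_um, fov_x_mm, fov_y_mm
    ))
  }
  xs <- numeric(0); ys <- numeric(0)
  for (k in seq_len(n_colonies)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, r, fov_x_mm - r)
      y <- stats::runif(1, r, fov_y_mm - r)
      if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= sep^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed) {
      stop(sprintf("failed to place colony %d of %d after %d attempts",
                   k, n_colonies, max_tries))
    }
  }
  mask <- rasterize_disks(xs, ys, r, width_px, height_px, fov_x_mm, fov_y_mm)
  px <- matrix(0L, height_px, width_px)
  n_in <- sum(mask)
  px[mask] <- rtrunc_int(n_in, intensity_mean, intensity_sd,
                         threshold, MAX_INTENSITY)
  px[!mask] <- rtrunc_int(length(px) - n_in, bg_mean, bg_sd, 0, threshold - 1)
  list(
    image = fluor_image(px, "expression_sfGFP", fov_x_mm, fov_y_mm),
    n_true = as.integer(n_colonies),
    mask_true = mask,
    centers = data.frame(x_mm = xs, y_mm = ys)
  )
}
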