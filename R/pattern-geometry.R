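# Printing maps (droplet occupancy grids) and their rasterization into
# footprint masks with hexagonal close-packing.

#' Droplet cell states in a printing map
#'
#' `0` = empty (no droplet printed), `1` = cargo (arabinose + alpha-hemolysin
#' + cascade blue dextran), `2` = inert (droplet printed without cargo).
#'
#' @format Named integer vector.
#' @export
MAP_STATES <- c(empty = 0L, cargo = 1L, inert = 2L)

#' Construct a layered droplet occupancy grid
#'
#' A printing map is the machine-readable release pattern: a stack of layers,
#' each a grid of droplet positions in one of the states of [MAP_STATES].
#' Only the bottom layer (layer 1) touches the hydrogel and forms
#' droplet-hydrogel bilayers, so only its cargo droplets define the release
#' footprint; upper layers contribute to storage volume (see
#' [compute_rvsa()]).
#'
#' @param layers List of integer matrices (identical dimensions) with values
#'   in [MAP_STATES]; `layers[[1]]` is the bottom layer.
#' @param droplet_diameter_um Printed droplet diameter (um); the printer
#'   produces 60-120 um droplets, and diameters outside that band are
#'   accepted but unusual.
#' @param packing Lattice of droplet centers: `"hexagonal"` (close-packed;
#'   odd rows offset by half a diameter, row pitch `d * sqrt(3) / 2`) or
#'   `"square"`.
#' @return An object of class `printing_map`.
#' @seealso [builtin_pattern()], [render_footprint()]
#' @export
printing_map <- function(layers, droplet_diameter_um = 100,
                         packing = c("hexagonal", "square")) {
  packing <- match.arg(packing)
  if (!is.list(layers) || length(layers) < 1L) {
    stop("'layers' must be a non-empty list of occupancy matrices")
  }
  dims <- lapply(layers, dim)
  if (any(vapply(layers, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1)))) {
    stop("each layer must be a numeric matrix")
  }
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all layers must share the same grid dimensions")
  }
  vals <- unique(unlist(layers))
  if (!all(vals %in% MAP_STATES)) {
    stop("layer entries must be 0 (empty), 1 (cargo) or 2 (inert)")
  }
  if (!is.numeric(droplet_diameter_um) || droplet_diameter_um <= 0) {
    stop("droplet diameter must be positive")
  }
  structure(
    list(layers = lapply(layers, function(m) {
           storage.mode(m) <- "integer"; m
         }),
         droplet_diameter_um = as.numeric(droplet_diameter_um),
         packing = packing),
    class = "printing_map"
  )
}

#' @export
print.printing_map <- function(x, ...) {
  cat(sprintf(
    "<printing_map> %d layer(s) of %d x %d, d = %g um, %s packing, %d cargo droplets (bottom layer)\n",
    length(x$layers), nrow(x$layers[[1]]), ncol(x$layers[[1]]),
    x$droplet_diameter_um, x$packing, sum(x$layers[[1]] == MAP_STATES["cargo"])
  ))
  invisible(x)
}

#' Built-in release patterns
#'
#' Reconstructions of the qualitative cross-sectional patterns printed in
#' the source experiments: a full network, a cross, a triangle, a
#' one-droplet-wide closed frame, a stripe, and a linear single-droplet
#' pathway. The same cross-section is used in every layer. Cells that are
#' not cargo are inert droplets (printed, but without arabinose, pore or
#' tracer), as in the experimental patterned networks.
#'
#' @param name One of `"full"`, `"cross"`, `"triangle"`, `"frame"`,
#'   `"stripe"`, `"single_path"`.
#' @param grid_rows,grid_cols Grid dimensions (default 8 x 8).
#' @param n_layers Number of layers (default 8).
#' @param droplet_diameter_um,packing Passed to [printing_map()].
#' @return A [printing_map()].
#' @examples
#' builtin_pattern("cross")
#' @export
builtin_pattern <- function(name, grid_rows = 8, grid_cols = 8, n_layers = 8,
                            droplet_diameter_um = 100,
                            packing = "hexagonal") {
  known <- c("full", "cross", "triangle", "frame", "stripe", "single_path")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    stop(sprintf("unknown pattern '%s'; available: %s",
                 as.character(name)[1], paste(known, collapse = ", ")))
  }
  cargo <- MAP_STATES[["cargo"]]
  inert <- MAP_STATES[["inert"]]
  m <- matrix(inert, grid_rows, grid_cols)
  mid_r <- ceiling(grid_rows / 2) + seq_len(2 - grid_rows %% 2) - 1L
  mid_c <- ceiling(grid_cols / 2) + seq_len(2 - grid_cols %% 2) - 1L
  switch(name,
    full = { m[] <- cargo },
    cross = { m[mid_r, ] <- cargo; m[, mid_c] <- cargo },
    triangle = {
      for (i in seq_len(grid_rows)) {
        k <- ceiling(i * grid_cols / grid_rows)
        m[i, seq_len(k)] <- cargo
      }
    },
    frame = {
      m[c(1L, grid_rows), ] <- cargo
      m[, c(1L, grid_cols)] <- cargo
    },
    stripe = { m[, mid_c] <- cargo },
    single_path = { m[mid_r[1], ] <- cargo }
  )
  printing_map(rep(list(m), n_layers),
               droplet_diameter_um = droplet_diameter_um, packing = packing)
}

#' Droplet center coordinates of a printing-map layer
#'
#' Physical (mm) centers of all non-empty droplets of one layer, with the
#' pattern centered in the field of view. Hexagonal packing offsets
#' odd rows by half a diameter and uses a row pitch of `d * sqrt(3) / 2`;
#' square packing uses pitch `d` on both axes. Neighboring equal-diameter
#' disks therefore touch at exact packing but never overlap beyond tangency.
#'
#' @param map A [printing_map()].
#' @param fov_x_mm,fov_y_mm Frame dimensions (mm).
#' @param layer Layer index (default 1, the bottom layer).
#' @return Data frame with columns `row`, `col`, `state`, `x_mm`, `y_mm`.
#' @export
droplet_centers <- function(map, fov_x_mm, fov_y_mm, layer = 1L) {
  stopifnot(inherits(map, "printing_map"))
  grid <- map$layers[[layer]]
  d <- map$droplet_diameter_um / 1000  # mm
  idx <- which(grid != MAP_STATES[["empty"]], arr.ind = TRUE)
  i <- idx[, "row"] - 1L
  j <- idx[, "col"] - 1L
  if (map$packing == "hexagonal") {
    x <- (j + 0.5 * (i %% 2)) * d
    y <- i * d * sqrt(3) / 2
  } else {
    x <- j * d
    y <- i * d
  }
  # center the occupied bounding box in the frame
  all_i <- (seq_len(nrow(grid)) - 1L)
  all_j <- (seq_len(ncol(grid)) - 1L)
  if (map$packing == "hexagonal") {
    xr <- range(c(outer(0.5 * (all_i %% 2), all_j, `+`)) * d)
    yr <- range(all_i * d * sqrt(3) / 2)
  } else {
    xr <- range(all_j * d)
    yr <- range(all_i * d)
  }
  x <- x + fov_x_mm / 2 - mean(xr)
  y <- y + fov_y_mm / 2 - mean(yr)
  data.frame(row = idx[, "row"], col = idx[, "col"],
             state = grid[idx], x_mm = x, y_mm = y)
}

# Rasterize a union of disks into a logical pixel mask by center sampling:
# a pixel belongs to a disk iff its *center* lies inside (squared distance
# <= r^2). Loops over per-disk bounding boxes only.
rasterize_disks <- function(centers_x, centers_y, radius_mm,
                            width_px, height_px, fov_x_mm, fov_y_mm) {
  sx <- fov_x_mm / width_px
  sy <- fov_y_mm / height_px
  mask <- matrix(FALSE, height_px, width_px)
  r2 <- radius_mm^2
  for (k in seq_along(centers_x)) {
    cx <- centers_x[k]; cy <- centers_y[k]
    cols <- max(1L, ceiling((cx - radius_mm) / sx)):
            min(width_px, ceiling((cx + radius_mm) / sx))
    rows <- max(1L, ceiling((cy - radius_mm) / sy)):
            min(height_px, ceiling((cy + radius_mm) / sy))
    if (length(cols) < 1L || length(rows) < 1L) next
    px <- (cols - 0.5) * sx
    py <- (rows - 0.5) * sy
    inside <- outer((py - cy)^2, (px - cx)^2, `+`) <= r2
    mask[rows, cols] <- mask[rows, cols] | inside
  }
  mask
}

#' Rasterize the release footprint of a printing map
#'
#' Renders the bottom-layer cargo droplets as disks of the printed diameter
#' at their packed centers and returns the union mask together with its
#' exact rasterized area. A pixel is inside a droplet iff its center lies
#' within the disk (center sampling), which makes the mask reproducible by
#' an exhaustive point-in-any-disk evaluation.
#'
#' @param map A [printing_map()].
#' @param width_px,height_px Raster dimensions (default 1920 x 1440).
#' @param fov_x_mm,fov_y_mm Frame dimensions (default 2.4887 x 1.8662 mm).
#' @param dilate_um Inflate every disk radius by this amount (um) before
#'   rasterizing; used to model an expression halo around the footprint.
#'   When nonzero, disks may extend beyond the frame and are clipped.
#' @param states Which cell states to render (default cargo only).
#' @param droplet_subset Optional integer vector selecting a subset of the
#'   rendered droplets (row indices into [droplet_centers()] of the cargo
#'   cells), e.g. the contact-failure droplets of the synthetic generator.
#' @param pattern_name Label stored in the result.
#' @return An object of class `footprint_truth`: list with `mask` (logical
#'   matrix), `area_mm2` (`pixel_area * popcount(mask)`) and `pattern_name`.
#' @export
render_footprint <- function(map, width_px = 1920, height_px = 1440,
                             fov_x_mm = 2.4887, fov_y_mm = 1.8662,
                             dilate_um = 0, states = "cargo",
                             droplet_subset = NULL, pattern_name = NULL) {
  stopifnot(inherits(map, "printing_map"))
  cen <- droplet_centers(map, fov_x_mm, fov_y_mm, layer = 1L)
  cen <- cen[cen$state %in% MAP_STATES[states], , drop = FALSE]
  if (!is.null(droplet_subset)) cen <- cen[droplet_subset, , drop = FALSE]
  r <- map$droplet_diameter_um / 2000  # radius in mm
  if (dilate_um == 0 && nrow(cen) > 0L) {
    out <- cen$x_mm - r < 0 | cen$x_mm + r > fov_x_mm |
           cen$y_mm - r < 0 | cen$y_mm + r > fov_y_mm
    if (any(out)) {
      stop(sprintf(
        "droplet(s) extend outside the frame: grid cells %s",
        paste(sprintf("(%d,%d)", cen$row[out], cen$col[out]), collapse = " ")
      ))
    }
  }
  mask <- rasterize_disks(cen$x_mm, cen$y_mm, r + dilate_um / 1000,
                          width_px, height_px, fov_x_mm, fov_y_mm)
  structure(
    list(mask = mask,
         area_mm2 = pixel_area(fov_x_mm, fov_y_mm, width_px, height_px) *
           sum(mask),
         pattern_name = pattern_name %||% "custom"),
    class = "footprint_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a printing map as JSON
#'
#' Layers are stored as arrays of integer state codes plus the diameter and
#' packing fields.
#'
#' @param map A [printing_map()].
#' @param path JSON file path.
#' @return `write_printing_map` returns `path` invisibly;
#'   `read_printing_map` returns a [printing_map()].
#' @export
write_printing_map <- function(map, path) {
  stopifnot(inherits(map, "printing_map"))
  jsonlite::write_json(
    list(droplet_diameter_um = map$droplet_diameter_um,
         packing = map$packing,
         layers = map$layers),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_printing_map
#' @export
read_printing_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- x$layers
  if (is.array(layers) && length(dim(layers)) == 3L) {
    layers <- lapply(seq_len(dim(layers)[1]), function(k) layers[k, , ])
  }
  printing_map(lapply(layers, as.matrix),
               droplet_diameter_um = x$droplet_diameter_um,
               packing = x$packing)
}
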