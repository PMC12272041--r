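# Printing maps, packing geometry and disk rasterization.

test_that("built-in patterns have the documented cargo structure", {
  full <- builtin_pattern("full")
  expect_equal(sum(full$layers[[1]] == MAP_STATES["cargo"]), 64)
  expect_length(full$layers, 8)

  sp <- builtin_pattern("single_path")
  cargo_per_col <- colSums(sp$layers[[1]] == MAP_STATES["cargo"])
  expect_true(all(cargo_per_col == 1))
  rows <- which(sp$layers[[1]] == MAP_STATES["cargo"], arr.ind = TRUE)[, "row"]
  expect_length(unique(rows), 1)  # a single linear chain

  fr <- builtin_pattern("frame")$layers[[1]]
  is_cargo <- fr == MAP_STATES["cargo"]
  expect_true(all(is_cargo[c(1, 8), ]) && all(is_cargo[, c(1, 8)]))
  expect_false(any(is_cargo[2:7, 2:7]))

  expect_error(builtin_pattern("hexagon"), "unknown pattern")
})

test_that("a single rasterized droplet approaches its analytic disk area", {
  one <- printing_map(list(matrix(MAP_STATES[["cargo"]], 1, 1)),
                      droplet_diameter_um = 100)
  analytic <- pi * 0.05^2  # mm^2
  # 10 px per diameter: 0.1 mm FOV over 10 px -> 10 um pixels
  lo <- render_footprint(one, width_px = 30, height_px = 30,
                         fov_x_mm = 0.3, fov_y_mm = 0.3)
  expect_lt(abs(lo$area_mm2 - analytic) / analytic, 0.02)
  # ~40 px per diameter (odd raster: disk center sits on a pixel center;
  # the lattice-count error fluctuates with alignment)
  hi <- render_footprint(one, width_px = 121, height_px = 121,
                         fov_x_mm = 0.3, fov_y_mm = 0.3)
  expect_lt(abs(hi$area_mm2 - analytic) / analytic, 0.005)
})

test_that("hex-packed rendering equals exhaustive point-in-any-disk", {
  map <- builtin_pattern("full", droplet_diameter_um = 100)
  w <- 128L; h <- 96L; fx <- 1.2; fy <- 0.9
  fp <- render_footprint(map, width_px = w, height_px = h,
                         fov_x_mm = fx, fov_y_mm = fy)
  cen <- droplet_centers(map, fx, fy)
  cen <- cen[cen$state == MAP_STATES["cargo"], ]
  oracle <- brute_disk_mask(cen$x_mm, cen$y_mm, 0.05, w, h, fx, fy)
  expect_identical(fp$mask, oracle)
  expect_identical(fp$area_mm2, pixel_area(fx, fy, w, h) * sum(oracle))
})

test_that("hex packing is tangent: no centers closer than one diameter", {
  for (pat in c("full", "cross", "frame")) {
    map <- builtin_pattern(pat, droplet_diameter_um = 80)
    cen <- droplet_centers(map, 2.4887, 1.8662)
    d2 <- as.matrix(dist(cbind(cen$x_mm, cen$y_mm)))
    diag(d2) <- Inf
    expect_gte(min(d2), 0.08 - 1e-12)
  }
})

test_that("cross footprint is one connected region with per-map occupancy", {
  map <- builtin_pattern("cross")
  fp <- render_footprint(map, width_px = 480, height_px = 360)
  expect_equal(dropnet:::label_components(fp$mask)$n, 1L)
  n_cargo <- sum(map$layers[[1]] == MAP_STATES["cargo"])
  expect_equal(n_cargo, 28)  # two full width-2 arms on an 8x8 grid
  # per-droplet occupancy: every cargo center pixel is inside the mask
  cen <- droplet_centers(map, 2.4887, 1.8662)
  cen <- cen[cen$state == MAP_STATES["cargo"], ]
  rows <- ceiling(cen$y_mm / (1.8662 / 360))
  cols <- ceiling(cen$x_mm / (2.4887 / 480))
  expect_true(all(fp$mask[cbind(rows, cols)]))
})

test_that("droplets that do not fit in the frame raise a geometry error", {
  map <- builtin_pattern("full", droplet_diameter_um = 400)
  expect_error(
    render_footprint(map, width_px = 100, height_px = 100,
                     fov_x_mm = 1.0, fov_y_mm = 1.0),
    "outside the frame.*\\(")
})

test_that("printing maps survive a JSON round trip", {
  map <- builtin_pattern("triangle", n_layers = 3, droplet_diameter_um = 72)
  path <- withr::local_tempfile(fileext = ".json")
  write_printing_map(map, path)
  back <- read_printing_map(path)
  expect_identical(back$layers, map$layers)
  expect_equal(back$droplet_diameter_um, 72)
  expect_identical(back$packing, "hexagonal")
})

test_that("map validation rejects ragged layers and bad states", {
  expect_error(printing_map(list(matrix(0L, 2, 2), matrix(0L, 3, 3))),
               "same grid dimensions")
  expect_error(printing_map(list(matrix(5L, 2, 2))), "empty")
})
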