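# Synthetic micrograph generator: exactness, determinism and the
# trends the analysis is meant to detect.

quick_params <- function(...) {
  synth_params(builtin_pattern("full"), width_px = 480, height_px = 360, ...)
}

test_that("noise-free, halo-free, hole-free pairs recover PF = 1 exactly", {
  p <- quick_params(halo_width_um = 0, hole_fraction = 0,
                    bg_sd = 0, act_sd = 0, cbd_sd = 0, seed = 1)
  sim <- simulate_image_pair(p)
  m <- compute_metrics(sim$expr, sim$cbd, thr = p$thr)
  expect_identical(m$PF, 1)
  expect_identical(m$A_U, 0)
  expect_identical(m$A_N, 0)
  expect_identical(sim$truth$PF_true, 1)
  expect_identical(m$A_I, sim$truth$A_I_true)
})

test_that("same parameters and seed reproduce identical images", {
  p <- quick_params(halo_width_um = 60, hole_fraction = 0.25, seed = 99)
  a <- simulate_image_pair(p)
  b <- simulate_image_pair(p)
  expect_identical(a$expr$pixels, b$expr$pixels)
  expect_identical(a$cbd$pixels, b$cbd$pixels)
  expect_identical(a$truth$hole_droplets, b$truth$hole_droplets)
})

test_that("a 50-um halo pair is recovered within 0.02 of geometric truth", {
  p <- synth_params(builtin_pattern("full"), width_px = 960, height_px = 720,
                    halo_width_um = 50, seed = 5)
  sim <- simulate_image_pair(p)
  m <- compute_metrics(sim$expr, sim$cbd, thr = p$thr)
  expect_lt(abs(m$PF - sim$truth$PF_true), 0.02)
})

test_that("noise stays on the correct side of every threshold", {
  p <- quick_params(halo_width_um = 40, hole_fraction = 0.2, seed = 12)
  sim <- simulate_image_pair(p)
  act <- sim$truth$activated_mask_true
  fp <- sim$truth$footprint$mask
  expect_true(all(sim$expr$pixels[act] >= p$thr$I_B))
  expect_true(all(sim$expr$pixels[!act] < p$thr$I_B))
  expect_true(all(sim$cbd$pixels[fp] >= p$thr$I_CBD))
  expect_true(all(sim$cbd$pixels[!fp] < p$thr$I_CBD))
})

test_that("halo width widens unintended area and degrades true fidelity", {
  halos <- c(0, 25, 50, 100)
  sims <- lapply(halos, function(h)
    simulate_image_pair(quick_params(halo_width_um = h, seed = 4)))
  a_u <- vapply(sims, function(s) s$truth$A_U_true, numeric(1))
  pf <- vapply(sims, function(s) s$truth$PF_true, numeric(1))
  expect_true(all(diff(a_u) >= 0))
  expect_true(all(diff(pf) <= 0))
})

test_that("contact failures are nested and inflate the dead footprint area", {
  fracs <- c(0, 0.2, 0.4, 0.8)
  sims <- lapply(fracs, function(f)
    simulate_image_pair(quick_params(hole_fraction = f, seed = 21)))
  a_n <- vapply(sims, function(s) s$truth$A_N_true, numeric(1))
  expect_true(all(diff(a_n) >= 0))
  holes <- lapply(sims, function(s) s$truth$hole_droplets)
  for (k in 2:4) expect_true(all(holes[[k - 1]] %in% holes[[k]]))
})

test_that("degenerate empty footprints warn instead of failing silently", {
  empty_map <- printing_map(list(matrix(MAP_STATES[["inert"]], 2, 2)))
  p <- synth_params(empty_map, width_px = 64, height_px = 48)
  expect_warning(sim <- simulate_image_pair(p), "degenerate")
  expect_true(is.nan(sim$truth$PF_true))
})

test_that("induction time course is switch-like between onset and plateau", {
  tc <- simulate_timecourse(onset_h = 10, plateau_h = 18, amplitude = 1e8,
                            baseline = 0, condition = "full", seed = 2)
  frac <- tc$I_T / 1e8
  expect_lt(frac[tc$time_h == 9], 0.10)
  expect_gte(frac[tc$time_h == 18], 0.95)
  # flat before onset and after plateau
  expect_true(all(abs(frac[tc$time_h <= 8]) < 0.05))
  expect_true(all(frac[tc$time_h >= 20] > 0.95))
})

test_that("control conditions stay at baseline", {
  for (cond in c("no_pore", "no_signal")) {
    tc <- simulate_timecourse(amplitude = 1e8, baseline = 5e5,
                              condition = cond, seed = 3)
    expect_true(all(abs(tc$I_T - 5e5) < 5e6))  # within noise of baseline
  }
  # zero amplitude is indistinguishable from the no-inducer control
  a <- simulate_timecourse(amplitude = 0, condition = "full",
                           noise_sd = 1e5, seed = 8)
  b <- simulate_timecourse(amplitude = 0, condition = "no_signal",
                           noise_sd = 1e5, seed = 8)
  expect_identical(a, b)
  expect_error(simulate_timecourse(times_h = c(-1, 0)), "non-negative")
  expect_error(simulate_timecourse(onset_h = 18, plateau_h = 10), "precede")
})

test_that("colony fields honour their ground-truth counts", {
  blank <- simulate_colony_field(0, seed = 1)
  expect_equal(blank$n_true, 0L)
  expect_false(any(blank$mask_true))
  expect_true(all(blank$image$pixels < 500))

  f <- simulate_colony_field(25, seed = 7)
  expect_equal(count_colonies(f$image, threshold = 500)$n_colonies, 25L)

  expect_error(
    simulate_colony_field(500, radius_um = 100, fov_x_mm = 1, fov_y_mm = 1,
                          width_px = 100, height_px = 100, seed = 1),
    "cannot pack"
  )
})

test_that("parameter validation rejects inconsistent intensity settings", {
  expect_error(quick_params(bg_mean = 200), "below the activation")
  expect_error(quick_params(act_mean = 100), "at or above")
  expect_error(quick_params(hole_fraction = 1.5), "\\[0, 1\\]")
  expect_error(quick_params(cbd_out = 600), "I_CBD")
})
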