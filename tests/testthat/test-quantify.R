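# Masks, baseline, area decomposition, PF, intensity statistics and R_VSA.

fov <- c(x = 0.3, y = 0.225)

expr_img <- function(px) fluor_image(px, "expression_mCherry", fov["x"], fov["y"])
cbd_img <- function(px) fluor_image(px, "footprint_CBD", fov["x"], fov["y"])

test_that("activation threshold is inclusive (Heaviside H(0) = 1)", {
  img <- expr_img(matrix(c(178, 179, 180, 0), 2, 2))
  m <- activation_mask(img, 179)
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(activation_mask(expr_img(matrix(0, 3, 3)), 179)))
  expect_error(activation_mask(img, 0), "\\(0, 4095\\]")
  expect_error(activation_mask(img, 5000), "\\(0, 4095\\]")
})

test_that("footprint mask thresholds the CBD channel and checks the tag", {
  expect_true(all(footprint_mask(cbd_img(matrix(4095, 3, 3)), 500)))
  expect_false(any(footprint_mask(cbd_img(matrix(499, 3, 3)), 500)))
  checker <- matrix(rep(c(400, 600), 18)[1:36], 6, 6)
  expect_identical(footprint_mask(cbd_img(checker), 500), checker == 600)
  expect_error(footprint_mask(expr_img(matrix(0, 2, 2)), 500), "channel")
})

test_that("baseline is the grand pixel mean, with calibrated defaults", {
  expect_equal(compute_baseline(list(expr_img(matrix(42, 5, 5)))), 42)
  a <- expr_img(matrix(c(100, 300, 200, 400), 2, 2))
  b <- expr_img(matrix(0, 2, 2))
  expect_equal(compute_baseline(list(a, b)), 125)
  expect_equal(compute_baseline(mode = "mcherry"), 179)
  expect_equal(compute_baseline(mode = "sfgfp"), 200)
  expect_error(compute_baseline(), "no control images")
  expect_error(compute_baseline(list(a, cbd_img(matrix(0, 2, 2)))),
               "share one channel")
})

test_that("metrics on aligned expression give PF = 1 and empty stray areas", {
  fp <- matrix(0, 12, 16); fp[4:9, 5:12] <- 4000
  ex <- matrix(100, 12, 16); ex[4:9, 5:12] <- 800
  m <- compute_metrics(expr_img(ex), cbd_img(fp))
  expect_equal(m$PF, 1)
  expect_equal(m$A_U, 0)
  expect_equal(m$A_N, 0)
  expect_equal(m$A_I, m$A_pix * sum(fp >= 500))
  expect_equal(m$I_M, 800)
})

test_that("no activated pixels gives PF = 1, A_N = A_I and zero intensities", {
  fp <- matrix(0, 8, 8); fp[3:6, 3:6] <- 2000
  expect_warning(compute_metrics(expr_img(matrix(50, 8, 8)), cbd_img(fp)),
                 "no activated pixels")
  m <- suppressWarnings(compute_metrics(expr_img(matrix(50, 8, 8)),
                                        cbd_img(fp)))
  expect_equal(m$PF, 1)
  expect_equal(m$A_N, m$A_I)
  expect_equal(m$I_T, 0)
  expect_equal(m$N_a, 0L)
  expect_equal(m$I_M, 0)
})

test_that("a toy pair straddling both thresholds matches the exhaustive count", {
  set.seed(7)
  ex <- matrix(sample(c(0, 100, 178, 179, 200, 634, 4095), 48, TRUE), 6, 8)
  cb <- matrix(sample(c(0, 499, 500, 501, 2000, 4095), 48, TRUE), 6, 8)
  m <- compute_metrics(expr_img(ex), cbd_img(cb))
  o <- naive_metrics(ex, cb, 179, 500, m$A_pix)
  expect_equal(unclass(m)[names(o)], o)
})

test_that("empty footprint reports PF as NaN with a warning, not an error", {
  expect_warning(
    compute_metrics(expr_img(matrix(300, 4, 4)), cbd_img(matrix(0, 4, 4))),
    "undefined"
  )
  m <- suppressWarnings(
    compute_metrics(expr_img(matrix(300, 4, 4)), cbd_img(matrix(0, 4, 4)))
  )
  expect_true(is.nan(m$PF))
})

test_that("PF may go negative when unintended area dominates; never clamped", {
  fp <- matrix(0, 10, 10); fp[5, 5] <- 1000   # one footprint pixel
  ex <- matrix(500, 10, 10)                   # activation everywhere
  m <- compute_metrics(expr_img(ex), cbd_img(fp))
  expect_lt(m$PF, 0)
  expect_equal(m$PF, (m$A_I - m$A_U) / m$A_I)
})

test_that("dimension mismatch is a shape error", {
  expect_error(
    compute_metrics(expr_img(matrix(0, 4, 4)), cbd_img(matrix(0, 4, 5))),
    "dimensions differ"
  )
})

test_that("area partition and intensity identities hold on random images", {
  set.seed(11)
  for (rep in 1:20) {
    pair <- random_image_pair()
    m <- compute_metrics(pair$expr, pair$cbd)
    act <- activation_mask(pair$expr, 179)
    fp <- footprint_mask(pair$cbd, 500)
    expect_identical(sum(fp), sum(!act & fp) + sum(act & fp))
    expect_equal(m$A_I, m$A_N + m$A_pix * sum(act & fp), tolerance = 1e-12)
    expect_equal(m$I_T, m$I_M * m$N_a, tolerance = 1e-12)
    expect_lte(m$PF, 1)
  }
})

test_that("total intensity is monotone non-decreasing as I_B decreases", {
  set.seed(3)
  pair <- random_image_pair()
  its <- vapply(c(2000, 1000, 500, 179, 50), function(ib) {
    compute_metrics(pair$expr, pair$cbd, thresholds(I_B = ib))$I_T
  }, numeric(1))
  expect_true(all(diff(its) >= 0))
})

test_that("volume-to-surface ratio follows the equivalent-sphere chain", {
  # independent closed form: R = N * (4/3) * c^{3/2} / (sqrt(pi) * A_I),
  # c the per-droplet cross-section, versus the stepwise diameter chain
  A_I <- 0.36
  cross <- A_I / 64
  oracle <- 512 * (4 / 3) * cross^1.5 / (sqrt(pi) * A_I)
  expect_equal(compute_rvsa(A_I, rvsa_spec(8, 64)), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 2), 0.45)
  # doubling the layer count at fixed footprint exactly doubles the ratio
  expect_equal(compute_rvsa(A_I, rvsa_spec(16, 64)),
               2 * compute_rvsa(A_I, rvsa_spec(8, 64)))
  expect_error(compute_rvsa(0, rvsa_spec(8, 64)), "positive")
  expect_error(rvsa_spec(8, 0), "counts")
})

test_that("printed droplet volume corresponds to the printed diameter", {
  d <- droplet_diameter_from_volume(150)  # ~150 pL droplets
  expect_equal(round(d / 5) * 5, 65)      # 5-um printing grain
  expect_error(droplet_diameter_from_volume(0), "positive")
})
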