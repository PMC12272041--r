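# Independent brute-force oracles. These deliberately share no code with the
# package: explicit per-pixel loops and textbook formulas only.

# Exhaustive per-pixel area decomposition and intensity statistics with the
# Heaviside convention H(z) = 1 iff z >= 0.
naive_metrics <- function(expr_px, cbd_px, I_B, I_CBD, A_pix) {
  N_a <- 0L; I_T <- 0; n_fp <- 0L; n_AU <- 0L; n_AN <- 0L
  for (y in seq_len(nrow(expr_px))) {
    for (x in seq_len(ncol(expr_px))) {
      act <- expr_px[y, x] >= I_B
      fp <- cbd_px[y, x] >= I_CBD
      if (act) { N_a <- N_a + 1L; I_T <- I_T + as.numeric(expr_px[y, x]) }
      if (fp) n_fp <- n_fp + 1L
      if (act && !fp) n_AU <- n_AU + 1L
      if (!act && fp) n_AN <- n_AN + 1L
    }
  }
  A_I <- A_pix * n_fp; A_U <- A_pix * n_AU; A_N <- A_pix * n_AN
  list(A_I = A_I, A_U = A_U, A_N = A_N,
       PF = if (A_I > 0) (A_I - A_U) / A_I else NaN,
       I_M = if (N_a > 0) I_T / N_a else 0,
       I_T = I_T, N_a = N_a, A_pix = A_pix)
}

# Queue-based flood fill counting connected components of at least
# min_area_px pixels (8-connectivity).
flood_fill_count <- function(mask, min_area_px = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      size <- 0L
      while (length(queue) > 0L) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        size <- size + 1L
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
              mask[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
      if (size >= min_area_px) count <- count + 1L
    }
  }
  count
}

# Point-in-any-disk rasterization evaluated at every pixel center.
brute_disk_mask <- function(cx, cy, r, width_px, height_px,
                            fov_x_mm, fov_y_mm) {
  sx <- fov_x_mm / width_px
  sy <- fov_y_mm / height_px
  mask <- matrix(FALSE, height_px, width_px)
  for (row in seq_len(height_px)) {
    py <- (row - 0.5) * sy
    for (col in seq_len(width_px)) {
      px <- (col - 0.5) * sx
      mask[row, col] <- any((px - cx)^2 + (py - cy)^2 <= r^2)
    }
  }
  mask
}

# Random 12-bit image pair straddling both thresholds.
random_image_pair <- function(width = 64, height = 48,
                              fov_x = 0.3, fov_y = 0.225) {
  expr <- matrix(sample(0:4095, width * height, replace = TRUE),
                 height, width)
  cbd <- matrix(sample(0:4095, width * height, replace = TRUE),
                height, width)
  list(
    expr = fluor_image(expr, "expression_mCherry", fov_x, fov_y),
    cbd = fluor_image(cbd, "footprint_CBD", fov_x, fov_y)
  )
}
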