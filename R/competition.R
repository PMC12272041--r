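# Micro-colony density quantification and normality-gated two-group
# statistics for competition outcomes.

# 8-connected (or 4-connected) component labelling of a binary mask via a
# pixel-adjacency graph. Counting micro-colonies is a standard
# connected-component problem; the graph machinery is igraph's.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask),
            connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  n_fg <- length(fg)
  labels <- matrix(0L, nr, nc)
  if (n_fg == 0L) return(list(labels = labels, n = 0L))
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_len(n_fg)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    both <- mask[r1, c1, drop = FALSE] &
      mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(both)) next
    a <- id[r1, c1, drop = FALSE][both]
    b <- id[r1 + dr, c1 + dc, drop = FALSE][both]
    edges <- c(edges, rbind(a, b))
  }
  g <- igraph::make_graph(edges = edges, n = n_fg, directed = FALSE)
  comp <- igraph::components(g)
  labels[fg] <- comp$membership
  list(labels = labels, n = as.integer(comp$no))
}

#' Count micro-colonies in a fluorescence field
#'
#' Binarizes the image at `>= threshold`, labels 8-connected components,
#' discards components smaller than `min_area_px`, and reports the surviving
#' count and its density per mm^2 of the analysed region. The segmentation
#' defaults (8-connectivity, no minimum area) are deliberately simple and
#' exposed as arguments; colony counting in crowded fields should be checked
#' against the labelled mask.
#'
#' @param img A [fluor_image()].
#' @param threshold Binarization threshold (a.u.) in `(0, 4095]`.
#' @param min_area_px Discard components with fewer pixels than this
#'   (default 1 = keep all).
#' @param roi Optional region of interest `c(x0, y0, x1, y1)` in 1-based
#'   pixel coordinates (inclusive); default is the full frame.
#' @return An object of class `colony_count`: list with `n_colonies`,
#'   `area_mm2`, `density_per_mm2`, `threshold`, `min_area_px`, `labels`
#'   (labelled component matrix of the analysed region).
#' @examples
#' field <- simulate_colony_field(25, seed = 7)
#' count_colonies(field$image, threshold = 500)$n_colonies
#' @export
count_colonies <- function(img, threshold, min_area_px = 1L, roi = NULL) {
  stopifnot(inherits(img, "fluor_image"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > MAX_INTENSITY) {
    stop("threshold must lie in (0, 4095]")
  }
  px <- img$pixels
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L)
    if (roi[1] > roi[3] || roi[2] > roi[4] ||
        roi[3] < 1L || roi[1] > width_px(img) ||
        roi[4] < 1L || roi[2] > height_px(img)) {
      stop("empty region of interest")
    }
    cols <- seq.int(max(1L, roi[1]), min(width_px(img), roi[3]))
    rows <- seq.int(max(1L, roi[2]), min(height_px(img), roi[4]))
    px <- px[rows, cols, drop = FALSE]
  }
  lab <- label_components(px >= threshold, connectivity = 8L)
  n <- lab$n
  if (min_area_px > 1L && n > 0L) {
    sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = n)
    keep <- which(sizes >= min_area_px)
    lab$labels[!(lab$labels %in% keep)] <- 0L
    n <- length(keep)
  }
  area <- length(px) * img_pixel_area(img)
  structure(
    list(n_colonies = as.integer(n), area_mm2 = area,
         density_per_mm2 = n / area, threshold = threshold,
         min_area_px = as.integer(min_area_px), labels = lab$labels),
    class = "colony_count"
  )
}

#' @export
print.colony_count <- function(x, ...) {
  cat(sprintf(
    "<colony_count> %d colonies in %.3f mm^2 (%.1f per mm^2; threshold %g, min area %d px)\n",
    x$n_colonies, x$area_mm2, x$density_per_mm2, x$threshold, x$min_area_px
  ))
  invisible(x)
}

#' Significance stars
#'
#' Four-tier convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, otherwise `ns`.
#'
#' @param p A p-value in `[0, 1]`.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Normality-gated two-group comparison
#'
#' Tests each group for normality with the Shapiro-Wilk test at
#' `alpha_normality`. If both groups pass, the groups are compared with a
#' two-sided two-sample t-test (classical equal-variance by default);
#' if at least one group fails, with a two-sided Wilcoxon rank-sum test.
#' A zero-variance group cannot be assessed by Shapiro-Wilk and is treated
#' as failing the gate (`normality_p = NA`). No multiple-testing correction
#' is applied; comparisons are reported per pair.
#'
#' @param a,b Numeric samples with at least 3 values each (the Shapiro-Wilk
#'   minimum).
#' @param alpha_normality Gate level for the normality test (default 0.05).
#' @param var_equal Use the classical pooled-variance t-test (default
#'   `TRUE`); set `FALSE` for Welch.
#' @return An object of class `group_test`: list with `test_used`
#'   (`"t_test"` or `"wilcoxon_rank_sum"`), `normality_p` (length-2),
#'   `p_value`, `stars`.
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(4), rnorm(4, mean = 10))
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, var_equal = TRUE) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 values for the Shapiro-Wilk gate")
  }
  sw_p <- vapply(list(a = a, b = b), function(x) {
    tryCatch(stats::shapiro.test(x)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  normal <- !is.na(sw_p) & sw_p > alpha_normality
  if (all(normal)) {
    test_used <- "t_test"
    p <- stats::t.test(a, b, var.equal = var_equal)$p.value
  } else {
    test_used <- "wilcoxon_rank_sum"
    p <- stats::wilcox.test(a, b)$p.value
  }
  structure(
    list(test_used = test_used, normality_p = sw_p, p_value = p,
         stars = significance_stars(p)),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "<group_test> %s: p = %.4g (%s); Shapiro-Wilk p = %.3g / %.3g\n",
    x$test_used, x$p_value, x$stars, x$normality_p[1], x$normality_p[2]
  ))
  invisible(x)
}
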