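#' ROI polygon in pixel coordinates
#'
#' A pathologist-drawn region of interest. Vertices live in continuous
#' pixel coordinates with the origin at the top-left corner of the image:
#' pixel `(r, c)` (1-based indices) covers `x` in `[c-1, c]` and `y` in
#' `[r-1, r]`, so its centre is `(c - 0.5, r - 0.5)`. The ring is
#' implicitly closed.
#'
#' @param vertices numeric n x 2 matrix, columns `x` (along image
#'   columns) and `y` (along image rows), n >= 3.
#' @param id character ROI identifier.
#' @return An object of class `roi_polygon`.
#' @examples
#' roi_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), id = "roi-1")
#' @export
roi_polygon <- function(vertices, id = "roi") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("an ROI polygon needs at least 3 (x, y) vertices")
  if (any(!is.finite(vertices))) stop("polygon vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ]) && n > 3L)
    vertices <- vertices[-n, , drop = FALSE]
  if (abs(shoelace_area(vertices)) < .Machine$double.eps)
    stop("polygon has zero area")
  if (!is_simple_polygon(vertices))
    stop("polygon is self-intersecting")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, id = as.character(id)),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> '%s', %d vertices, area %.1f px^2\n",
              x$id, nrow(x$vertices), abs(shoelace_area(x$vertices))))
  invisible(x)
}

# signed shoelace area in squared pixel units
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) proper-crossing test between non-adjacent edges
is_simple_polygon <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE]) # x1 y1 x2 y2
  crosses <- function(a, b) {
    d1 <- sign((b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1]))
    d2 <- sign((b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1]))
    d3 <- sign((a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1]))
    d4 <- sign((a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1]))
    d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through the closing edge
      if (crosses(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

# even-odd point-in-polygon, vectorised over points; points exactly on an
# edge count as inside
points_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  xi <- v[, 1]; yi <- v[, 2]
  xj <- v[c(2:n, 1), 1]; yj <- v[c(2:n, 1), 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- xi[k]; y1 <- yi[k]; x2 <- xj[k]; y2 <- yj[k]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
              py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | (abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) & within)
    crosses_ray <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses_ray)
  }
  inside | on_edge
}

#' Rasterise an ROI polygon onto the image grid
#'
#' A pixel belongs to the ROI iff its centre lies inside the polygon by
#' the even-odd rule; centres exactly on an edge count as inside.
#'
#' @param poly a [roi_polygon()].
#' @param shape integer vector `c(H, W)` of the target raster.
#' @return Logical H x W mask. Warns if the polygon covers no pixel
#'   centre.
#' @export
rasterize_roi <- function(poly, shape) {
  if (!inherits(poly, "roi_polygon")) stop("`poly` must be an roi_polygon")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  v <- poly$vertices
  rows <- seq_len(H); cols <- seq_len(W)
  py <- rep(rows - 0.5, times = W)
  px <- rep(cols - 0.5, each = H)
  mask <- matrix(points_in_polygon(px, py, v), H, W)
  if (!any(mask))
    warning(sprintf("ROI '%s' covers no pixel centre of a %d x %d raster",
                    poly$id, H, W))
  mask
}

#' Physical area of an ROI polygon
#'
#' Shoelace area converted to square millimetres through the image
#' resolution. Areas far outside the range typically drawn for Ki-67
#' scoring fields (about 0.02-3.15 mm^2) trigger a sanity warning but are
#' still returned.
#'
#' @param poly a [roi_polygon()].
#' @param mpp microns per pixel.
#' @return Area in mm^2.
#' @examples
#' sq <- roi_polygon(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
#' roi_area_mm2(sq, mpp = 0.5) # 0.25
#' @export
roi_area_mm2 <- function(poly, mpp) {
  if (!inherits(poly, "roi_polygon")) stop("`poly` must be an roi_polygon")
  if (mpp <= 0) stop("`mpp` must be positive")
  a <- abs(shoelace_area(poly$vertices)) * mpp^2 * 1e-6
  if (a < 0.0203 || a > 3.1473)
    warning(sprintf("ROI '%s' area %.4f mm^2 is outside the usual 0.0203-3.1473 mm^2 scoring range",
                    poly$id, a))
  a
}

#' Score the Ki-67 proliferation index of one ROI
#'
#' A nucleus belongs to the ROI iff the pixel covering its centroid is
#' inside the ROI mask (centroid rule: each nucleus is counted by at most
#' one of several adjacent ROIs). The PI is the percentage of positive
#' nuclei among the belonging nuclei. An ROI containing no nucleus is
#' flagged and its PI left undefined (`NA`), since 0% is a meaningful
#' score in its own right.
#'
#' @param records nucleus table from [classify_nuclei()].
#' @param roi_mask logical mask from [rasterize_roi()], or `NULL` to
#'   score the whole raster.
#' @param roi_id identifier copied into the result.
#' @param area_mm2 optional physical ROI area to carry along.
#' @return An object of class `roi_score`: list with `roi_id`, `n_pos`,
#'   `n_neg`, `n_total`, `pi_percent`, `neg_percent` (full precision;
#'   printed at 0.1 resolution), `area_mm2` and `no_cells`.
#' @export
score_roi <- function(records, roi_mask = NULL, roi_id = "roi",
                      area_mm2 = NA_real_) {
  if (is.null(roi_mask)) {
    inside <- rep(TRUE, nrow(records))
  } else {
    H <- nrow(roi_mask); W <- ncol(roi_mask)
    # pixel covering the continuous centroid point
    pr <- pmin(pmax(floor(records$centroid_row - 0.5) + 1L, 1L), H)
    pc <- pmin(pmax(floor(records$centroid_col - 0.5) + 1L, 1L), W)
    inside <- roi_mask[cbind(pr, pc)]
    if (nrow(records) == 0) inside <- logical(0)
  }
  n_pos <- sum(records$call[inside] == "positive")
  n_tot <- sum(inside)
  structure(list(
    roi_id = as.character(roi_id),
    n_pos = n_pos,
    n_neg = n_tot - n_pos,
    n_total = n_tot,
    pi_percent = if (n_tot > 0) 100 * n_pos / n_tot else NA_real_,
    neg_percent = if (n_tot > 0) 100 * (n_tot - n_pos) / n_tot else NA_real_,
    area_mm2 = area_mm2,
    no_cells = n_tot == 0
  ), class = "roi_score")
}

#' @export
print.roi_score <- function(x, ...) {
  if (x$no_cells) {
    cat(sprintf("<roi_score> '%s': no cells in ROI (PI undefined)\n", x$roi_id))
  } else {
    cat(sprintf("<roi_score> '%s': PI %.1f%% (%d positive / %d nuclei, %.1f%% negative)\n",
                x$roi_id, x$pi_percent, x$n_pos, x$n_total, x$neg_percent))
  }
  invisible(x)
}

#' Draw the scoring overlay on an ROI image
#'
#' Returns a copy of the input with 1-pixel nucleus boundary contours
#' drawn in pure red for positive and pure blue for negative nuclei, and
#' the ROI outline in black -- the standard review rendering for
#' AI-assisted Ki-67 reads.
#'
#' @param image an [rgb_image()].
#' @param labels integer label matrix matching the image raster.
#' @param records nucleus table from [classify_nuclei()] giving each
#'   label's call.
#' @param roi_mask optional logical ROI mask whose outline is drawn
#'   black.
#' @return A new `rgb_image`; the input is not modified.
#' @export
render_overlay <- function(image, labels, records, roi_mask = NULL) {
  if (!inherits(image, "rgb_image")) stop("`image` must be an rgb_image")
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  if (any(dim(labels) != c(H, W))) stop("`labels` does not match the image")
  boundary <- boundary_mask(labels)
  if (any(boundary)) {
    call_of <- setNames(records$call, records$label_id)
    ids <- labels[boundary]
    is_pos <- call_of[as.character(ids)] == "positive"
    idx <- which(boundary)
    red <- idx[is_pos]; blue <- idx[!is_pos]
    plane <- H * W
    px[red] <- 255L; px[red + plane] <- 0L; px[red + 2L * plane] <- 0L
    px[blue] <- 0L; px[blue + plane] <- 0L; px[blue + 2L * plane] <- 255L
  }
  if (!is.null(roi_mask)) {
    ob <- boundary_mask(matrix(as.integer(roi_mask), H, W))
    idx <- which(ob)
    plane <- H * W
    px[idx] <- 0L; px[idx + plane] <- 0L; px[idx + 2L * plane] <- 0L
  }
  rgb_image(px, image$mpp)
}

# pixels of a labelled object adjacent (4-neighbourhood, zero padding) to
# a different label or to background
boundary_mask <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- labels
  core_r <- 2:(H + 1L); core_c <- 2:(W + 1L)
  diff_any <- matrix(FALSE, H, W)
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    diff_any <- diff_any | (pad[core_r + o[1], core_c + o[2]] != labels)
  labels > 0 & diff_any
}
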