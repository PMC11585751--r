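#' Threshold the haematoxylin channel into a nuclear foreground mask
#'
#' Pixels strictly greater than the threshold become foreground. With
#' `method = "otsu"` the threshold is computed by Otsu's method on a
#' 256-bin histogram of the channel (via [EBImage::otsu()] over the
#' channel's own value range); with `method = "fixed"` the supplied
#' optical-density cut-off is used as-is.
#'
#' @param h_channel H x W nonnegative numeric matrix (haematoxylin OD).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold OD cut-off, required when `method = "fixed"`.
#' @return Logical H x W matrix with attribute `threshold` recording the
#'   cut-off used.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2)
#' threshold_foreground(m, method = "fixed", fixed_threshold = 0.5)
#' @export
threshold_foreground <- function(h_channel, method = c("otsu", "fixed"),
                                 fixed_threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(h_channel) || !is.numeric(h_channel))
    stop("`h_channel` must be a numeric matrix")
  if (min(h_channel) < 0) stop("`h_channel` must be nonnegative")
  if (method == "fixed") {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold))
      stop("`fixed_threshold` is required when method = \"fixed\"")
    thr <- as.numeric(fixed_threshold)
  } else {
    rng <- range(h_channel)
    if (diff(rng) == 0) {
      # constant channel: no separable classes, everything is background
      thr <- rng[2]
    } else {
      thr <- as.numeric(EBImage::otsu(EBImage::Image(h_channel),
                                      range = rng, levels = 256))
    }
  }
  mask <- h_channel > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Normalised Euclidean distance transform of a nuclear mask
#'
#' For every foreground pixel, the Euclidean distance (pixel units,
#' centre to centre) to the nearest background pixel of the image is
#' computed, then the whole map is divided by its maximum so the tallest
#' peak equals 1. Background pixels are 0. A mask with no background
#' pixel has no finite distances and is returned as all ones by
#' convention; an empty mask is all zeros.
#'
#' @param mask logical H x W matrix (nuclear foreground).
#' @return Numeric H x W matrix in \[0, 1\] with attribute `raw_max`, the
#'   un-normalised maximum distance in pixels (0 for an empty mask).
#' @examples
#' m <- matrix(FALSE, 1, 5); m[1, 2:4] <- TRUE
#' compute_distance_map(m) # 0, 0.5, 1, 0.5, 0
#' @export
compute_distance_map <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mode(mask) <- "logical"
  if (!any(mask)) {
    out <- matrix(0, nrow(mask), ncol(mask))
    attr(out, "raw_max") <- 0
    return(out)
  }
  if (all(mask)) {
    out <- matrix(1, nrow(mask), ncol(mask))
    attr(out, "raw_max") <- Inf
    return(out)
  }
  raw <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)),
                          metric = "euclidean")
  raw <- matrix(as.numeric(raw), nrow(mask))
  mx <- max(raw)
  out <- raw / mx
  attr(out, "raw_max") <- mx
  out
}

#' Detect watershed seeds as peaks of the distance map
#'
#' Seeds are local maxima of the normalised distance map: a pixel whose
#' value is at least that of each of its neighbours and at least
#' `min_height`. A plateau of equal-valued maxima yields exactly one
#' seed, its topmost-then-leftmost pixel. Candidates are then accepted
#' greedily in decreasing height (ties: topmost, then leftmost) subject
#' to a pairwise Euclidean separation of at least `min_distance` pixels.
#'
#' @param dmap matrix from [compute_distance_map()] (values in \[0, 1\]).
#' @param min_distance minimum seed separation in pixels (>= 1).
#' @param min_height minimum normalised peak height in \[0, 1\].
#' @param connectivity pixel neighbourhood, 8 (default) or 4.
#' @return Integer n x 2 matrix of seed coordinates, columns `row`,
#'   `col` (1-based).
#' @export
detect_seeds <- function(dmap, min_distance = 7, min_height = 0.2,
                         connectivity = 8) {
  if (!is.matrix(dmap)) stop("`dmap` must be a matrix")
  if (min_distance < 1) stop("`min_distance` must be >= 1 pixel")
  if (min_height < 0 || min_height > 1) stop("`min_height` must be in [0, 1]")
  H <- nrow(dmap); W <- ncol(dmap)
  # pad with -Inf so border pixels compare only against real neighbours
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- dmap
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else if (connectivity == 4) {
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  } else stop("`connectivity` must be 4 or 8")
  is_max <- matrix(TRUE, H, W)
  core_r <- 2:(H + 1L); core_c <- 2:(W + 1L)
  for (o in offs)
    is_max <- is_max & (dmap >= pad[core_r + o[1], core_c + o[2]])
  is_max <- is_max & dmap >= min_height & dmap > 0
  if (!any(is_max))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  # one representative per equal-valued plateau (adjacent maxima always
  # share a value, so plain connected components suffice)
  comp <- .cc_label(is_max, as.integer(connectivity))
  idx <- which(is_max, arr.ind = TRUE)
  lab <- comp[is_max]
  ord <- order(lab, idx[, 1], idx[, 2])
  first <- ord[!duplicated(lab[ord])]
  cand <- idx[first, , drop = FALSE]
  val <- dmap[cand]
  # greedy non-maximum suppression, highest peak first
  ord <- order(-val, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  acc_r <- numeric(0); acc_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc_r) == 0 ||
        all((acc_r - cand[i, 1])^2 + (acc_c - cand[i, 2])^2 >=
            min_distance^2)) {
      keep[i] <- TRUE
      acc_r <- c(acc_r, cand[i, 1]); acc_c <- c(acc_c, cand[i, 2])
    }
  }
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  storage.mode(out) <- "integer"
  out
}

#' Marker-controlled watershed segmentation
#'
#' Floods the negated distance map from the seed markers, restricted to
#' the foreground mask: pixels are claimed in order of decreasing
#' distance-map height, so touching nuclei split along the valley between
#' their peaks. Every foreground pixel reachable from a seed receives
#' exactly one label; foreground components containing no seed remain 0.
#' Equal-height contested pixels are resolved deterministically in favour
#' of the earlier front (lower seed index for symmetric inputs).
#'
#' @param dmap matrix from [compute_distance_map()].
#' @param seeds integer n x 2 matrix of (row, col) seed coordinates, as
#'   returned by [detect_seeds()]. Seed i becomes label i.
#' @param mask logical foreground matrix the flood is restricted to.
#' @param connectivity 8 (default) or 4.
#' @return Integer H x W label matrix; 0 is background.
#' @export
watershed_segment <- function(dmap, seeds, mask, connectivity = 8) {
  if (!is.matrix(dmap) || !is.matrix(mask) || any(dim(dmap) != dim(mask)))
    stop("`dmap` and `mask` must be matrices of identical shape")
  mode(mask) <- "logical"
  if (is.null(seeds) || nrow(seeds) == 0) {
    warning("no seeds supplied; returning an empty label map")
    return(matrix(0L, nrow(dmap), ncol(dmap)))
  }
  markers <- matrix(0L, nrow(dmap), ncol(dmap))
  markers[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
  .watershed_flood(dmap, markers, mask, as.integer(connectivity))
}

#' Remove implausibly small or large nuclei from a label map
#'
#' Drops instances whose pixel area falls outside `[min_area, max_area]`
#' (used against debris specks and merged/oversized detections) and
#' renumbers the survivors contiguously from 1, preserving their original
#' order.
#'
#' @param labels integer label matrix (0 = background).
#' @param min_area,max_area inclusive pixel-area bounds.
#' @return Integer label matrix with labels `1..K`.
#' @export
filter_nuclei <- function(labels, min_area = 0, max_area = Inf) {
  if (min_area > max_area) stop("`min_area` must be <= `max_area`")
  if (!any(labels > 0)) return(labels)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  lut <- integer(length(areas))
  lut[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0
  out[pos] <- lut[labels[pos]]
  out
}

#' Segmentation parameter set
#'
#' Bundles the tunable segmentation parameters with their defaults. The
#' defaults were chosen for typical 20x-40x H-DAB material and every one
#' of them is expected to be tuned per staining protocol; area gates are
#' physical (square microns) and are converted to pixels through the
#' image's mpp.
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold OD cut-off when `threshold_method = "fixed"`.
#' @param min_distance_px minimum seed separation, pixels.
#' @param min_height minimum normalised distance-map peak height.
#' @param min_area_um2,max_area_um2 nucleus area gates in square microns
#'   (defaults 10-400, spanning typical mammalian nuclear cross-sections).
#' @param connectivity 8 or 4.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(threshold_method = "otsu", fixed_threshold = NULL,
                       min_distance_px = 7, min_height = 0.2,
                       min_area_um2 = 10, max_area_um2 = 400,
                       connectivity = 8) {
  stopifnot(min_distance_px >= 1, min_height >= 0, min_height <= 1,
            min_area_um2 <= max_area_um2, connectivity %in% c(4, 8))
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_distance_px = min_distance_px,
                 min_height = min_height,
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2,
                 connectivity = connectivity),
            class = "seg_params")
}

#' Segment nuclei from stain channels
#'
#' Runs the full nuclear segmentation chain on the haematoxylin channel:
#' threshold, Euclidean distance transform, peak seeding,
#' marker-controlled watershed, and physical-size filtering.
#'
#' @param channels a [stain_channels()] object.
#' @param params a [seg_params()] parameter set.
#' @return Integer label matrix (nuclei numbered `1..K`), with attributes
#'   `threshold` (OD cut-off used) and `n_seeds` (seed count before size
#'   filtering).
#' @examples
#' \dontrun{
#' sim <- simulate_roi_image(simulation_config(seed = 1))
#' ch <- separate_stains(rgb_to_od(sim$image), mpp = sim$image$mpp)
#' labels <- segment_nuclei(ch)
#' max(labels) # number of nuclei
#' }
#' @export
segment_nuclei <- function(channels, params = seg_params()) {
  if (!inherits(channels, "stain_channels"))
    stop("`channels` must be a stain_channels object")
  mask <- threshold_foreground(channels$hematoxylin,
                               method = params$threshold_method,
                               fixed_threshold = params$fixed_threshold)
  dmap <- compute_distance_map(mask)
  seeds <- detect_seeds(dmap, min_distance = params$min_distance_px,
                        min_height = params$min_height,
                        connectivity = params$connectivity)
  labels <- if (nrow(seeds) == 0) {
    matrix(0L, nrow(mask), ncol(mask))
  } else {
    watershed_segment(dmap, seeds, mask, connectivity = params$connectivity)
  }
  px_per_um2 <- 1 / channels$mpp^2
  labels <- filter_nuclei(labels,
                          min_area = params$min_area_um2 * px_per_um2,
                          max_area = params$max_area_um2 * px_per_um2)
  attr(labels, "threshold") <- attr(mask, "threshold")
  attr(labels, "n_seeds") <- nrow(seeds)
  labels
}
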