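#' RGB brightfield image with physical resolution
#'
#' Light container for an 8-bit RGB image and its isotropic resolution in
#' microns per pixel (mpp). All pipeline entry points that start from
#' colour data take this object.
#'
#' @param pixels numeric or integer H x W x 3 array with values in
#'   \[0, 255\].
#' @param mpp microns per pixel (positive scalar, isotropic).
#' @return An object of class `rgb_image` with elements `pixels` (integer
#'   array) and `mpp`.
#' @examples
#' img <- rgb_image(array(255L, dim = c(4, 4, 3)), mpp = 0.5)
#' dim(img$pixels)
#' @export
rgb_image <- function(pixels, mpp) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a positive scalar")
  structure(list(pixels = array(as.integer(round(pixels)), dim = dim(pixels)),
                 mpp = as.numeric(mpp)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %.4g microns/px\n", d[1], d[2], x$mpp))
  invisible(x)
}

#' H-DAB stain matrix
#'
#' Builds the stain matrix used for colour deconvolution. Rows are unit
#' optical-density direction vectors in RGB-OD space. The defaults are the
#' standard Ruifrok-Johnston reference vectors for haematoxylin and DAB; a
#' residual third vector is completed as the normalised cross product so
#' the matrix is always invertible.
#'
#' @param hematoxylin,dab length-3 nonnegative RGB-OD direction vectors;
#'   they are normalised to unit length.
#' @return 3 x 3 numeric matrix with rows `hematoxylin`, `dab`,
#'   `residual`, each of unit Euclidean norm.
#' @references Ruifrok AC, Johnston DA (2001). Quantification of
#'   histochemical staining by color deconvolution. Anal Quant Cytol
#'   Histol 23:291-299.
#' @examples
#' M <- hdab_stain_matrix()
#' rowSums(M^2) # all 1
#' @export
hdab_stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                              dab = c(0.269, 0.568, 0.778)) {
  unit <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(!is.finite(v)))
      stop(sprintf("`%s` must be a finite length-3 vector", what))
    n <- sqrt(sum(v^2))
    if (n == 0) stop(sprintf("`%s` must be nonzero", what))
    v / n
  }
  h <- unit(hematoxylin, "hematoxylin")
  d <- unit(dab, "dab")
  res <- c(h[2] * d[3] - h[3] * d[2],
           h[3] * d[1] - h[1] * d[3],
           h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(res^2))
  if (nr < 1e-8)
    stop("hematoxylin and dab vectors are collinear; stain matrix is singular")
  m <- rbind(hematoxylin = h, dab = d, residual = res / nr)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Convert RGB intensities to optical density
#'
#' Applies the Beer-Lambert relation per channel,
#' `OD = -log10(max(I, 1) / 255)`. Intensities are floored at 1 before the
#' logarithm so that the output is finite; the maximum attainable OD is
#' therefore `log10(255)` (about 2.4065).
#'
#' @param image an [rgb_image()], or a bare H x W x 3 intensity array.
#' @return H x W x 3 numeric array of optical densities in
#'   \[0, log10(255)\].
#' @examples
#' img <- rgb_image(array(128L, dim = c(2, 2, 3)), mpp = 0.5)
#' range(rgb_to_od(img))
#' @export
rgb_to_od <- function(image) {
  px <- if (inherits(image, "rgb_image")) image$pixels else image
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected an rgb_image or an H x W x 3 array")
  -log10(pmax(px, 1) / 255)
}

#' Separate an optical-density image into haematoxylin and DAB channels
#'
#' Colour deconvolution: each pixel's OD vector is expressed in the basis
#' of the stain matrix rows by solving the 3 x 3 linear system, giving
#' per-stain concentration maps. Negative concentrations (deconvolution
#' bleed-through / noise) are clamped to zero.
#'
#' @param od H x W x 3 optical-density array, e.g. from [rgb_to_od()].
#' @param stain_matrix a 3 x 3 matrix from [hdab_stain_matrix()] (rows
#'   hematoxylin, dab, residual).
#' @param mpp microns per pixel carried into the result.
#' @return A `stain_channels` object: list with `hematoxylin` and `dab`
#'   (H x W nonnegative matrices) and `mpp`.
#' @examples
#' img <- rgb_image(array(255L, dim = c(3, 3, 3)), mpp = 0.5)
#' ch <- separate_stains(rgb_to_od(img), hdab_stain_matrix(), mpp = 0.5)
#' max(ch$hematoxylin) # 0 for a white image
#' @export
separate_stains <- function(od, stain_matrix = hdab_stain_matrix(), mpp) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("`od` must be an H x W x 3 array")
  if (!is.matrix(stain_matrix) || any(dim(stain_matrix) != c(3L, 3L)))
    stop("`stain_matrix` must be 3 x 3")
  if (abs(det(stain_matrix)) < 1e-8)
    stop("stain matrix is singular; check the stain vectors")
  d <- dim(od)
  flat <- matrix(od, nrow = d[1] * d[2], ncol = 3L) # pixels x RGB
  # od_pixel = conc %*% stain_matrix  =>  conc = od_pixel %*% inv(M)
  conc <- flat %*% solve(stain_matrix)
  conc[conc < 0] <- 0
  stain_channels(hematoxylin = matrix(conc[, 1], d[1], d[2]),
                 dab = matrix(conc[, 2], d[1], d[2]),
                 mpp = mpp)
}

#' Construct stain channels directly
#'
#' Bypass constructor for inputs that already come as split haematoxylin /
#' DAB optical-density planes, skipping the deconvolution step.
#'
#' @param hematoxylin,dab H x W nonnegative numeric matrices of the same
#'   shape.
#' @param mpp microns per pixel.
#' @return A `stain_channels` object.
#' @export
stain_channels <- function(hematoxylin, dab, mpp) {
  if (!is.matrix(hematoxylin) || !is.matrix(dab) ||
      any(dim(hematoxylin) != dim(dab)))
    stop("`hematoxylin` and `dab` must be matrices of identical shape")
  if (min(hematoxylin) < 0 || min(dab) < 0)
    stop("optical densities must be nonnegative")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a positive scalar")
  structure(list(hematoxylin = hematoxylin, dab = dab, mpp = as.numeric(mpp)),
            class = "stain_channels")
}

#' @export
print.stain_channels <- function(x, ...) {
  cat(sprintf("<stain_channels> %d x %d px, %.4g microns/px (H max %.3f, DAB max %.3f)\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin), x$mpp,
              max(x$hematoxylin), max(x$dab)))
  invisible(x)
}

# Compose OD concentration maps back into an 8-bit RGB array through the
# Beer-Lambert relation. Shared by the simulator and kept internal.
od_to_rgb <- function(h_od, d_od, stain_matrix = hdab_stain_matrix()) {
  d <- dim(h_od)
  conc <- cbind(as.vector(h_od), as.vector(d_od), 0)
  od <- conc %*% stain_matrix
  px <- 255 * 10^(-od)
  array(px, dim = c(d[1], d[2], 3L))
}
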