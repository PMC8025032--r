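# Vascular irregularity: windowed information entropy, rotational-SVD
# directionality/anisotropy, the anisotropy-weighted entropy map used for
# automatic tumor segmentation, and the modulated angiogram.

#' Windowed information entropy map
#'
#' For every pixel, the Shannon entropy of the amplitude histogram in the
#' centered \code{window} x \code{window} mm neighborhood:
#' \deqn{H = -\sum_{i=1}^{n} P_i \log_2 P_i}
#' with \eqn{P_i} the fraction of window pixels falling in bin \eqn{i}
#' (\eqn{0 \log 0 := 0}). Bin edges are global -- \code{n_bins} equal-width
#' bins spanning [0, max of the image] -- so entropies are comparable across
#' windows. Border windows are clipped.
#'
#' @param map background-thresholded \code{\link{map_image}} (or matrix).
#' @param window window side (mm), default 1.
#' @param n_bins number of histogram bins (>= 2), default 32.
#' @param pixel_size mm per pixel (from the \code{map_image} if absent).
#' @return Object of class \code{entropy_map}: \code{values} (bits, in
#'   [0, log2(n_bins)]), \code{window_mm}, \code{n_bins}, \code{pixel_size}.
#' @export
entropy_map <- function(map, window = 1, n_bins = 32, pixel_size = NULL) {
  if (n_bins < 2) stop("config error: n_bins must be >= 2")
  px <- as_pixels(map)
  stop_if_not_matrix(px, "map")
  if (is.null(pixel_size))
    pixel_size <- if (inherits(map, "map_image")) map$pixel_size else 1
  w <- window_px(window, pixel_size)
  hi <- max(px)
  # bin index per pixel (values == hi land in the top bin)
  bin <- if (hi > 0) pmin(floor(px / hi * n_bins) + 1L, n_bins) else
    matrix(1L, nrow(px), ncol(px))
  total <- box_sum(matrix(1, nrow(px), ncol(px)), w)
  H <- matrix(0, nrow(px), ncol(px))
  for (b in seq_len(n_bins)) {
    ind <- matrix(as.numeric(bin == b), nrow(px), ncol(px))
    if (!any(ind > 0)) next
    P <- box_sum(ind, w) / total
    P <- pmax(pmin(P, 1), 0)
    contrib <- ifelse(P > 0, -P * log2(P), 0)
    H <- H + contrib
  }
  structure(list(values = H, window_mm = window, n_bins = n_bins,
                 pixel_size = pixel_size), class = "entropy_map")
}

#' Normalized SVD dominancy of a rotated window
#'
#' \deqn{N_{SVD}(\theta) = \Sigma_{11}(\theta) / \mathrm{tr}[\Sigma(\theta)]}
#' the largest singular value of the window rotated by \eqn{\theta} (bilinear
#' interpolation, zero fill) over the sum of its singular values. An all-zero
#' (rank-0) window returns 1 by convention.
#'
#' @param window_matrix square numeric matrix.
#' @param theta rotation angle (degrees).
#' @return Scalar in (0, 1].
#' @export
nsvd <- function(window_matrix, theta = 0) {
  if (nrow(window_matrix) != ncol(window_matrix))
    stop("window must be square")
  cpp_nsvd(window_matrix, theta)
}

#' Directionality of a window
#'
#' \deqn{D = \max_\theta N_{SVD}(\theta) - \min_\theta N_{SVD}(\theta)}
#' over a grid of rotation angles covering [0, 180) degrees. Smooth straight
#' vessels give high \eqn{D}; disordered (or rotation-invariant) texture
#' gives \eqn{D} near 0.
#'
#' @param window_matrix square numeric matrix.
#' @param theta_grid rotation angles (degrees), default 0 to 170 in steps
#'   of 10.
#' @return Scalar \eqn{D \ge 0}.
#' @export
directionality <- function(window_matrix, theta_grid = seq(0, 170, by = 10)) {
  if (!length(theta_grid)) stop("config error: empty theta grid")
  if (nrow(window_matrix) != ncol(window_matrix))
    stop("window must be square")
  cpp_directionality(window_matrix, as.numeric(theta_grid))
}

#' Anisotropy from directionality
#'
#' \deqn{A = 1 / (D + \epsilon)} -- high where the vasculature lacks a
#' dominant orientation (tumor-like disorder); \eqn{\epsilon} bounds the
#' reciprocal.
#'
#' @param D directionality value(s), \eqn{\ge 0}.
#' @param epsilon regularization (default 0.01), so \eqn{A \le 1/\epsilon}.
#' @return Anisotropy value(s).
#' @export
anisotropy <- function(D, epsilon = 0.01) {
  if (any(D < 0)) stop("D must be non-negative")
  1 / (D + epsilon)
}

#' Anisotropy-weighted entropy
#'
#' \deqn{E = H \exp(-k \, A^{-1}) = H \exp(-k (D + \epsilon))}
#' The weight is at most 1, so \eqn{E \le H}; windows with high
#' directionality (smooth healthy vessels) are strongly suppressed while
#' disordered tumor-like windows keep their entropy. The alternative literal
#' reading \eqn{E = H \exp(-k (A - 1))} is available as
#' \code{reading = "offset"} (it suppresses low-directionality windows
#' instead and is not the default).
#'
#' @param H entropy value(s) (bits), \eqn{\ge 0}.
#' @param A anisotropy value(s), \eqn{> 0}.
#' @param k weighting coefficient, default 30.
#' @param reading which rendering of the weighting to use.
#' @return Weighted entropy value(s).
#' @export
weighted_entropy <- function(H, A, k = 30, reading = c("reciprocal", "offset")) {
  reading <- match.arg(reading)
  if (any(H < 0)) stop("H must be non-negative")
  if (any(A <= 0)) stop("A must be positive")
  switch(reading,
         reciprocal = H * exp(-k / A),
         offset = H * exp(-k * (A - 1)))
}

#' Anisotropy-weighted entropy map
#'
#' Slides the analysis window across the image and computes, per pixel, the
#' entropy \eqn{H}, directionality \eqn{D}, anisotropy \eqn{A = 1/(D+\epsilon)}
#' and weighted entropy \eqn{E}. Windows are extracted with a \eqn{\sqrt 2}
#' margin before rotation and center-cropped after, so rotated corners are
#' filled with real neighboring pixels rather than padding.
#'
#' @param map background-thresholded \code{\link{map_image}} (or matrix).
#' @param window window side (mm), default 1.
#' @param n_bins histogram bins for the entropy, default 32.
#' @param k entropy weighting coefficient, default 30.
#' @param epsilon anisotropy regularization, default 0.01.
#' @param rotation_step rotation step (degrees), default 10.
#' @param pixel_size mm per pixel (from the \code{map_image} if absent).
#' @return Object of class \code{feature_maps} with matrices \code{H},
#'   \code{D}, \code{A} (NA where the window holds no signal, since texture
#'   orientation is undefined there), \code{E}, the window \code{support}
#'   mask, and the parameters used.
#' @export
weighted_entropy_map <- function(map, window = 1, n_bins = 32, k = 30,
                                 epsilon = 0.01, rotation_step = 10,
                                 pixel_size = NULL) {
  px <- as_pixels(map)
  stop_if_not_matrix(px, "map")
  if (is.null(pixel_size))
    pixel_size <- if (inherits(map, "map_image")) map$pixel_size else 1
  w <- window_px(window, pixel_size)
  thetas <- seq(0, 180 - rotation_step, by = rotation_step)
  margin <- ceiling(w * (sqrt(2) - 1) / 2) + 1
  H <- entropy_map(px, window = window, n_bins = n_bins,
                   pixel_size = pixel_size)$values
  D <- cpp_directionality_map(px, as.integer(w), as.integer(margin),
                              as.numeric(thetas))
  # windows with no signal at all have no defined texture orientation; their
  # anisotropy is NA so region statistics are not swamped by the empty-window
  # convention (N_SVD = 1, D = 0, A = 1/epsilon)
  support <- box_sum(matrix(as.numeric(px != 0), nrow(px), ncol(px)), w) > 0.5
  A <- matrix(NA_real_, nrow(px), ncol(px))
  A[support] <- anisotropy(D[support], epsilon)
  E <- H * exp(-k * (D + epsilon))
  structure(list(H = H, D = D, A = A, E = E, support = support,
                 window_mm = window, n_bins = n_bins, k = k,
                 epsilon = epsilon, rotation_step = rotation_step,
                 pixel_size = pixel_size),
            class = "feature_maps")
}

#' Automatic tumor segmentation from the weighted entropy map
#'
#' Binarizes \eqn{M_{ae}} at the whole-support mean plus
#' \code{sd_multiplier} standard deviations and keeps the 8-connected
#' component with the largest pixel count (the cancer mask).
#'
#' @param mae a \code{\link{weighted_entropy_map}} result, or a numeric
#'   matrix of weighted entropy values.
#' @param sd_multiplier threshold offset in SDs, default 1.4 (calibrated in
#'   the source system against breast MRI tumor sizes; exposed as a plain
#'   configuration default here).
#' @param support_mask logical matrix restricting the mean/SD statistics and
#'   the mask to the breast support; default: the whole frame.
#' @return Object of class \code{tumor_mask}: \code{mask} (logical, a single
#'   8-connected component, possibly empty), \code{threshold},
#'   \code{sd_multiplier}. Warns when nothing exceeds the threshold.
#' @export
segment_tumor <- function(mae, sd_multiplier = 1.4, support_mask = NULL) {
  E <- if (inherits(mae, "feature_maps")) mae$E else mae
  stop_if_not_matrix(E, "mae")
  if (is.null(support_mask)) support_mask <- matrix(TRUE, nrow(E), ncol(E))
  vals <- E[support_mask]
  thr <- mean(vals) + sd_multiplier * sd(vals)
  cand <- E > thr & support_mask
  if (!any(cand)) {
    warning("empty suprathreshold set; returning empty tumor mask")
    return(structure(list(mask = cand, threshold = thr,
                          sd_multiplier = sd_multiplier),
                     class = "tumor_mask"))
  }
  lab <- label8(cand)
  areas <- label_areas(lab)
  best <- which.max(areas)
  structure(list(mask = lab == best, threshold = thr,
                 sd_multiplier = sd_multiplier),
            class = "tumor_mask")
}

#' Tumor dimensions from a segmentation mask
#'
#' Long axis (LA) and short axis (SA) are the extents of the mask along and
#' perpendicular to its principal axis (plus one pixel, so a single-pixel
#' mask has LA = SA = one pixel). With per-slice masks the elevational extent
#' is the number of non-empty slices times the elevational spacing and the
#' volume is the summed slice area times the spacing; otherwise an ellipsoid
#' approximation from LA, SA and (if given) the elevational extent is
#' reported and flagged.
#'
#' @param mask a \code{\link{segment_tumor}} result or logical matrix.
#' @param pixel_size in-plane pixel size (mm).
#' @param per_slice_masks optional list of per-elevational-slice logical
#'   masks.
#' @param elevational_spacing elevational slice spacing (mm), default 1.
#' @return List: \code{la_cm}, \code{sa_cm}, \code{el_cm} (NA without
#'   elevational data), \code{volume_cm3}, \code{method}
#'   (\code{"slices"} or \code{"ellipsoid"}).
#' @export
tumor_dimensions <- function(mask, pixel_size, per_slice_masks = NULL,
                             elevational_spacing = 1) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  if (!any(m)) stop("undefined dimensions: empty tumor mask")
  idx <- which(m, arr.ind = TRUE)
  xy <- idx * pixel_size
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  if (nrow(cc) > 1) {
    v <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  } else v <- c(1, 0)
  u <- c(-v[2], v[1])
  la <- diff(range(cc %*% v)) + pixel_size
  sa <- diff(range(cc %*% u)) + pixel_size
  if (sa > la) { tmp <- la; la <- sa; sa <- tmp }
  if (!is.null(per_slice_masks)) {
    nonempty <- vapply(per_slice_masks, function(s) any(s), logical(1))
    el <- sum(nonempty) * elevational_spacing
    vol <- sum(vapply(per_slice_masks, sum, numeric(1))) * pixel_size^2 *
      elevational_spacing
    method <- "slices"
  } else {
    el <- NA_real_
    # ellipsoid (oblate, elevational extent assumed equal to SA if unknown)
    vol <- pi / 6 * la * sa * (if (is.na(el)) sa else el)
    method <- "ellipsoid"
  }
  list(la_cm = la / 10, sa_cm = sa / 10, el_cm = el / 10,
       volume_cm3 = vol / 1000, method = method)
}

#' Modulate an angiogram with the weighted entropy map
#'
#' \deqn{M_f = (M_{ae} + \beta) \, M_{PA}} with \eqn{M_{ae}} normalized to
#' [0, 1]: lesions (high \eqn{M_{ae}}) are enhanced while the background
#' constant \eqn{\beta} maintains the healthy-tissue information at reduced
#' weight; the result is self-normalized. The additive reading
#' \eqn{M_f = M_{ae} + \beta M_{PA}} is available as
#' \code{mode = "additive"}.
#'
#' @param map the original \code{\link{map_image}} \eqn{M_{PA}}.
#' @param mae a \code{\link{weighted_entropy_map}} result or matrix.
#' @param beta background constant, default 0.07.
#' @param mode \code{"multiplicative"} (default) or \code{"additive"}.
#' @return Modulated \code{\link{map_image}} \eqn{M_f}, self-normalized.
#' @export
modulate <- function(map, mae, beta = 0.07,
                     mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  px <- as_pixels(map)
  E <- if (inherits(mae, "feature_maps")) mae$E else mae
  if (!all(dim(px) == dim(E))) stop("shape mismatch between map and mae")
  En <- normalize01(E)
  out <- switch(mode,
                multiplicative = (En + beta) * px,
                additive = En + beta * px)
  wrap_like(map, normalize01(out), sprintf("modulate(%s, beta=%.2f)", mode, beta))
}
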