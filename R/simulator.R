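#' Full-ring transducer array geometry
#'
#' Geometry and response parameters of a desk-scale 2D ring-array
#' photoacoustic scanner. Defaults match a whole-breast full-ring system:
#' 512 elements on a 220 mm ring, 2.25 MHz central frequency, 100 us record
#' window. The DAQ sampling rate and the detection bandwidth are not fixed by
#' the hardware description and are exposed as parameters (defaults 40 MHz
#' and 70% fractional bandwidth).
#'
#' @param ring_diameter ring diameter (mm).
#' @param n_elements number of elements (>= 3), evenly spaced on the ring.
#' @param center_frequency transducer central frequency (MHz).
#' @param fractional_bandwidth -6 dB fractional bandwidth of the
#'   Gaussian-envelope band-pass impulse response.
#' @param sampling_rate DAQ sampling rate (MHz).
#' @param record_window record length after the laser pulse (us).
#' @param speed_of_sound homogeneous speed of sound (mm/us).
#' @return Object of class \code{ring_array_geometry}; includes element
#'   positions \code{elem_x}, \code{elem_y} (mm, ring centered at the origin)
#'   and \code{dt} (us), \code{n_samples}.
#' @export
ring_array_geometry <- function(ring_diameter = 220,
                                n_elements = 512,
                                center_frequency = 2.25,
                                fractional_bandwidth = 0.7,
                                sampling_rate = 40,
                                record_window = 100,
                                speed_of_sound = 1.5) {
  if (n_elements < 3) stop("n_elements must be >= 3")
  if (ring_diameter <= 0 || sampling_rate <= 0 || record_window <= 0 ||
      speed_of_sound <= 0)
    stop("geometry parameters must be positive")
  phi <- 2 * pi * (seq_len(n_elements) - 1) / n_elements
  dt <- 1 / sampling_rate
  structure(list(
    ring_diameter = ring_diameter, n_elements = n_elements,
    center_frequency = center_frequency,
    fractional_bandwidth = fractional_bandwidth,
    sampling_rate = sampling_rate, record_window = record_window,
    speed_of_sound = speed_of_sound,
    elem_x = ring_diameter / 2 * cos(phi),
    elem_y = ring_diameter / 2 * sin(phi),
    dt = dt, n_samples = round(record_window * sampling_rate)
  ), class = "ring_array_geometry")
}

# Gaussian-envelope band-pass impulse response, unity gain at the central
# frequency. Returns a kernel centered at sample (length(h)+1)/2.
bandpass_kernel <- function(geometry) {
  f0 <- geometry$center_frequency
  sigma_f <- geometry$fractional_bandwidth * f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  th <- seq(-4 * sigma_t, 4 * sigma_t, by = geometry$dt)
  h <- exp(-th^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * th)
  # unity gain at the central frequency (discrete-convolution sense)
  gain <- Mod(sum(h * exp(-2i * pi * f0 * th)))
  h / gain
}

# Convolve each row of traces with kernel k (centered), linear convolution.
convolve_rows <- function(traces, k) {
  n <- ncol(traces); m <- length(k); half <- (m - 1) / 2
  nfft <- 2^ceiling(log2(n + m))
  K <- fft(c(k, rep(0, nfft - m)))
  out <- t(apply(traces, 1, function(p) {
    P <- fft(c(p, rep(0, nfft - n)))
    y <- Re(fft(P * K, inverse = TRUE)) / nfft
    y[(half + 1):(half + n)]
  }))
  out
}

#' Simulate ring-array channel data from an inclusion phantom
#'
#' Analytic forward model: the initial pressure is
#' \eqn{p_0(r) = \Gamma \mu_a(r) \Phi(r)} with the Grueneisen parameter
#' treated as a unit constant. The phantom is decomposed into uniform disks
#' (the breast background disk plus one disk per inclusion carrying the
#' absorption excess over background); each disk contributes the classic
#' N-shaped transient of a uniform spherical absorber of matching radius,
#' \eqn{p(d,t) = p_0 (d - ct)/(2d)} for \eqn{|d - ct| < a}, delayed by the
#' element distance. Traces are optionally convolved with the transducer
#' band-pass impulse response; white Gaussian noise can be added under a
#' seed.
#'
#' @param phantom a \code{\link{make_inclusion_phantom}} object.
#' @param fluence fluence at the phantom plane: scalar or matrix from
#'   \code{\link{fluence_map}}; a matrix is averaged per absorber. Use 1 for
#'   a flat-fluence (absorption-only) simulation.
#' @param geometry a \code{\link{ring_array_geometry}}.
#' @param noise_sigma SD of additive white Gaussian noise (trace units).
#' @param seed RNG seed for the noise.
#' @param impulse_response \code{"bandpass"} (default) applies the transducer
#'   band-pass; \code{"none"} keeps the wideband analytic transients (use for
#'   quantitative amplitude studies).
#' @return Object of class \code{channel_data}: \code{traces}
#'   (n_elements x n_samples), \code{dt} (us), \code{geometry}.
#' @export
forward_simulate <- function(phantom, fluence = 1, geometry = ring_array_geometry(),
                             noise_sigma = 0, seed = NULL,
                             impulse_response = c("bandpass", "none")) {
  stopifnot(inherits(phantom, "breast_phantom"),
            inherits(geometry, "ring_array_geometry"))
  impulse_response <- match.arg(impulse_response)
  ring_r <- geometry$ring_diameter / 2
  if (phantom$breast_radius >= ring_r)
    stop("geometry error: phantom does not fit inside the ring")

  flu_at <- function(center) {
    if (is.matrix(fluence)) {
      i <- which.min(abs(phantom$x - center[1]))
      j <- which.min(abs(phantom$y - center[2]))
      fluence[i, j]
    } else fluence
  }

  # disk decomposition: background disk + excess-absorption inclusion disks
  disks <- list(list(center = c(0, 0), radius = phantom$breast_radius,
                     p0 = phantom$background_props$mu_a * flu_at(c(0, 0))))
  for (inc in phantom$inclusions) {
    dmu <- inc$props$mu_a - phantom$background_props$mu_a
    if (dmu != 0)
      disks[[length(disks) + 1]] <- list(center = inc$center,
                                         radius = inc$diameter / 2,
                                         p0 = dmu * flu_at(inc$center))
  }
  for (d in disks)
    if (sqrt(sum(d$center^2)) + d$radius >= ring_r)
      stop("geometry error: absorber outside the ring")

  c0 <- geometry$speed_of_sound
  tt <- (seq_len(geometry$n_samples) - 1) * geometry$dt
  traces <- matrix(0, geometry$n_elements, geometry$n_samples)
  for (e in seq_len(geometry$n_elements)) {
    pe <- c(geometry$elem_x[e], geometry$elem_y[e])
    tr <- numeric(geometry$n_samples)
    for (d in disks) {
      dist <- sqrt(sum((pe - d$center)^2))
      arg <- dist - c0 * tt
      sup <- abs(arg) < d$radius
      if (any(sup)) tr[sup] <- tr[sup] + d$p0 * arg[sup] / (2 * dist)
    }
    traces[e, ] <- tr
  }

  if (impulse_response == "bandpass")
    traces <- convolve_rows(traces, bandpass_kernel(geometry))
  if (noise_sigma > 0)
    traces <- traces + with_seed(seed,
      matrix(rnorm(length(traces), 0, noise_sigma), nrow(traces), ncol(traces)))

  structure(list(traces = traces, dt = geometry$dt, geometry = geometry),
            class = "channel_data")
}

#' Reconstruction grid
#'
#' @param xlim,ylim grid extents (mm) in the ring coordinate frame (ring
#'   center at the origin).
#' @param pixel_size pixel spacing (mm).
#' @return Object of class \code{recon_grid} with pixel-center coordinates.
#' @export
recon_grid <- function(xlim, ylim, pixel_size = 0.1) {
  x <- seq(xlim[1] + pixel_size / 2, xlim[2] - pixel_size / 2, by = pixel_size)
  y <- seq(ylim[1] + pixel_size / 2, ylim[2] - pixel_size / 2, by = pixel_size)
  structure(list(x = x, y = y, pixel_size = pixel_size), class = "recon_grid")
}

#' Universal back-projection reconstruction
#'
#' Implements the universal back-projection (UBP) formula for a full-ring
#' aperture: the back-projection term \eqn{b(t) = 2 p(t) - 2 t \, dp/dt}
#' (derivative by central differences, one-sided at the ends) is evaluated at
#' the flight time \eqn{t = |r_{pixel} - r_{element}| / c} for every element
#' (linear interpolation between samples) and summed with equal weights over
#' the ring.
#'
#' @param data a \code{\link{forward_simulate}} result (or compatible
#'   \code{channel_data}).
#' @param grid a \code{\link{recon_grid}}; must lie inside the ring.
#' @return A \code{\link{map_image}} of reconstructed amplitude on the grid.
#'   Pixels whose flight time exceeds the record window for some element
#'   contribute zero for that element and trigger a coverage warning.
#' @export
ubp_reconstruct <- function(data, grid) {
  stopifnot(inherits(data, "channel_data"), inherits(grid, "recon_grid"))
  g <- data$geometry
  ring_r <- g$ring_diameter / 2
  if (max(abs(grid$x)) >= ring_r || max(abs(grid$y)) >= ring_r)
    stop("reconstruction grid must lie inside the ring")
  nt <- ncol(data$traces)
  tt <- (seq_len(nt) - 1) * data$dt
  # b(t) = 2 p - 2 t dp/dt
  dp <- data$traces
  dp[, 2:(nt - 1)] <- (data$traces[, 3:nt] - data$traces[, 1:(nt - 2)]) /
    (2 * data$dt)
  dp[, 1] <- (data$traces[, 2] - data$traces[, 1]) / data$dt
  dp[, nt] <- (data$traces[, nt] - data$traces[, nt - 1]) / data$dt
  b <- 2 * data$traces - 2 * sweep(dp, 2, tt, `*`)

  nx <- length(grid$x); ny <- length(grid$y)
  X <- matrix(grid$x, nx, ny)
  Y <- matrix(grid$y, nx, ny, byrow = TRUE)
  img <- matrix(0, nx, ny)
  uncovered <- FALSE
  inv_c_dt <- 1 / (g$speed_of_sound * data$dt)
  for (e in seq_len(g$n_elements)) {
    d <- sqrt((X - g$elem_x[e])^2 + (Y - g$elem_y[e])^2)
    ti <- d * inv_c_dt + 1        # fractional sample index (1-based)
    i0 <- floor(ti)
    frac <- ti - i0
    ok <- i0 >= 1 & i0 < nt
    if (any(!ok)) uncovered <- TRUE
    i0ok <- i0[ok]
    be <- b[e, ]
    val <- numeric(length(ti))
    val[ok] <- be[i0ok] * (1 - frac[ok]) + be[i0ok + 1] * frac[ok]
    img <- img + val
  }
  if (uncovered)
    warning("coverage warning: some pixels' flight times exceed the record window")
  map_image(img / g$n_elements, grid$pixel_size, provenance = "ubp_reconstruct")
}

#' Depth compensation of reconstructed amplitude
#'
#' Multiplies each pixel by \eqn{e^{0.6 \times \mathrm{depth(cm)}}} to
#' compensate the fluence decay with depth (identity at depth 0).
#'
#' @param image a \code{\link{map_image}} or numeric matrix.
#' @param depth_cm pixel depth in cm: a scalar (plane at constant depth) or a
#'   matrix matching the image.
#' @param rate compensation rate per cm (default 0.6).
#' @return Compensated image, same type as the input.
#' @export
depth_compensate <- function(image, depth_cm, rate = 0.6) {
  px <- if (inherits(image, "map_image")) image$pixels else image
  out <- px * exp(rate * depth_cm)
  if (inherits(image, "map_image")) {
    image$pixels <- out
    add_provenance(image, "depth_compensate")
  } else out
}

#' Detect absorbing inclusions in a reconstructed phantom image
#'
#' Lightly smooths the image, thresholds at the background mean plus three
#' background standard deviations, and returns 8-connected components of at
#' least \code{min_area} pixels with centroids (mm) and equivalent diameters.
#'
#' @param image reconstructed \code{\link{map_image}} whose pixel grid is
#'   described by \code{grid}.
#' @param grid the \code{\link{recon_grid}} used for the reconstruction.
#' @param background_mask logical matrix marking background pixels used for
#'   the threshold statistics (non-empty).
#' @param search_mask optional logical matrix restricting where detections
#'   are accepted (e.g. the breast interior, to exclude boundary artifacts).
#' @param smooth_sigma Gaussian smoothing sigma (px); the default 3 px is
#'   about the in-plane system resolution (~0.3 mm) on a 0.1 mm grid.
#' @param min_area minimum component area (px).
#' @return data.frame with one row per detection: \code{x_mm}, \code{y_mm}
#'   (centroid in the ring frame), \code{area_px},
#'   \code{equiv_diameter_mm}, \code{peak}.
#' @export
detect_inclusions <- function(image, grid, background_mask, search_mask = NULL,
                              smooth_sigma = 3, min_area = 2) {
  stopifnot(inherits(image, "map_image"), inherits(grid, "recon_grid"))
  if (missing(background_mask) || sum(background_mask) == 0)
    stop("config error: background_mask must be non-empty")
  sm <- as_mat(EBImage::gblur(image$pixels, sigma = smooth_sigma))
  thr <- mean(sm[background_mask]) + 3 * sd(sm[background_mask])
  cand <- sm > thr
  if (!is.null(search_mask)) cand <- cand & search_mask
  lab <- label8(cand)
  areas <- label_areas(lab)
  keep <- which(areas >= min_area)
  if (!length(keep))
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      area_px = integer(0), equiv_diameter_mm = numeric(0),
                      peak = numeric(0)))
  cent <- label_centroids(lab)
  out <- data.frame(
    x_mm = approx(seq_along(grid$x), grid$x, xout = cent[keep, 1])$y,
    y_mm = approx(seq_along(grid$y), grid$y, xout = cent[keep, 2])$y,
    area_px = areas[keep],
    equiv_diameter_mm = 2 * sqrt(areas[keep] / pi) * grid$pixel_size,
    peak = vapply(keep, function(k) max(sm[lab == k]), numeric(1))
  )
  out[order(-out$peak), , drop = FALSE]
}
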