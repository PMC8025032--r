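#' Specification of a synthetic vascular MAP scene
#'
#' Describes a two-compartment breast angiogram: a healthy compartment of
#' smooth, preferentially oriented vessel segments spread uniformly over the
#' field of view,
#' and a tumor compartment of short, tortuous, densely packed microvessels
#' confined to a disk (emulating tumor-associated angiogenesis).
#' \code{response_fraction} removes that fraction of the tumor microvessels,
#' emulating vascular regression under neoadjuvant chemotherapy
#' (0 = untreated baseline, 1 = complete response: only crossing healthy
#' vessels remain in the tumor region).
#'
#' Vessel centerlines are heading random walks: the local heading diffuses
#' with scale \code{tortuosity} (rad per sqrt(mm)), so healthy vessels
#' (small scale) stay smooth and directional while tumor microvessels (large
#' scale) curl tightly. Contrast between compartments is purely geometric
#' (density, length, orientation order); all vessels share the same peak
#' amplitude so irregularity metrics are tested independently of brightness.
#'
#' @param domain_size field of view (mm), length-2 vector.
#' @param pixel_size pixel spacing (mm).
#' @param healthy_vessel_count expected number of healthy vessel segments
#'   per field-of-view area (segments are drawn over a buffered domain so
#'   coverage is stationary up to the image border).
#' @param healthy_vessel_length_range healthy segment length range (mm);
#'   segments emulate the branch-to-branch vessel stretches seen in a MAP,
#'   several times longer than tumor microvessels.
#' @param healthy_tortuosity heading random-walk scale of healthy vessels
#'   (rad / sqrt(mm)).
#' @param preferred_orientation mean healthy orientation (deg).
#' @param orientation_jitter SD of healthy orientations around the preferred
#'   one (deg).
#' @param tumor_center,tumor_radius tumor disk geometry (mm; center relative
#'   to the field-of-view center).
#' @param tumor_microvessel_count microvessels in the untreated tumor.
#' @param tumor_tortuosity heading random-walk scale of tumor microvessels.
#' @param tumor_vessel_length_range microvessel length range (mm).
#' @param vessel_radius_range vessel radius range (mm); rendered as a Gaussian
#'   cross-section with sigma = radius / 2.
#' @param response_fraction fraction of tumor microvessels removed, in [0,1].
#' @param noise_sigma SD of additive background noise (peak vessel
#'   amplitude = 1).
#' @param seed RNG seed; same seed and spec give a bit-identical scene.
#' @return Object of class \code{vascular_scene_spec}.
#' @export
vascular_scene_spec <- function(domain_size = c(20, 20),
                                pixel_size = 0.1,
                                healthy_vessel_count = 60,
                                healthy_vessel_length_range = c(3, 6),
                                healthy_tortuosity = 0.05,
                                preferred_orientation = 30,
                                orientation_jitter = 15,
                                tumor_center = c(0, 0),
                                tumor_radius = 4,
                                tumor_microvessel_count = 120,
                                tumor_tortuosity = 1.5,
                                tumor_vessel_length_range = c(1, 2.5),
                                vessel_radius_range = c(0.15, 0.3),
                                response_fraction = 0,
                                noise_sigma = 0.05,
                                seed = 1) {
  if (response_fraction < 0 || response_fraction > 1)
    stop("response_fraction must be in [0, 1]")
  if (tumor_microvessel_count > 0 && tumor_radius <= 0)
    stop("config error: tumor_radius must be positive when tumor microvessels are requested")
  if (any(abs(tumor_center) + tumor_radius > domain_size / 2))
    stop("tumor region must lie inside the domain")
  structure(list(
    domain_size = domain_size, pixel_size = pixel_size,
    healthy_vessel_count = healthy_vessel_count,
    healthy_vessel_length_range = healthy_vessel_length_range,
    healthy_tortuosity = healthy_tortuosity,
    preferred_orientation = preferred_orientation,
    orientation_jitter = orientation_jitter,
    tumor_center = tumor_center, tumor_radius = tumor_radius,
    tumor_microvessel_count = tumor_microvessel_count,
    tumor_tortuosity = tumor_tortuosity,
    tumor_vessel_length_range = tumor_vessel_length_range,
    vessel_radius_range = vessel_radius_range,
    response_fraction = response_fraction,
    noise_sigma = noise_sigma, seed = seed
  ), class = "vascular_scene_spec")
}

# One vessel centerline as a dense polyline (step mm), heading random walk.
trace_vessel <- function(start, heading0, tortuosity, length_mm, step,
                         half, two_sided = FALSE) {
  n <- max(2L, ceiling(length_mm / step))
  walk <- function(h0, sgn) {
    dh <- rnorm(n, 0, tortuosity * sqrt(step))
    h <- h0 + cumsum(dh)
    dx <- sgn * step * cos(h); dy <- sgn * step * sin(h)
    px <- start[1] + cumsum(dx); py <- start[2] + cumsum(dy)
    keep <- abs(px) <= half[1] & abs(py) <= half[2]
    if (!all(keep)) {
      k <- which(!keep)[1]
      if (k <= 1) return(NULL)
      keep <- seq_len(k - 1)
      px <- px[keep]; py <- py[keep]
    }
    cbind(px, py)
  }
  pts <- walk(heading0, 1)
  if (two_sided) {
    back <- walk(heading0 + pi, 1)
    if (!is.null(back)) pts <- rbind(back[rev(seq_len(nrow(back))), , drop = FALSE],
                                     start, pts)
  }
  pts
}

# Stamp a Gaussian-profile vessel (max-combined) into img; pts in mm
# (origin at image center), sigma in mm.
stamp_vessel <- function(img, pts, sigma, pixel_size, half) {
  if (is.null(pts) || nrow(pts) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  rad_px <- max(1L, ceiling(3 * sigma / pixel_size))
  off <- -rad_px:rad_px
  # pixel-center coordinate of row/col i: (i - (n+1)/2) * pixel_size
  pr <- pts[, 1] / pixel_size + (nr + 1) / 2
  pc <- pts[, 2] / pixel_size + (nc + 1) / 2
  for (i in seq_len(nrow(pts))) {
    r0 <- round(pr[i]); c0 <- round(pc[i])
    rs <- r0 + off; cs <- c0 + off
    rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
    if (!any(rok) || !any(cok)) next
    rs <- rs[rok]; cs <- cs[cok]
    d2 <- outer((rs - pr[i])^2, (cs - pc[i])^2, "+") * pixel_size^2
    img[rs, cs] <- pmax(img[rs, cs], exp(-d2 / (2 * sigma^2)))
  }
  img
}

#' Generate a synthetic vascular MAP scene with ground truth
#'
#' @param spec a \code{\link{vascular_scene_spec}}.
#' @return List with elements \code{map} (a \code{\link{map_image}}) and
#'   \code{truth}: \code{tumor_mask} (the tumor disk), \code{healthy_mask}
#'   (an annulus beyond a 2 mm guard band around the tumor, kept clear of the
#'   image border), \code{background_mask}
#'   (vessel-free pixels before noise, usable as the out-of-tissue background
#'   region for thresholding), \code{n_healthy}, \code{n_tumor_rendered}.
#' @export
make_vascular_scene <- function(spec) {
  stopifnot(inherits(spec, "vascular_scene_spec"))
  with_seed(spec$seed, {
    half <- spec$domain_size / 2
    np <- round(spec$domain_size / spec$pixel_size)
    img <- matrix(0, np[1], np[2])
    step <- spec$pixel_size / 2

    # healthy compartment: smooth directional vessel segments with uniform
    # centers. Finite segment length (branch-point to branch-point in a MAP)
    # keeps the spatial correlation length of the compartment a few mm, so
    # distinct analysis windows sample distinct vessels. Centers are sampled
    # from a buffered domain (image plus half the maximum segment length) and
    # walks may leave the image, so edge pixels are not coverage-depleted --
    # the compartment is stationary across the whole field of view.
    buffer <- spec$healthy_vessel_length_range[2] / 2 + 1
    half_ext <- half + buffer
    n_buffered <- round(spec$healthy_vessel_count *
                          prod(2 * half_ext) / prod(2 * half))
    for (i in seq_len(n_buffered)) {
      start <- runif(2, -half_ext, half_ext)
      heading <- (spec$preferred_orientation +
                    rnorm(1, 0, spec$orientation_jitter)) * pi / 180
      len <- runif(1, spec$healthy_vessel_length_range[1],
                   spec$healthy_vessel_length_range[2])
      radius <- runif(1, spec$vessel_radius_range[1], spec$vessel_radius_range[2])
      pts <- trace_vessel(start, heading, spec$healthy_tortuosity,
                          length_mm = len / 2, step = step,
                          half = half_ext, two_sided = TRUE)
      img <- stamp_vessel(img, pts, sigma = radius / 2,
                          pixel_size = spec$pixel_size, half = half)
    }

    # tumor compartment: short tortuous microvessels in the tumor disk;
    # draw all, keep the first (1 - response_fraction) share so increasing
    # response_fraction removes a nested subset (monotone regression).
    n_keep <- round((1 - spec$response_fraction) * spec$tumor_microvessel_count)
    for (i in seq_len(spec$tumor_microvessel_count)) {
      u <- runif(1); ang <- runif(1, 0, 2 * pi)
      start <- spec$tumor_center + spec$tumor_radius * sqrt(u) * 0.9 *
        c(cos(ang), sin(ang))
      heading <- runif(1, 0, 2 * pi)
      len <- runif(1, spec$tumor_vessel_length_range[1],
                   spec$tumor_vessel_length_range[2])
      radius <- runif(1, spec$vessel_radius_range[1], spec$vessel_radius_range[2])
      pts <- trace_vessel(start, heading, spec$tumor_tortuosity,
                          length_mm = len, step = step, half = half)
      if (i <= n_keep)
        img <- stamp_vessel(img, pts, sigma = radius / 2,
                            pixel_size = spec$pixel_size, half = half)
    }

    background_mask <- img < 1e-3
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
      img[img < 0] <- 0   # PA amplitudes are non-negative
    }

    x <- (seq_len(np[1]) - (np[1] + 1) / 2) * spec$pixel_size
    y <- (seq_len(np[2]) - (np[2] + 1) / 2) * spec$pixel_size
    R2 <- outer(x - spec$tumor_center[1], y - spec$tumor_center[2],
                function(dx, dy) dx^2 + dy^2)
    tumor_mask <- R2 <= spec$tumor_radius^2
    # healthy reference: an annulus beyond a 2 mm guard band, kept away from
    # the image border so window clipping affects both regions alike
    healthy_mask <- R2 > (spec$tumor_radius + 2)^2 &
      R2 <= (0.85 * min(half))^2

    list(
      map = map_image(img, spec$pixel_size, provenance = "synthetic_scene"),
      truth = list(tumor_mask = tumor_mask,
                   healthy_mask = healthy_mask,
                   background_mask = background_mask,
                   n_healthy = spec$healthy_vessel_count,
                   n_tumor_rendered = n_keep)
    )
  })
}
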