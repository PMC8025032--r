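# Skeleton-based relative vessel density.
#
# MAP angiograms are binarized, thinned to one-pixel centerlines, broken into
# independent vessels at junction points, short spurs are discarded, and the
# relative density is the number of distinct vessels intersecting a sliding
# window divided by the window area.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning to a 1-px-wide skeleton (8-connected homotopic).
thin_skeleton <- function(mask) {
  M <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  # neighbor order P2..P9 clockwise from north (row-1)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P <- lapply(offs, function(o) shift_mat(M, -o[1], -o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(M), ncol(M))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (P[[i]] == 0L & P[[j]] == 1L)
      }
      if (pass == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0L
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0L
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0L
      }
      del <- M == 1L & B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) { M[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  M > 0L
}

# 8-neighbor count of each skeleton pixel.
neighbor_count <- function(sk) {
  M <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  n <- matrix(0L, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) n <- n + shift_mat(M, dr, dc)
  n
}

# Split centerlines into independent segments at junction pixels.
segment_labels <- function(skeleton, junctions) label8(skeleton & !junctions)

#' Extract a vessel skeleton graph from a MAP angiogram
#'
#' Binarizes the conditioned MAP with hysteresis thresholding (weak/strong
#' thresholds are fractions of a high reference quantile, so the skeleton is
#' invariant to global intensity scaling), thins to one-pixel centerlines,
#' marks junctions (skeleton pixels with three or more 8-neighbors), and
#' splits the centerlines into independent vessel segments at the junctions.
#'
#' @param map conditioned \code{\link{map_image}} (or matrix).
#' @param pixel_size mm per pixel (taken from the \code{map_image} if absent).
#' @param low,high hysteresis thresholds as fractions of the reference
#'   intensity.
#' @param ref_quantile quantile of the positive intensities used as the
#'   reference.
#' @return Object of class \code{skeleton_graph}: \code{skeleton} (logical
#'   centerline mask), \code{junctions} (logical), \code{segments} (integer
#'   label matrix, one id per independent vessel), \code{n_segments},
#'   \code{pixel_size}. An all-zero map yields an empty skeleton.
#' @export
extract_skeleton <- function(map, pixel_size = NULL, low = 0.2, high = 0.5,
                             ref_quantile = 0.995) {
  px <- as_pixels(map)
  if (is.null(pixel_size))
    pixel_size <- if (inherits(map, "map_image")) map$pixel_size else 1
  pos <- px[px > 0]
  if (!length(pos)) {
    empty <- matrix(FALSE, nrow(px), ncol(px))
    return(structure(list(skeleton = empty, junctions = empty,
                          segments = matrix(0L, nrow(px), ncol(px)),
                          n_segments = 0L, pixel_size = pixel_size),
                     class = "skeleton_graph"))
  }
  ref <- quantile(pos, ref_quantile, names = FALSE)
  weak <- px >= low * ref
  strong <- px >= high * ref
  lab <- label8(weak)
  keep <- unique(lab[strong & lab > 0])
  mask <- matrix(lab %in% keep & lab > 0, nrow(px), ncol(px))
  sk <- thin_skeleton(mask)
  junctions <- sk & neighbor_count(sk) >= 3
  segs <- segment_labels(sk, junctions)
  structure(list(skeleton = sk, junctions = junctions, segments = segs,
                 n_segments = max(segs), pixel_size = pixel_size),
            class = "skeleton_graph")
}

#' Split a skeleton at junctions and remove short segments
#'
#' Re-derives the independent vessel segments of a skeleton graph and drops
#' segments with fewer than \code{min_length} pixels (noise spurs).
#'
#' @param skeleton a \code{\link{extract_skeleton}} result.
#' @param min_length minimum segment pixel count (default 3).
#' @return A filtered \code{skeleton_graph} (segment ids renumbered 1..n).
#' @export
split_and_filter <- function(skeleton, min_length = 3) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  segs <- segment_labels(skeleton$skeleton, skeleton$junctions)
  areas <- label_areas(segs)
  keep <- which(areas >= min_length)
  relabel <- integer(max(segs, 1L))
  relabel[keep] <- seq_along(keep)
  out <- segs
  out[segs > 0] <- relabel[segs[segs > 0]]
  skeleton$segments <- out
  skeleton$n_segments <- length(keep)
  skeleton$skeleton <- out > 0 | skeleton$junctions
  skeleton
}

#' Relative vessel density map
#'
#' For every pixel, the number of distinct vessel segments intersecting the
#' centered \code{window} x \code{window} mm window divided by the window
#' area (mm^2). Windows are clipped at the image border and the clipped area
#' is used. The window size is rounded to an odd pixel count.
#'
#' @param skeleton a filtered \code{\link{skeleton_graph}}.
#' @param window window side (mm), default 2.
#' @return Object of class \code{density_map}: \code{values} (mm^-2),
#'   \code{window_mm}, \code{pixel_size}.
#' @export
density_map <- function(skeleton, window = 2) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  if (round(window / skeleton$pixel_size) < 3)
    stop("config error: window smaller than 3 pixels")
  w <- window_px(window, skeleton$pixel_size)
  nr <- nrow(skeleton$segments); nc <- ncol(skeleton$segments)
  counts <- matrix(0, nr, nc)
  for (id in seq_len(skeleton$n_segments)) {
    hit <- box_sum(matrix(as.numeric(skeleton$segments == id), nr, nc), w)
    counts <- counts + (hit > 0.5)
  }
  area <- box_sum(matrix(1, nr, nc), w) * skeleton$pixel_size^2
  structure(list(values = counts / area, window_mm = window,
                 pixel_size = skeleton$pixel_size),
            class = "density_map")
}

#' Highlight high-vessel-density regions
#'
#' Returns the mask of 8-connected regions whose relative density exceeds
#' \code{threshold} and whose area is at least \code{min_area}; small
#' suprathreshold islands (likely artifacts or sub-clinical foci) are
#' rejected.
#'
#' @param density a \code{\link{density_map}}.
#' @param threshold density threshold (mm^-2), default 2.5.
#' @param min_area minimum region area (mm^2), default 4.
#' @return Logical matrix.
#' @export
highlight_regions <- function(density, threshold = 2.5, min_area = 4) {
  stopifnot(inherits(density, "density_map"))
  lab <- label8(density$values > threshold)
  areas <- label_areas(lab) * density$pixel_size^2
  keep <- which(areas >= min_area)
  matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab))
}
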