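# ROI-vs-healthy statistics: metric values are sampled over non-overlapping
# windows (numerical independence), compared with a one-tailed Welch t-test
# under the null that the tumor ROI mean does not exceed the healthy mean.

#' ROI definition carried across time points
#'
#' The region of interest is the cancer-affected area delineated on the
#' baseline (T1) image and reused unchanged on the coregistered follow-up
#' images; the healthy mask must be disjoint from it.
#'
#' @param roi_mask,healthy_mask logical matrices, disjoint.
#' @return Object of class \code{roi_definition}.
#' @export
roi_definition <- function(roi_mask, healthy_mask) {
  if (!all(dim(roi_mask) == dim(healthy_mask)))
    stop("masks must share dimensions")
  if (any(roi_mask & healthy_mask))
    stop("roi_mask and healthy_mask must be disjoint")
  structure(list(roi_mask = roi_mask > 0, healthy_mask = healthy_mask > 0),
            class = "roi_definition")
}

#' Non-overlapping window samples of a metric map
#'
#' Tiles the bounding box of \code{mask} with disjoint \code{window} x
#' \code{window} mm tiles; a tile qualifies when at least
#' \code{min_fraction} of its pixels lie inside the mask, and contributes the
#' mean metric value over its in-mask pixels.
#'
#' @param metric_map numeric matrix (or an object with a \code{values}
#'   matrix, e.g. a \code{\link{density_map}} or \code{\link{entropy_map}}).
#' @param mask logical matrix defining the region.
#' @param window tile side (mm).
#' @param pixel_size mm per pixel.
#' @param min_fraction minimum in-mask fraction of the full tile area for a
#'   tile to qualify (default 0.5).
#' @return Object of class \code{window_samples}: \code{values} (one mean
#'   per tile, NA metric pixels excluded), \code{tiles} (data.frame of tile
#'   row/col bounds), \code{window_mm}. Errors when no tile qualifies.
#' @export
window_samples <- function(metric_map, mask, window, pixel_size,
                           min_fraction = 0.5) {
  vals <- if (is.matrix(metric_map)) metric_map else metric_map$values
  if (!all(dim(vals) == dim(mask))) stop("metric map and mask shape mismatch")
  w <- max(1L, round(window / pixel_size))
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("sample-size error: empty mask")
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  samples <- numeric(0)
  tiles <- list()
  for (rs in seq(r0, r1, by = w)) {
    re <- min(rs + w - 1, nrow(mask))   # full tiles, clipped at the image edge
    for (cs in seq(c0, c1, by = w)) {
      ce <- min(cs + w - 1, ncol(mask))
      sub <- mask[rs:re, cs:ce, drop = FALSE]
      # fraction relative to the full w x w tile area
      if (sum(sub) / w^2 >= min_fraction) {
        v <- vals[rs:re, cs:ce, drop = FALSE][sub]
        if (any(!is.na(v))) {
          samples <- c(samples, mean(v, na.rm = TRUE))
          tiles[[length(tiles) + 1]] <- c(rs, re, cs, ce)
        }
      }
    }
  }
  if (!length(samples))
    stop("sample-size error: no window with >= ", min_fraction,
         " of its area inside the mask")
  tl <- do.call(rbind, tiles)
  structure(list(values = samples,
                 tiles = data.frame(r0 = tl[, 1], r1 = tl[, 2],
                                    c0 = tl[, 3], c1 = tl[, 4]),
                 window_mm = window),
            class = "window_samples")
}

#' One-tailed Welch t-test (ROI greater than healthy)
#'
#' Welch's unequal-variances t-test with Satterthwaite degrees of freedom,
#' one-tailed for the alternative that the ROI population mean exceeds the
#' healthy population mean (null: ROI mean less than or equal). When both
#' groups are constant with equal means the test is undecidable and p = 0.5
#' is returned, flagged.
#'
#' @param roi,healthy \code{\link{window_samples}} objects or numeric
#'   vectors (each of length >= 2).
#' @return Object of class \code{welch_result}: group means and standard
#'   errors, \code{t}, \code{df}, \code{p}, \code{degenerate} flag.
#' @export
welch_one_tailed <- function(roi, healthy) {
  x <- if (inherits(roi, "window_samples")) roi$values else roi
  y <- if (inherits(healthy, "window_samples")) healthy$values else healthy
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 samples")
  degenerate <- FALSE
  if (sd(x) == 0 && sd(y) == 0) {
    degenerate <- TRUE
    t_stat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    df <- length(x) + length(y) - 2
    p <- if (mean(x) == mean(y)) 0.5 else if (mean(x) > mean(y)) 0 else 1
  } else {
    ht <- t.test(x, y, alternative = "greater", var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(
    mean_roi = mean(x), se_roi = sd(x) / sqrt(length(x)),
    mean_healthy = mean(y), se_healthy = sd(y) / sqrt(length(y)),
    n_roi = length(x), n_healthy = length(y),
    t = t_stat, df = df, p = p,
    alternative = "roi mean greater than healthy mean",
    degenerate = degenerate
  ), class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("ROI %.4g +/- %.2g (n=%d) vs healthy %.4g +/- %.2g (n=%d)\n",
              x$mean_roi, x$se_roi, x$n_roi,
              x$mean_healthy, x$se_healthy, x$n_healthy))
  cat(sprintf("Welch one-tailed: t = %.3f, df = %.2f, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' PA amplitude ratio between ROI and depth-matched healthy tissue
#'
#' @param map \code{\link{map_image}} or matrix of PA amplitudes.
#' @param roi_mask,healthy_mask_same_depth logical matrices; the healthy
#'   region should sit at the same depth band as the ROI so fluence cancels.
#' @return Mean ROI amplitude divided by mean healthy amplitude.
#' @export
amplitude_ratio <- function(map, roi_mask, healthy_mask_same_depth) {
  px <- as_pixels(map)
  h <- mean(px[healthy_mask_same_depth])
  if (h == 0) stop("undefined ratio: zero mean amplitude in the healthy region")
  mean(px[roi_mask]) / h
}

# Metric maps used in the longitudinal report for one conditioned MAP.
compute_metric_maps <- function(map, density_window = 2, entropy_window = 1,
                                n_bins = 32, k = 30, epsilon = 0.01,
                                rotation_step = 10, min_length = 3) {
  sk <- split_and_filter(extract_skeleton(map), min_length = min_length)
  dens <- density_map(sk, window = density_window)
  fm <- weighted_entropy_map(map, window = entropy_window, n_bins = n_bins,
                             k = k, epsilon = epsilon,
                             rotation_step = rotation_step)
  list(density = dens$values, entropy = fm$H, anisotropy = fm$A,
       features = fm, skeleton = sk)
}

#' Longitudinal ROI-vs-healthy report
#'
#' For each time point: relative vessel density, entropy and anisotropy are
#' sampled over non-overlapping windows inside the (fixed, baseline-defined)
#' ROI and the healthy region, compared by one-tailed Welch t-tests, and the
#' tumor dimensions from the automatic segmentation are appended.
#'
#' @param maps named list of conditioned \code{\link{map_image}}s, one per
#'   time point (e.g. \code{list(T1 = ..., T2 = ..., T3 = ...)}), coregistered.
#' @param roi a \code{\link{roi_definition}} (ROI defined on the first time
#'   point).
#' @param density_window,texture_window analysis window sides (mm) of the
#'   density and entropy/anisotropy maps.
#' @param stat_window side (mm) of the non-overlapping tiles used to draw
#'   ROI and healthy samples for the Welch tests. It should be at least the
#'   spatial correlation length of the vasculature, otherwise neighboring
#'   tiles share vessels and the test is anti-conservative; 4 mm suits the
#'   synthetic scenes.
#' @param sd_multiplier segmentation threshold multiplier passed to
#'   \code{\link{segment_tumor}}.
#' @param support_mask optional breast-support mask for the segmentation
#'   statistics.
#' @param ... further parameters for \code{compute_metric_maps}
#'   (\code{n_bins}, \code{k}, \code{epsilon}, \code{rotation_step},
#'   \code{min_length}).
#' @return Object of class \code{nac_report}: \code{metrics} (data.frame:
#'   time_point, metric, n/mean/se per region, t, df, p_one_tailed) and
#'   \code{dimensions} (data.frame per time point; NA row when the
#'   segmentation is empty).
#' @export
longitudinal_report <- function(maps, roi, density_window = 2,
                                texture_window = 1, stat_window = 4,
                                sd_multiplier = 1.4,
                                support_mask = NULL, ...) {
  stopifnot(inherits(roi, "roi_definition"))
  if (is.null(names(maps)) || any(names(maps) == ""))
    names(maps) <- paste0("T", seq_along(maps))
  rows <- list()
  dims <- list()
  for (tp in names(maps)) {
    map <- maps[[tp]]
    if (is.null(map)) {
      warning("missing time point ", tp, "; partial report")
      next
    }
    mm <- compute_metric_maps(map, density_window = density_window,
                              entropy_window = texture_window, ...)
    for (metric in c("density", "entropy", "anisotropy")) {
      rs <- window_samples(mm[[metric]], roi$roi_mask, stat_window,
                           map$pixel_size)
      hs <- window_samples(mm[[metric]], roi$healthy_mask, stat_window,
                           map$pixel_size)
      wt <- welch_one_tailed(rs, hs)
      rows[[length(rows) + 1]] <- data.frame(
        time_point = tp, metric = metric,
        n_roi = wt$n_roi, mean_roi = wt$mean_roi, se_roi = wt$se_roi,
        n_healthy = wt$n_healthy, mean_healthy = wt$mean_healthy,
        se_healthy = wt$se_healthy,
        t = wt$t, df = wt$df, p_one_tailed = wt$p)
    }
    seg <- suppressWarnings(segment_tumor(mm$features,
                                          sd_multiplier = sd_multiplier,
                                          support_mask = support_mask))
    dims[[length(dims) + 1]] <- if (any(seg$mask)) {
      d <- tumor_dimensions(seg, map$pixel_size)
      data.frame(time_point = tp, la_cm = d$la_cm, sa_cm = d$sa_cm,
                 el_cm = d$el_cm, volume_cm3 = d$volume_cm3,
                 method = d$method)
    } else data.frame(time_point = tp, la_cm = NA_real_, sa_cm = NA_real_,
                      el_cm = NA_real_, volume_cm3 = NA_real_,
                      method = "empty")
  }
  structure(list(metrics = do.call(rbind, rows),
                 dimensions = do.call(rbind, dims)),
            class = "nac_report")
}

#' @export
print.nac_report <- function(x, ...) {
  cat("ROI-vs-healthy longitudinal report\n")
  print(x$metrics, digits = 4)
  cat("\nTumor dimensions (automatic segmentation)\n")
  print(x$dimensions, digits = 3)
  invisible(x)
}

#' Write a longitudinal report to CSV
#'
#' @param report an \code{\link{longitudinal_report}} result.
#' @param metrics_csv,dimensions_csv output paths.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, metrics_csv, dimensions_csv = NULL) {
  stopifnot(inherits(report, "nac_report"))
  write.csv(report$metrics, metrics_csv, row.names = FALSE)
  if (!is.null(dimensions_csv))
    write.csv(report$dimensions, dimensions_csv, row.names = FALSE)
  invisible(c(metrics_csv, dimensions_csv))
}
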