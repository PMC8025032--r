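# Float-TIFF + JSON-sidecar I/O. TIFF stores values scaled to [0, 1]; the
# sidecar records the scale (and offset for signed data) so round-trips are
# exact to float precision.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a MAP image as float TIFF with a JSON sidecar
#'
#' @param map a \code{\link{map_image}}.
#' @param path output TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return Invisibly, \code{path}.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "map_image"))
  scale <- max(abs(map$pixels), 1e-300)
  tiff::writeTIFF(map$pixels / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(type = "map_image", scale = scale, pixel_size = map$pixel_size,
         provenance = map$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a MAP image written by \code{\link{write_map_tiff}}
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A \code{\link{map_image}}.
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  px <- tiff::readTIFF(path)
  map_image(px * meta$scale, meta$pixel_size, provenance = meta$provenance)
}

#' Write ring-array channel data (float TIFF + JSON sidecar)
#'
#' Traces are bipolar, so they are stored as \code{(x/scale + 1)/2} with the
#' scale in the sidecar together with the geometry.
#'
#' @param data a \code{\link{forward_simulate}} result.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
write_channel_data <- function(data, path) {
  stopifnot(inherits(data, "channel_data"))
  scale <- max(abs(data$traces), 1e-300)
  tiff::writeTIFF((data$traces / scale + 1) / 2, path,
                  bits.per.sample = 32L, reduce = FALSE)
  g <- data$geometry
  jsonlite::write_json(
    list(type = "channel_data", scale = scale, dt = data$dt,
         geometry = g[c("ring_diameter", "n_elements", "center_frequency",
                        "fractional_bandwidth", "sampling_rate",
                        "record_window", "speed_of_sound")]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read channel data written by \code{\link{write_channel_data}}
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A \code{channel_data} object.
#' @export
read_channel_data <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  tr <- (tiff::readTIFF(path) * 2 - 1) * meta$scale
  geometry <- do.call(ring_array_geometry, as.list(meta$geometry))
  structure(list(traces = tr, dt = meta$dt, geometry = geometry),
            class = "channel_data")
}

# Order the pixels of one segment into a chain by walking from an endpoint.
order_chain <- function(pix) {
  n <- nrow(pix)
  if (n <= 2) return(pix)
  left <- seq_len(n)
  adj <- function(i, pool)
    pool[abs(pix[pool, 1] - pix[i, 1]) <= 1 & abs(pix[pool, 2] - pix[i, 2]) <= 1 &
           pool != i]
  deg <- vapply(left, function(i) length(adj(i, left)), integer(1))
  cur <- left[which(deg == 1)[1]]
  if (is.na(cur)) cur <- left[1]
  path <- integer(0)
  while (length(left)) {
    path <- c(path, cur)
    left <- setdiff(left, cur)
    nb <- adj(cur, left)
    if (!length(nb)) break
    cur <- nb[1]
  }
  pix[c(path, setdiff(seq_len(n), path)), , drop = FALSE]
}

#' Export skeleton segments as a polyline CSV
#'
#' One row per centerline pixel: \code{segment_id}, \code{x_mm},
#' \code{y_mm} (origin at the image center), ordered along each segment.
#'
#' @param skeleton a \code{\link{skeleton_graph}}.
#' @param path output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_skeleton_csv <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  nr <- nrow(skeleton$segments); nc <- ncol(skeleton$segments)
  out <- list()
  for (id in seq_len(skeleton$n_segments)) {
    pix <- which(skeleton$segments == id, arr.ind = TRUE)
    pix <- order_chain(pix)
    out[[id]] <- data.frame(
      segment_id = id,
      x_mm = (pix[, 1] - (nr + 1) / 2) * skeleton$pixel_size,
      y_mm = (pix[, 2] - (nc + 1) / 2) * skeleton$pixel_size)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(segment_id = integer(0), x_mm = numeric(0), y_mm = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write feature maps (H, D, A, E) as a multi-page float TIFF
#'
#' @param fm a \code{\link{weighted_entropy_map}} result.
#' @param path output TIFF path (pages in the order H, D, A, E); parameters
#'   and per-page scales go to the JSON sidecar.
#' @return Invisibly, \code{path}.
#' @export
write_feature_maps <- function(fm, path) {
  stopifnot(inherits(fm, "feature_maps"))
  pages <- c("H", "D", "A", "E")
  # anisotropy is NA outside the window support; stored as 0 (the support
  # mask is recoverable from H > 0 or D > 0)
  grab <- function(p) { m <- fm[[p]]; m[is.na(m)] <- 0; m }
  scales <- vapply(pages, function(p) max(abs(grab(p)), 1e-300), numeric(1))
  tiff::writeTIFF(lapply(seq_along(pages),
                         function(i) grab(pages[i]) / scales[i]),
                  path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(type = "feature_maps", pages = pages, scales = scales,
         params = fm[c("window_mm", "n_bins", "k", "epsilon",
                       "rotation_step", "pixel_size")]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
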