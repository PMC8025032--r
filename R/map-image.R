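#' 2D maximum-amplitude-projection (MAP) angiogram container
#'
#' A thin container for a 2D photoacoustic amplitude image \eqn{M_{PA}} with
#' its physical pixel spacing and a processing-history list.
#'
#' @param pixels numeric matrix of PA amplitudes (arbitrary linear units).
#' @param pixel_size physical pixel spacing (mm), positive.
#' @param provenance character vector of processing steps already applied.
#' @return Object of class \code{map_image}.
#' @export
map_image <- function(pixels, pixel_size, provenance = character()) {
  stop_if_not_matrix(pixels, "pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (mm)")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = as.character(provenance)),
            class = "map_image")
}

#' @export
print.map_image <- function(x, ...) {
  cat("map_image:", nrow(x$pixels), "x", ncol(x$pixels), "px,",
      x$pixel_size, "mm/px, range [", signif(min(x$pixels), 3), ",",
      signif(max(x$pixels), 3), "]\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Append a provenance tag, preserving class.
add_provenance <- function(map, tag) {
  map$provenance <- c(map$provenance, tag)
  map
}

#' Maximum-amplitude projection of a volume
#'
#' Per-pixel maximum over the elevational axis of a 3D stack, the standard
#' projection used for whole-breast angiogram quantification (the elevational
#' resolution of a ring-array scanner is much coarser than in-plane, so
#' quantification is done on 2D MAPs).
#'
#' @param volume 3D numeric array (x, y, elevational slice).
#' @param pixel_size in-plane pixel spacing (mm).
#' @return A \code{\link{map_image}}.
#' @export
map_project <- function(volume, pixel_size) {
  if (!is.array(volume) || length(dim(volume)) != 3)
    stop("volume must be a 3D array")
  px <- apply(volume, c(1, 2), max)
  map_image(px, pixel_size, provenance = "map_project")
}
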