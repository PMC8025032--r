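# Internal helpers shared across modules.

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# stream so generators don't clobber the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Window size in pixels: nearest odd pixel count covering `mm` at `pixel_size`
# mm/px, never below 3 px.
window_px <- function(mm, pixel_size) {
  w <- round(mm / pixel_size)
  if (w %% 2 == 0) w <- w + 1
  max(w, 3L)
}

normalize01 <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x
}

# EBImage returns Image (S4 array) objects; keep plain base matrices inside
# the package.
as_mat <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- matrix(x, dim(x)[1], dim(x)[2])
  x
}

# Box filter (sum over a w x w window, zero outside the image), exact clipped
# windows at borders.
box_sum <- function(x, w) {
  stopifnot(w %% 2 == 1)
  k <- matrix(1, w, w)
  as_mat(EBImage::filter2(x, k, boundary = 0))
}

# 8-connected labeling. EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally via union-find.
label8 <- function(mask) {
  mask <- mask > 0
  lab <- as_mat(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Area (pixel count) per label of a label matrix.
label_areas <- function(lab) {
  n <- max(lab)
  if (n == 0) return(integer(0))
  tabulate(lab[lab > 0], nbins = n)
}

# Centroids (row, col) per label.
label_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- factor(lab[lab > 0], levels = seq_len(n))
  cbind(as.numeric(tapply(idx[, 1], l, mean)),
        as.numeric(tapply(idx[, 2], l, mean)))
}

# Dice overlap of two logical masks.
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) stop(name, " must be a numeric matrix")
  if (any(!is.finite(x))) stop(name, " must be finite")
  invisible(x)
}
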