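# Independent pure-R oracles used to check the package's computations.

# Bilinear rotation about the window center, zero fill -- the reference
# definition the compiled path must reproduce.
rotate_ref <- function(w, theta_deg) {
  n <- nrow(w)
  cc <- (n + 1) / 2
  th <- theta_deg * pi / 180
  out <- matrix(0, n, n)
  for (cl in 1:n) for (r in 1:n) {
    xc <- cl - cc; yc <- r - cc
    xs <- cos(th) * xc + sin(th) * yc
    ys <- -sin(th) * xc + cos(th) * yc
    sr <- ys + cc; sc <- xs + cc
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    v <- 0
    for (dr in 0:1) for (dc in 0:1) {
      rr <- r0 + dr; ccx <- c0 + dc
      if (rr >= 1 && rr <= n && ccx >= 1 && ccx <= n)
        v <- v + (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc) * w[rr, ccx]
    }
    out[r, cl] <- v
  }
  out
}

nsvd_ref <- function(w, theta_deg) {
  s <- svd(if (abs(theta_deg) < 1e-12) w else rotate_ref(w, theta_deg))$d
  if (sum(s) <= 0) 1 else s[1] / sum(s)
}

directionality_ref <- function(w, thetas = seq(0, 170, by = 10)) {
  v <- vapply(thetas, function(t) nsvd_ref(w, t), numeric(1))
  max(v) - min(v)
}

# Hand-evaluated Welch t with Satterthwaite degrees of freedom, one-tailed.
welch_ref <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 1 - pt(t, df))
}

# Shannon entropy of a vector under fixed global bin edges [0, hi].
entropy_ref <- function(v, n_bins, hi) {
  b <- pmin(floor(v / hi * n_bins) + 1L, n_bins)
  p <- tabulate(b, nbins = n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Straight synthetic vessel image: Gaussian cross-section around a line
# x = x0 (axis-aligned), peak 1.
straight_vessel_image <- function(n = 80, x0_px = 40.5, sigma_px = 1.5) {
  d <- abs(matrix(seq_len(n), n, n) - x0_px)
  exp(-d^2 / (2 * sigma_px^2))
}
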