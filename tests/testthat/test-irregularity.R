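test_that("windowed entropy matches closed-form cases", {
  # constant image: a single occupied bin everywhere -> H = 0
  em <- entropy_map(matrix(3, 30, 30), window = 5, n_bins = 8, pixel_size = 1)
  expect_true(all(em$values == 0))
  # half the window pixels in each of two bins -> 1 bit
  img <- matrix(rep(c(0.1, 0.9), each = 15), 30, 30)  # two half-planes
  em <- entropy_map(img, window = 10, n_bins = 2, pixel_size = 1)
  w <- pactangio:::window_px(10, 1)  # 11
  expect_equal(em$values[15, 15], 1, tolerance = 0.1)
  # exact check at the half-plane boundary with an even split: use a stripe
  # pattern so every window is split 6/5 -> compare against the oracle
  stripes <- matrix(rep(c(0.1, 0.9), length.out = 30), 30, 30)
  em2 <- entropy_map(stripes, window = 10, n_bins = 2, pixel_size = 1)
  expect_equal(em2$values[15, 15],
               entropy_ref(stripes[10:20, 10:20], 2, max(stripes)),
               tolerance = 1e-10)
  # uniform occupation of all bins -> log2(n_bins)
  vals <- rep(seq(0.5, 3.5, by = 1) / 4, length.out = 121)
  img3 <- matrix(0.01, 30, 30)
  img3[10:20, 10:20] <- matrix(vals[order(runif(121))], 11, 11)
  img3 <- img3 / max(img3) * 1  # top value defines the upper edge
  em3 <- entropy_map(img3, window = 10, n_bins = 4, pixel_size = 1)
  expect_lte(max(em3$values), 2 + 1e-12)
  expect_error(entropy_map(matrix(1, 5, 5), n_bins = 1), "n_bins")
})

test_that("entropy is bounded by [0, log2(n_bins)] on random windows", {
  set.seed(7)
  for (rep in 1:4) {
    img <- matrix(runif(50 * 50), 50, 50)
    nb <- sample(c(2, 8, 32), 1)
    em <- entropy_map(img, window = 8, n_bins = nb, pixel_size = 1)
    expect_true(all(em$values >= -1e-12))          # 2500 windows per rep
    expect_true(all(em$values <= log2(nb) + 1e-12))
  }
})

test_that("normalized SVD dominancy matches its defining cases", {
  # rank-1 window: one nonzero singular value
  r1 <- outer(c(1, 2, 3, 4), c(2, 0.5, 1, 3))
  expect_equal(nsvd(r1, 0), 1, tolerance = 1e-12)
  # identity: equal singular values
  expect_equal(nsvd(diag(8), 0), 1 / 8, tolerance = 1e-12)
  # diag(3, 1): 3 / (3 + 1)
  expect_equal(nsvd(diag(c(3, 1)), 0), 0.75, tolerance = 1e-12)
  # all-zero window: rank-0 convention
  expect_equal(nsvd(matrix(0, 5, 5), 37), 1)
  expect_error(nsvd(matrix(0, 2, 3), 0), "square")
})

test_that("directionality equals the brute-force oracle to 1e-10", {
  set.seed(123)
  worst <- 0
  for (k in 1:200) {
    w <- matrix(runif(100), 10, 10)
    worst <- max(worst, abs(directionality(w) - directionality_ref(w)))
  }
  expect_lt(worst, 1e-10)
})

test_that("directionality separates lines from disorder and disks", {
  # rotation-invariant window (radial disk profile): D would be exactly 0
  # in the continuum; bilinear interpolation leaves a small floor (~0.04)
  d2 <- (matrix(1:11, 11, 11) - 6)^2 + (matrix(1:11, 11, 11, byrow = TRUE) - 6)^2
  disk <- exp(-d2 / (2 * 1.5^2))
  expect_lt(directionality(disk), 0.05)
  # straight line beats matched-energy isotropic noise
  line <- matrix(0, 11, 11); line[6, ] <- 1
  set.seed(5)
  noise <- matrix(runif(121), 11, 11)
  noise <- noise * sqrt(sum(line^2) / sum(noise^2))
  expect_gt(directionality(line), directionality(noise))
  # the disk floor sits far below a line's directionality
  expect_lt(directionality(disk), directionality(line) / 5)
  expect_error(directionality(line, numeric(0)), "theta")
})

test_that("anisotropy and the entropy weighting follow their formulas", {
  expect_equal(anisotropy(0), 100)
  expect_equal(anisotropy(0.99), 1)
  D <- seq(0, 1, by = 0.1)
  expect_true(all(diff(anisotropy(D)) < 0))
  expect_error(anisotropy(-0.1), "non-negative")
  expect_equal(weighted_entropy(0, 5), 0)
  expect_equal(weighted_entropy(3, 2, k = 0), 3)
  expect_equal(weighted_entropy(2, 4, k = 30), 2 * exp(-30 / 4),
               tolerance = 1e-12)
  # high-D (healthy-like) windows are suppressed more than low-D windows
  wt <- function(D) weighted_entropy(1, anisotropy(D))
  expect_lt(wt(0.5), wt(0.05))
  # the offset reading suppresses the other side; both are available
  expect_lt(weighted_entropy(1, anisotropy(0.05), reading = "offset"),
            weighted_entropy(1, anisotropy(0.5), reading = "offset"))
})

test_that("weighted entropy map is consistent, bounded and suppressive", {
  z <- weighted_entropy_map(matrix(0, 40, 40), pixel_size = 0.1)
  expect_true(all(z$E == 0))
  fx <- scene_t1(seed = 7)
  fm <- weighted_entropy_map(fx$map)
  expect_true(all(fm$E <= fm$H + 1e-12))
  expect_true(all(fm$H >= -1e-12))
  expect_true(all(fm$A <= 1 / fm$epsilon + 1e-9, na.rm = TRUE))
  expect_true(all(is.na(fm$A) == !fm$support))
  tm <- fx$scene$truth$tumor_mask
  hm <- fx$scene$truth$healthy_mask
  expect_gt(mean(fm$E[tm]), mean(fm$E[hm]))
  # the map's D agrees with the single-window evaluation on margin-padded
  # patches at sampled pixels
  w <- pactangio:::window_px(fm$window_mm, fm$pixel_size)
  margin <- ceiling(w * (sqrt(2) - 1) / 2) + 1
  off <- (w - 1) / 2 + margin
  set.seed(9)
  px <- fx$map$pixels
  crop <- function(m) m[(margin + 1):(margin + w), (margin + 1):(margin + w)]
  for (k in 1:10) {
    r <- sample(30:170, 1); c <- sample(30:170, 1)
    patch <- px[(r - off):(r + off), (c - off):(c + off)]
    prof <- vapply(seq(0, 170, 10), function(t) {
      rot <- if (t == 0) patch else rotate_ref(patch, t)
      s <- svd(crop(rot))$d
      if (sum(s) <= 0) 1 else s[1] / sum(s)
    }, numeric(1))
    expect_equal(fm$D[r, c], max(prof) - min(prof), tolerance = 1e-10)
  }
})

test_that("a fully directional scene is almost entirely suppressed", {
  # axis-aligned separated straight vessels; border windows excluded (their
  # zero-filled truncation is not a vessel feature)
  n <- 200
  x <- (seq_len(n) - (n + 1) / 2) * 0.1
  img <- matrix(0, n, n)
  for (xk in seq(-14, 14, by = 2))
    img <- pmax(img, matrix(exp(-(x - xk)^2 / (2 * 0.15^2)), n, n))
  fm <- weighted_entropy_map(map_image(img, 0.1))
  interior <- matrix(FALSE, n, n); interior[10:(n - 9), 10:(n - 9)] <- TRUE
  expect_lte(max(fm$E[interior]), 0.01 * max(fm$H[interior]))
})

test_that("tumor segmentation keeps the largest suprathreshold component", {
  E <- matrix(0, 50, 50)
  E[5:16, 5:14] <- 10    # 120 px blob
  E[30:38, 30:34] <- 10  # 45 px blob
  seg <- segment_tumor(E, sd_multiplier = 1.4)
  expect_true(all(seg$mask[5:16, 5:14]))
  expect_false(any(seg$mask[30:38, 30:34]))
  expect_equal(sum(seg$mask), 120)
  expect_warning(s0 <- segment_tumor(matrix(1, 10, 10)), "empty")
  expect_false(any(s0$mask))
})

test_that("segmentation recovers the tumor and releases it after response", {
  fx <- scene_t1(seed = 7)
  fm <- weighted_entropy_map(fx$map)
  seg <- segment_tumor(fm)
  tm <- fx$scene$truth$tumor_mask
  expect_gt(pactangio:::dice(seg$mask, tm), 0.5)
  idx <- which(seg$mask, arr.ind = TRUE)
  ctr <- colMeans(idx)                       # centroid in px
  true_ctr <- c(100.5, 100.5)
  expect_lt(sqrt(sum((ctr - true_ctr)^2)) * 0.1, 4)  # within tumor radius
  # complete-response scene: any detected component barely overlaps the
  # former tumor
  sc1 <- make_vascular_scene(vascular_scene_spec(seed = 7, response_fraction = 1))
  pm1 <- preprocess_map(sc1$map, background_region = sc1$truth$background_mask)
  seg1 <- suppressWarnings(segment_tumor(weighted_entropy_map(pm1)))
  if (any(seg1$mask)) expect_lt(pactangio:::dice(seg1$mask, tm), 0.1)
})

test_that("tumor dimensions follow the principal-axis convention", {
  # 10 mm x 5 mm rectangle at 0.1 mm/px
  m <- matrix(FALSE, 200, 200); m[51:150, 101:150] <- TRUE
  d <- tumor_dimensions(m, pixel_size = 0.1)
  expect_equal(d$la_cm, 1.0, tolerance = 0.01)
  expect_equal(d$sa_cm, 0.5, tolerance = 0.01)
  # single pixel
  m1 <- matrix(FALSE, 10, 10); m1[5, 5] <- TRUE
  d1 <- tumor_dimensions(m1, pixel_size = 0.1)
  expect_equal(d1$la_cm, 0.01)
  expect_equal(d1$sa_cm, 0.01)
  # circle: LA = SA = diameter
  d2g <- (matrix(1:200, 200, 200) - 100)^2 +
    (matrix(1:200, 200, 200, byrow = TRUE) - 100)^2
  dc <- tumor_dimensions(d2g <= 40^2, pixel_size = 0.1)
  expect_equal(dc$la_cm, 0.8, tolerance = 0.03)
  expect_equal(dc$sa_cm, 0.8, tolerance = 0.03)
  # slice stack: elevational extent and summed volume
  slices <- list(m, m, matrix(FALSE, 200, 200))
  ds <- tumor_dimensions(m, pixel_size = 0.1, per_slice_masks = slices,
                         elevational_spacing = 1)
  expect_equal(ds$el_cm, 0.2)
  expect_equal(ds$volume_cm3, 2 * (10 * 5) * 1 / 1000)
  expect_equal(ds$method, "slices")
  expect_error(tumor_dimensions(matrix(FALSE, 5, 5), 0.1), "empty")
})

test_that("modulation enhances lesions while retaining background", {
  px <- matrix(runif(400, 0.1, 1), 20, 20)
  m <- map_image(px, 0.1)
  # M_ae = 0 everywhere: output proportional to beta * M_PA, i.e. the
  # normalized angiogram
  out <- modulate(m, matrix(0, 20, 20))
  expect_equal(out$pixels, px / max(px), tolerance = 1e-12)
  # tumor-to-background weighting ratio (1 + beta) / beta
  E <- matrix(0, 20, 20); E[1:10, ] <- 1
  flat <- map_image(matrix(1, 20, 20), 0.1)
  out2 <- modulate(flat, E, beta = 0.07)
  expect_equal(out2$pixels[1, 1] / out2$pixels[15, 15], 1.07 / 0.07,
               tolerance = 1e-9)
  # beta -> infinity recovers the plain angiogram
  out3 <- modulate(m, E[1:20, 1:20] * 0 + c(1, 0), beta = 1e9)
  expect_equal(out3$pixels, px / max(px), tolerance = 1e-6)
  expect_error(modulate(m, matrix(0, 5, 5)), "shape")
})
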