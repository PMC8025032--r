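# Brute-force oracle: count connected chains (8-connectivity) of a skeleton
# after removing junction pixels, via BFS.
count_chains_ref <- function(skel, junctions) {
  m <- skel & !junctions
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    if (lab[idx[k, 1], idx[k, 2]] > 0) next
    nxt <- nxt + 1L
    queue <- list(idx[k, ])
    lab[idx[k, 1], idx[k, 2]] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            m[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  nxt
}

test_that("a single straight vessel yields one segment and no junction", {
  img <- straight_vessel_image(n = 60, x0_px = 30.5, sigma_px = 1.5)
  sk <- extract_skeleton(img, pixel_size = 0.1)
  expect_equal(sk$n_segments, 1)
  expect_false(any(sk$junctions))
  # skeleton is invariant to global intensity scaling
  sk2 <- extract_skeleton(img * 137, pixel_size = 0.1)
  expect_identical(sk$skeleton, sk2$skeleton)
})

test_that("a plus-shaped crossing splits into four segments at one junction", {
  img <- matrix(0, 41, 41)
  img[21, 5:37] <- 1
  img[5:37, 21] <- 1
  sk <- extract_skeleton(img, pixel_size = 0.1)
  expect_equal(sk$n_segments, 4)
  jidx <- which(sk$junctions, arr.ind = TRUE)
  expect_gt(nrow(jidx), 0)
  expect_true(all(abs(jidx[, 1] - 21) <= 1 & abs(jidx[, 2] - 21) <= 1))
  expect_equal(sk$n_segments, count_chains_ref(sk$skeleton, sk$junctions))
})

test_that("short spurs are filtered while long vessels are kept", {
  img <- matrix(0, 41, 41)
  img[21, 3:39] <- 1        # long vessel
  img[19:20, 10] <- 1       # 2-px spur
  sk <- split_and_filter(extract_skeleton(img, pixel_size = 0.1),
                         min_length = 3)
  expect_equal(sk$n_segments, 2)   # spur removed; vessel split at the spur
  expect_true(all(label_lengths <- tabulate(sk$segments[sk$segments > 0]) >= 3))
  # graphs with all segments >= min_length are unchanged
  img2 <- matrix(0, 41, 41); img2[21, 3:39] <- 1
  sk2 <- extract_skeleton(img2, pixel_size = 0.1)
  expect_equal(split_and_filter(sk2)$n_segments, sk2$n_segments)
})

test_that("segment counts match the brute-force chain oracle on random scenes", {
  for (s in c(2, 9)) {
    fx <- make_vascular_scene(vascular_scene_spec(seed = s))
    pm <- preprocess_map(fx$map, background_region = fx$truth$background_mask)
    sk <- extract_skeleton(pm)
    expect_equal(sk$n_segments, count_chains_ref(sk$skeleton, sk$junctions))
  }
})

test_that("density is segments per window area with clipped borders", {
  empty <- extract_skeleton(matrix(0, 50, 50), pixel_size = 0.1)
  expect_true(all(density_map(empty)$values == 0))
  # one straight segment through the window center: window 2 mm at 0.1 mm/px
  # is 21 px, area 4.41 mm^2
  img <- matrix(0, 61, 61); img[31, 5:57] <- 1
  sk <- split_and_filter(extract_skeleton(img, pixel_size = 0.1))
  dm <- density_map(sk, window = 2)
  w_px <- 21
  expect_equal(dm$values[31, 31], 1 / (w_px^2 * 0.01), tolerance = 1e-12)
  # at the image corner the clipped area is used
  corner_area <- (11 * 11) * 0.01
  expect_equal(dm$values[1, 1], 0)
  expect_error(density_map(sk, window = 0.1), "window")
})

test_that("density values equal a brute-force recount at sampled pixels", {
  fx <- scene_t1(seed = 7)
  sk <- split_and_filter(extract_skeleton(fx$map))
  dm <- density_map(sk, window = 2)
  w <- pactangio:::window_px(2, sk$pixel_size)
  h <- (w - 1) / 2
  set.seed(42)
  n <- nrow(sk$segments)
  for (k in 1:100) {
    r <- sample(seq_len(n), 1); c <- sample(seq_len(n), 1)
    rs <- max(1, r - h):min(n, r + h)
    cs <- max(1, c - h):min(n, c + h)
    ids <- unique(as.vector(sk$segments[rs, cs])); ids <- ids[ids > 0]
    area <- length(rs) * length(cs) * sk$pixel_size^2
    expect_equal(dm$values[r, c], length(ids) / area, tolerance = 1e-10)
  }
})

test_that("adding a segment never decreases density", {
  img <- matrix(0, 61, 61); img[31, 5:57] <- 1
  sk1 <- split_and_filter(extract_skeleton(img, pixel_size = 0.1))
  img2 <- img; img2[10, 5:57] <- 1
  sk2 <- split_and_filter(extract_skeleton(img2, pixel_size = 0.1))
  expect_true(all(density_map(sk2)$values >= density_map(sk1)$values - 1e-12))
})

test_that("density map is translation-equivariant with the skeleton", {
  img <- matrix(0, 80, 80); img[30, 10:70] <- 1; img[50, 20:60] <- 1
  shift <- function(m, d) rbind(matrix(0, d, ncol(m)), m[1:(nrow(m) - d), ])
  d1 <- density_map(split_and_filter(extract_skeleton(img, pixel_size = 0.1)))
  d2 <- density_map(split_and_filter(extract_skeleton(shift(img, 5),
                                                      pixel_size = 0.1)))
  interior <- 20:60
  expect_equal(d2$values[interior + 5, interior], d1$values[interior, interior],
               tolerance = 1e-12)
})

test_that("high-density highlighting enforces threshold and minimum area", {
  fx <- scene_t1(seed = 7)
  sk <- split_and_filter(extract_skeleton(fx$map))
  dm <- density_map(sk)
  expect_false(any(highlight_regions(dm, threshold = max(dm$values) + 1)))
  # a suprathreshold blob smaller than min_area is rejected
  fake <- dm
  fake$values <- matrix(0, 200, 200)
  fake$values[100:117, 100:116] <- 3      # 18 x 17 px ~ 3.06 mm^2 < 4 mm^2
  expect_false(any(highlight_regions(fake, threshold = 2.5, min_area = 4)))
  fake$values[100:120, 100:120] <- 3      # 4.41 mm^2 >= 4 mm^2
  expect_true(any(highlight_regions(fake, threshold = 2.5, min_area = 4)))
  # on the baseline tumor scene the highlighted region localizes the tumor:
  # the majority of the tumor is highlighted while the healthy annulus is
  # mostly not. The threshold is scene-calibrated (1.5x the healthy-region
  # mean), the same move the clinical maps use to suppress healthy-region
  # enhancement.
  tm <- fx$scene$truth$tumor_mask; hm <- fx$scene$truth$healthy_mask
  hl <- highlight_regions(dm, threshold = 1.5 * mean(dm$values[hm]),
                          min_area = 4)
  expect_gt(mean(hl[tm]), 0.5)
  expect_gt(mean(hl[tm]), 2 * mean(hl[hm]))
})

test_that("ROI-vs-healthy density ordering is robust to the window size", {
  fx <- scene_t1(seed = 7)
  sk <- split_and_filter(extract_skeleton(fx$map))
  tm <- fx$scene$truth$tumor_mask
  hm <- fx$scene$truth$healthy_mask
  for (w in 1:4) {
    dm <- density_map(sk, window = w)
    expect_gt(mean(dm$values[tm]), mean(dm$values[hm]))
  }
})
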