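# Small single-disk phantom helper: negligible background absorption so the
# channel data is dominated by one absorber.
single_disk_phantom <- function(diameter = 0.3, center_radius = 5.2,
                                breast_radius = 12) {
  make_inclusion_phantom(diameters = diameter, ring_radius = center_radius,
                         breast_radius = breast_radius,
                         background_props = optical_properties(1e-9, 5),
                         duplicate_smallest_at_center = FALSE)
}

test_that("geometry invariants are enforced", {
  expect_error(ring_array_geometry(n_elements = 2), "n_elements")
  g <- ring_array_geometry()
  expect_equal(g$n_samples, 4000)
  expect_equal(length(g$elem_x), 512)
  expect_equal(sqrt(g$elem_x^2 + g$elem_y^2), rep(110, 512), tolerance = 1e-9)
})

test_that("a central absorber peaks at radius over speed of sound", {
  # diameter chosen so the N-wave edges fall between time samples (an edge
  # exactly on a sample is included or not depending on rounding)
  ph <- single_disk_phantom(diameter = 0.74, center_radius = 1e-9)
  ph$inclusions[[1]]$center <- c(0, 0)
  ch <- forward_simulate(ph, fluence = 1, impulse_response = "none")
  t_us <- (which.max(abs(ch$traces[1, ])) - 1) * ch$dt
  expect_equal(t_us, 110 / 1.5, tolerance = 0.02)
  # all elements see the same signal (central source)
  expect_lt(max(abs(sweep(ch$traces, 2, ch$traces[1, ]))), 1e-12)
})

test_that("forward model is linear and vanishes without fluence", {
  ph <- single_disk_phantom()
  ch0 <- forward_simulate(ph, fluence = 0, impulse_response = "none")
  expect_true(all(ch0$traces == 0))
  ch1 <- forward_simulate(ph, fluence = 1, impulse_response = "none")
  ch2 <- forward_simulate(ph, fluence = 2, impulse_response = "none")
  expect_equal(ch2$traces, 2 * ch1$traces, tolerance = 1e-12)
})

test_that("rotating the phantom by one element pitch permutes channels", {
  ph <- single_disk_phantom(diameter = 1)
  ch <- forward_simulate(ph, fluence = 1, impulse_response = "none")
  g <- ch$geometry
  pitch <- 2 * pi / g$n_elements
  ctr <- ph$inclusions[[1]]$center
  ph2 <- ph
  ph2$inclusions[[1]]$center <- c(cos(pitch) * ctr[1] - sin(pitch) * ctr[2],
                                  sin(pitch) * ctr[1] + cos(pitch) * ctr[2])
  ch2 <- forward_simulate(ph2, fluence = 1, impulse_response = "none")
  shifted <- rbind(ch2$traces[2:g$n_elements, ], ch2$traces[1, , drop = FALSE])
  expect_lt(max(abs(shifted - ch$traces)), 1e-12 + 1e-9 * max(abs(ch$traces)))
})

test_that("noise injection is seeded and band-pass preserves determinism", {
  ph <- single_disk_phantom()
  a <- forward_simulate(ph, fluence = 1, noise_sigma = 1e-5, seed = 3)
  b <- forward_simulate(ph, fluence = 1, noise_sigma = 1e-5, seed = 3)
  expect_identical(a$traces, b$traces)
  c_ <- forward_simulate(ph, fluence = 1, noise_sigma = 1e-5, seed = 4)
  expect_false(identical(a$traces, c_$traces))
})

test_that("UBP maps zero traces to a zero image and is linear", {
  ph <- single_disk_phantom()
  ch <- forward_simulate(ph, fluence = 1, impulse_response = "none")
  ch0 <- ch; ch0$traces[] <- 0
  grid <- recon_grid(c(2, 8), c(-3, 3), 0.1)
  expect_true(all(ubp_reconstruct(ch0, grid)$pixels == 0))
  # two well-separated absorbers reconstruct as the sum of the singles
  ph_b <- single_disk_phantom(diameter = 0.5)
  ph_b$inclusions[[1]]$center <- c(-4, -3)
  ch_b <- forward_simulate(ph_b, fluence = 1, impulse_response = "none")
  ch_ab <- ch; ch_ab$traces <- ch$traces + ch_b$traces
  img_ab <- ubp_reconstruct(ch_ab, grid)$pixels
  img_sum <- ubp_reconstruct(ch, grid)$pixels + ubp_reconstruct(ch_b, grid)$pixels
  expect_equal(img_ab, img_sum, tolerance = 1e-10)
})

test_that("UBP localizes a point-like absorber within one pixel", {
  for (ctr in list(c(5.2, 0), c(-3.14, 7.05))) {
    ph <- single_disk_phantom(diameter = 0.3,
                              center_radius = sqrt(sum(ctr^2)))
    ph$inclusions[[1]]$center <- ctr
    ch <- forward_simulate(ph, fluence = 1, impulse_response = "none")
    grid <- recon_grid(ctr[1] + c(-3, 3), ctr[2] + c(-3, 3), 0.1)
    img <- ubp_reconstruct(ch, grid)
    i <- arrayInd(which.max(img$pixels), dim(img$pixels))
    expect_lt(abs(grid$x[i[1]] - ctr[1]), 0.1 + 1e-9)
    expect_lt(abs(grid$y[i[2]] - ctr[2]), 0.1 + 1e-9)
  }
})

test_that("pixels beyond the record window raise a coverage warning", {
  ph <- single_disk_phantom()
  g <- ring_array_geometry(record_window = 30)  # 45 mm reach only
  ch <- forward_simulate(ph, fluence = 1, geometry = g,
                         impulse_response = "none")
  grid <- recon_grid(c(-5, 5), c(-5, 5), 0.5)
  expect_warning(ubp_reconstruct(ch, grid), "coverage")
  expect_error(ubp_reconstruct(ch, recon_grid(c(100, 115), c(-5, 5), 0.5)),
               "inside the ring")
})

test_that("depth compensation applies exp(0.6 depth) and inverts decay", {
  img <- matrix(runif(100), 10, 10)
  expect_equal(depth_compensate(img, 0), img)
  expect_equal(depth_compensate(img, 1), img * exp(0.6), tolerance = 1e-12)
  z <- matrix(seq(0, 3, length.out = 10), 10, 10)
  decayed <- exp(-0.6 * z)
  flat <- depth_compensate(decayed, z)
  expect_equal(max(flat) - min(flat), 0, tolerance = 1e-12)
})

test_that("detection requires a background mask and ignores blank images", {
  grid <- recon_grid(c(-5, 5), c(-5, 5), 0.1)
  blank <- map_image(matrix(0, 100, 100), 0.1)
  bg <- matrix(FALSE, 100, 100); bg[1:10, 1:10] <- TRUE
  expect_error(detect_inclusions(blank, grid, matrix(FALSE, 100, 100)),
               "background_mask")
  expect_equal(nrow(detect_inclusions(blank, grid, bg)), 0)
})

test_that("simulate-reconstruct recovers geometry and relative amplitude", {
  res <- phantom_detection_run()
  m <- res$matches
  expect_equal(nrow(m), 7)
  expect_true(all(m$offset_mm < 0.3))
  # equal-absorption inclusions >= 1 mm reconstruct with similar amplitude:
  # mean reconstructed amplitude over each (eroded) true disk within 10%
  grid <- res$grid
  X <- matrix(grid$x, length(grid$x), length(grid$y))
  Y <- matrix(grid$y, length(grid$x), length(grid$y), byrow = TRUE)
  amps <- vapply(res$phantom$inclusions, function(inc) {
    d <- sqrt((X - inc$center[1])^2 + (Y - inc$center[2])^2)
    mean(res$image$pixels[d <= inc$diameter / 2 - grid$pixel_size])
  }, numeric(1))
  expect_lt(max(amps) / min(amps), 1.10)
})
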