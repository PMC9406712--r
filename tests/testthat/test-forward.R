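test_that("phase projection matches the closed-form chord integral", {
  # uniform sphere: central-ray phase = (2 pi / lambda) * dn * 2R = 2.060 rad
  sp <- phantom_spec(grid_size = 96L, voxel_size = 0.1, cell_radius = 4,
                     ri_range = c(1.354, 1.354), edge_width = 0.01, seed = 1L)
  su <- generate_phantom(sp)
  pj <- project_phase(su, 0)
  expect_equal(max(pj$phase), 2 * pi / 0.488 * 0.02 * 8, tolerance = 0.02)
  # zero-contrast volume projects to identically zero phase
  flat <- tomogram(array(1.334, c(16, 16, 16)), 0.1)
  expect_true(all(project_phase(flat, 30)$phase == 0))
  expect_error(project_phase(su, NaN), "finite")
})

test_that("projections are 360-degree periodic and conserve mass", {
  ph <- generate_phantom(small_spec(seed = 2L))
  a <- project_phase(ph, 25)$phase
  b <- project_phase(ph, 25 + 360)$phase
  expect_equal(a, b, tolerance = 1e-9)
  # Radon mass conservation across angles (interpolation tolerance)
  masses <- vapply(c(0, 17, 45, 122.5, 301), function(th)
    sum(project_phase(ph, th)$phase), numeric(1))
  expect_lt(max(abs(masses - masses[1])) / masses[1], 1e-3)
})

test_that("synthesized holograms are non-negative with the carrier at the
           requested spectral location", {
  set.seed(1)
  n <- 128L
  U <- complex_field(exp(1i * matrix(0, n, n)), 0.1)
  carrier <- c(0.25, 0.25) / sqrt(2)
  h <- synthesize_hologram(U, carrier)
  expect_gte(min(h$intensity), 0)
  S <- Mod(fft(h$intensity))
  S[1, 1] <- 0                       # drop DC, find the +1/-1 order pair
  peak <- which(S == max(S), arr.ind = TRUE)[1, ]
  fpk <- (peak - 1) / n
  fpk <- ifelse(fpk > 0.5, fpk - 1, fpk)
  # peak lies within a spectral bin of the requested carrier
  expect_lt(max(abs(unname(sort(abs(fpk))) - sort(abs(carrier)))), 1.5 / n)
})

test_that("demodulation of a synthesized hologram recovers the object phase", {
  n <- 128L
  xg <- matrix(seq(-1, 1, length.out = n), n, n)
  phase <- 1.2 * exp(-(xg^2 + t(xg)^2) / 0.18)
  U <- complex_field(exp(1i * phase), 0.1)
  # carrier on an exact spectral bin: the round trip is then ramp-free
  h <- synthesize_hologram(U, carrier = c(24, 24) / n)
  u2 <- demodulate(h)
  inner <- 17:112
  rec <- Arg(u2$field)[inner, inner]
  expect_lt(rmse(depiston(rec, phase[inner, inner]), phase[inner, inner]),
            1e-2)
})

test_that("hologram synthesis rejects carriers below the separation bound", {
  set.seed(7)
  n <- 64L
  phase <- matrix(rnorm(n * n), n, n)
  phase <- Re(fft(fft(phase) * outer(exp(-8 * fft_freq_test(n)^2),
                                     exp(-8 * fft_freq_test(n)^2)),
                  inverse = TRUE)) / n^2
  U <- complex_field(exp(1i * 3 * phase / max(abs(phase))), 0.1)
  expect_error(synthesize_hologram(U, carrier = c(0.01, 0.01)), "carrier")
})

test_that("rolling sequence geometry matches its ground truth", {
  sp <- phantom_spec(grid_size = 24L, voxel_size = 0.2, cell_radius = 1.8,
                     seed = 4L)
  fl <- flow_spec(translation_per_frame = 1.0, rotation_per_frame = 45,
                  n_frames = 8, noise_sigma = 0)
  seq1 <- simulate_rolling_sequence(sp, fl, frame_size = 96L)
  expect_equal(seq1$truth$angles[8], 315)
  # full-turn construction: frame N completes 360 degrees
  fl2 <- flow_spec(translation_per_frame = 0.5, rotation_per_frame = 40,
                   n_frames = 10, noise_sigma = 0)
  seq2 <- simulate_rolling_sequence(sp, fl2, frame_size = 96L)
  expect_equal(seq2$truth$angles[10], 360)
  # static flow with zero noise: all frames identical
  fl0 <- flow_spec(translation_per_frame = 0, rotation_per_frame = 0,
                   n_frames = 3, noise_sigma = 0)
  seq0 <- simulate_rolling_sequence(sp, fl0, frame_size = 64L)
  expect_equal(seq0$holograms[[1]]$intensity, seq0$holograms[[3]]$intensity)
  # trajectory leaving the field of view names the first offending frame
  flbad <- flow_spec(translation_per_frame = 5, rotation_per_frame = 10,
                     n_frames = 12, noise_sigma = 0)
  expect_error(simulate_rolling_sequence(sp, flbad, frame_size = 64L),
               "frame [0-9]+")
})

test_that("rendered centroid track is collinear with the tilt direction", {
  sp <- phantom_spec(grid_size = 24L, voxel_size = 0.2, cell_radius = 1.8,
                     seed = 4L)
  fl <- flow_spec(tilt_angle = 45, translation_per_frame = 1.0,
                  rotation_per_frame = 0, n_frames = 11, noise_sigma = 0)
  seq1 <- simulate_rolling_sequence(sp, fl, frame_size = 128L,
                                    aberration_peak = 0)
  qpms <- lapply(seq_along(seq1$truth$phases), function(i)
    qpm(seq1$truth$phases[[i]], sp$voxel_size, i))
  tr <- track_centroids(qpms)
  d <- tr$track
  # spacing 1 um / 0.2 um = 5 px per frame, within 0.2 px
  steps <- sqrt(diff(d$x)^2 + diff(d$y)^2) / sp$voxel_size
  expect_lt(max(abs(steps - 5)), 0.2)
  # direction 45 degrees from the y axis, within 1 degree
  ang <- atan2(d$x[-1], d$y[-1]) * 180 / pi
  expect_lt(max(abs(ang - 45)), 1)
  # collinearity of the track
  expect_gt(summary(lm(d$y ~ d$x))$r.squared, 0.999)
})
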