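mk_blob_qpm <- function(n, cr, cc, sigma = 3, amp = 2, px = 0.1, idx = 1L) {
  ph <- amp * exp(-((row(matrix(0, n, n)) - cr)^2 +
                    (col(matrix(0, n, n)) - cc)^2) / (2 * sigma^2))
  qpm(ph, px, idx)
}

test_that("centroid tracking follows a diagonal translation with sub-pixel
           accuracy", {
  n <- 96L
  qpms <- lapply(0:5, function(k)
    mk_blob_qpm(n, 20 + 5 * k / sqrt(2), 20 + 5 * k / sqrt(2), idx = k + 1L))
  tr <- track_centroids(qpms)
  steps <- sqrt(diff(tr$track$x)^2 + diff(tr$track$y)^2) / 0.1
  expect_lt(max(abs(steps - 5)), 0.2)
  ang <- atan2(tr$track$x[-1], tr$track$y[-1]) * 180 / pi
  expect_lt(max(abs(ang - 45)), 1)
  expect_equal(tr$track$l[1], 0)
  expect_equal(tr$track$l, sqrt(tr$track$x^2 + tr$track$y^2))
})

test_that("tracking a static sequence stays on the frame-1 centroid and
           empty frames fail", {
  qpms <- lapply(1:4, function(k) mk_blob_qpm(64L, 30, 25, idx = k))
  tr <- track_centroids(qpms)
  expect_lt(max(tr$track$l) / 0.1, 0.2)
  flat <- lapply(1:2, function(k) qpm(matrix(0, 32, 32), 0.1, k))
  expect_error(track_centroids(flat), "frame 1")
  # two well-separated qualifying blobs are ambiguous
  two <- mk_blob_qpm(96L, 24, 24)
  two$phase <- two$phase + mk_blob_qpm(96L, 72, 72)$phase
  expect_error(track_centroids(list(two)), "components")
})

test_that("TSI vanishes for identical or offset maps and grows for
           uncorrelated ones", {
  set.seed(5)
  a <- qpm(matrix(rnorm(32 * 32), 32, 32), 0.1)
  expect_equal(tamura_similarity_index(a, a), 0)
  b <- a; b$phase <- a$phase + 1.7          # constant offset is removed
  expect_lt(tamura_similarity_index(a, b), 1e-9)
  c2 <- qpm(matrix(rnorm(32 * 32), 32, 32), 0.1)
  expect_gt(tamura_similarity_index(a, c2),
            tamura_similarity_index(a, a))
  expect_error(tamura_similarity_index(a, qpm(matrix(0, 8, 8), 0.1)),
               "shape")
})

test_that("full-rotation search finds the first period of a periodic
           sequence", {
  # compact object orbiting with period 12: frames 13 and 25 exactly repeat
  # frame 1; the earliest full-turn frame must be returned on the tie
  blob <- function(ang) {
    cx <- 24 + 10 * cos(ang); cy <- 24 + 10 * sin(ang)
    outer(seq_len(48), seq_len(48), function(i, j)
      2 * exp(-((i - cx)^2 + (j - cy)^2) / 18))
  }
  qpms <- lapply(seq_len(30), function(k)
    qpm(blob(2 * pi * (k - 1) / 12), 0.1, k))
  f <- find_full_rotation(qpms, min_lag = 6L)
  expect_equal(as.integer(f), 13L)
  expect_equal(as.integer(find_full_rotation(qpms, search_window = 20L)), 20L)
  expect_error(find_full_rotation(qpms, search_window = integer(0)), "empty")
})

test_that("angle assignment is proportional to displacement and drops frames
           beyond the full turn", {
  df <- data.frame(frame = 1:6, x = c(0, 6, 12, 30, 36, 60),
                   y = c(0, 8, 16, 40, 48, 80))
  df$l <- sqrt(df$x^2 + df$y^2)
  tr <- structure(list(track = df, centroid_px = cbind(df$y, df$x),
                       pixel_pitch = 0.1, frame_of_360 = 6L,
                       L360 = df$l[6]),
                  class = "rolling_track")
  ang <- assign_angles(tr)
  expect_equal(ang$angles$theta_deg[1], 0)
  # centroid at (30, 40) um with L360 = 100 um -> l = 50 -> theta = 180
  expect_equal(ang$angles$theta_deg[4], 180)
  # displacement at half of L360 maps to the 180-degree midpoint
  expect_equal(ang$angles$theta_deg[5], 360 * 60 / 100)
  expect_equal(ang$L360, 100)
  expect_equal(nrow(ang$angles), 6)
  # monotone displacement gives non-decreasing angles
  expect_true(all(diff(ang$angles$theta_deg) >= 0))
  # rigid rotation of the coordinate frame leaves angles unchanged
  rot <- pi / 5
  df2 <- df
  df2$x <- cos(rot) * df$x - sin(rot) * df$y
  df2$y <- sin(rot) * df$x + cos(rot) * df$y
  df2$l <- sqrt(df2$x^2 + df2$y^2)
  tr2 <- tr; tr2$track <- df2; tr2$L360 <- df2$l[6]
  expect_equal(assign_angles(tr2)$angles$theta_deg, ang$angles$theta_deg,
               tolerance = 1e-12)
  trbad <- tr; trbad$track$l <- rep(0, 6); trbad$L360 <- 0
  expect_error(assign_angles(trbad), "L360")
})
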