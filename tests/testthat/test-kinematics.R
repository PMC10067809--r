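test_that("vcl matches closed forms on hand-constructed tracks", {
  straight <- tibble::tibble(frame = 0:2, x_um = c(0, 1, 2), y_um = 0)
  expect_equal(vcl(straight, fps = 60), 60)          # 2 um in 2/60 s
  zig <- tibble::tibble(frame = 0:2, x_um = c(0, 1, 2), y_um = c(0, 1, 0))
  expect_equal(vcl(zig, fps = 60), 2 * sqrt(2) * 30) # 84.8528...
  expect_equal(vcl(zig, fps = 60), 84.8528, tolerance = 1e-5)
})

test_that("vcl equals the naive loop oracle on a long zigzag track", {
  set.seed(41)
  tr <- random_track(180)
  expect_equal(vcl(tr, fps = 60), naive_vcl(tr, fps = 60))
})

test_that("vcl is invariant under rotation and translation", {
  set.seed(42)
  tr <- random_track(60)
  th <- 0.73
  rot <- tibble::tibble(
    frame = tr$frame,
    x_um = cos(th) * tr$x_um - sin(th) * tr$y_um + 12.5,
    y_um = sin(th) * tr$x_um + cos(th) * tr$y_um - 3.1
  )
  expect_equal(vcl(rot, fps = 60), vcl(tr, fps = 60))
})

test_that("dropped frames lengthen elapsed time, not the path rate", {
  full <- tibble::tibble(frame = 0:4, x_um = 0:4, y_um = 0)
  gap <- tibble::tibble(frame = c(0, 1, 4), x_um = c(0, 1, 4), y_um = 0)
  expect_equal(vcl(gap, fps = 60), vcl(full, fps = 60))
})

test_that("vap equals vcl on straight tracks and for window 1", {
  straight <- tibble::tibble(frame = 0:9, x_um = 0:9, y_um = 2 * (0:9))
  for (w in c(1, 3, 5, 9)) {
    expect_equal(vap(straight, fps = 60, window = w), vcl(straight, fps = 60))
  }
  set.seed(43)
  tr <- random_track(50)
  expect_equal(vap(tr, fps = 60, window = 1), vcl(tr, fps = 60))
})

test_that("vap on the 5-point zigzag matches the reference smoother and is < vcl", {
  zig <- tibble::tibble(frame = 0:4, x_um = 0:4, y_um = c(0, 1, 0, 1, 0))
  v <- vap(zig, fps = 60, window = 3)
  expect_equal(v, naive_vap(zig, fps = 60, window = 3))
  expect_lt(v, vcl(zig, fps = 60))
})

test_that("vap matches the reference smoother on random tracks and windows", {
  set.seed(44)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    w <- sample(seq(1, min(n, 11), by = 2), 1)
    tr <- random_track(n)
    expect_equal(vap(tr, fps = 60, window = w),
                 naive_vap(tr, fps = 60, window = w))
  }
})

test_that("degenerate inputs error cleanly", {
  one_pt <- tibble::tibble(frame = 0, x_um = 0, y_um = 0)
  expect_error(vcl(one_pt, 60), "degenerate")
  tr <- random_track(10)
  expect_error(vap(tr, 60, window = 4), "odd")
  expect_error(vap(tr, 60, window = 11), "exceeds")
  expect_error(vcl(tr, fps = 0), "fps")
  bad <- tibble::tibble(frame = c(0, 2, 1), x_um = 0:2, y_um = 0)
  expect_error(vcl(bad, 60), "increasing")
})

test_that("subsample summaries are unweighted means over tracks", {
  t1 <- dplyr::mutate(random_track(30), track_id = 1)
  # scale a copy so its speed doubles
  t2 <- dplyr::mutate(t1, track_id = 2, x_um = 2 * x_um, y_um = 2 * y_um)
  s <- summarize_subsample(dplyr::bind_rows(t1, t2), fps = 60, min_frames = 30)
  expect_equal(s$n_tracks, 2)
  expect_equal(s$mean_vcl, 1.5 * vcl(t1, 60))
  one <- summarize_subsample(t1, fps = 60, min_frames = 30)
  expect_equal(one$mean_vcl, vcl(t1, 60))
})

test_that("male-level trait is the mean of subsample means, not the pooled mean", {
  set.seed(45)
  # subsample 1: one slow track; subsample 2: three fast tracks
  slow <- dplyr::mutate(random_track(30), male_id = "m", subsample = 1, track_id = 1)
  fast <- purrr::map_dfr(2:4, function(k) {
    dplyr::mutate(random_track(30), x_um = 3 * x_um, y_um = 3 * y_um,
                  male_id = "m", subsample = 2, track_id = k)
  })
  tracks <- dplyr::bind_rows(slow, fast)
  tv <- track_velocities(tracks, fps = 60, min_frames = 30)
  unweighted <- mean(tapply(tv$vcl, tv$subsample, mean))
  pooled <- mean(tv$vcl)
  m <- summarize_male(tracks, fps = 60, min_frames = 30)
  expect_equal(m$vcl_mean, unweighted)
  expect_false(isTRUE(all.equal(unweighted, pooled)))
  expect_equal(m$n_tracks, 4)
})

test_that("tracks below the minimum length are excluded", {
  long <- dplyr::mutate(random_track(40), track_id = 1)
  short <- dplyr::mutate(random_track(10), track_id = 2)
  tv <- track_velocities(dplyr::bind_rows(long, short), min_frames = 30)
  expect_equal(nrow(tv), 1)
  expect_equal(tv$track_id, 1)
})
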