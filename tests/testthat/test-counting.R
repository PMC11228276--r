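test_that("dark-frame calibration recovers offset and sigma maps within CLT bounds", {
  cam <- tiny_camera(rows = 24, cols = 24, read_noise = 5, offset = 100)
  dark <- simulate_dark_frames(cam, 1000, seed = 21)
  cal <- calibrate_camera(dark, k = 5)
  expect_true(all(abs(cal$offset - 100) < 0.8))
  expect_true(all(abs(cal$sigma - 5) < 0.8))
  expect_equal(sum(cal$hot), 0)

  # zero-noise dark: sigma identically 0, no hot pixels
  cam0 <- tiny_camera(read_noise = 0, offset = 50)
  cal0 <- calibrate_camera(simulate_dark_frames(cam0, 10, seed = 1))
  expect_true(all(cal0$sigma == 0))
  expect_equal(sum(cal0$hot), 0)

  # an injected hot pixel is flagged
  hot <- tibble::tibble(row = 3, col = 7, value = 500)
  camh <- tiny_camera(read_noise = 2, offset = 100, hot = hot)
  calh <- calibrate_camera(simulate_dark_frames(camh, 100, seed = 2))
  expect_true(calh$hot[3, 7])
  expect_equal(sum(calh$hot), 1)

  expect_error(calibrate_camera(
    render_frames(manual_photons(100, 100, 0.1), tiny_ii(), cam,
                  n_frames = 3, seed = 1)), "dark")
})

test_that("detection agrees with a brute-force scan of the acceptance rules", {
  cam <- tiny_camera(rows = 24, cols = 24, read_noise = 2, offset = 100)
  cal <- calibrate_camera(simulate_dark_frames(cam, 300, seed = 3), k = 5)
  crit <- cluster_criteria(ratio_low = 0.05, ratio_high = 0.95,
                           isolation = FALSE)
  set.seed(14)
  for (rep in 1:5) {
    ph <- manual_photons(x = runif(3, 100, 380), y = runif(3, 100, 380),
                         t = rep(0.4, 3), frame = rep(0, 3))
    fs <- render_frames(ph, tiny_ii(gain_mean = 2000), cam, n_frames = 1,
                        seed = rep)
    got <- detect_events(fs$frames[, , 1], cal, crit)
    want <- oracle_detect(fs$frames[, , 1], cal$offset, cal$sigma, 5,
                          0.05, 0.95)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      expect_setequal(paste(got$row, got$col),
                      paste(want[, 1], want[, 2]))
    }
  }
})

test_that("a single bright cluster yields exactly one candidate at the true peak", {
  cam <- tiny_camera(rows = 32, cols = 32, read_noise = 0, offset = 0)
  cal <- calibrate_camera(simulate_dark_frames(cam, 5, seed = 1), k = 5)
  ph <- manual_photons(x = 15.5 * 20, y = 10.5 * 20, t = 0.1)
  fs <- render_frames(ph, tiny_ii(gain_mean = 1000), cam, n_frames = 1, seed = 6)
  cand <- detect_events(fs$frames[, , 1], cal,
                        cluster_criteria(0.02, 0.999))
  expect_equal(nrow(cand), 1)
  expect_equal(unname(c(cand$row, cand$col)), c(11, 16))
})

test_that("false positives on calibrated noise respect the Gaussian tail bound", {
  cam <- tiny_camera(rows = 64, cols = 64, read_noise = 4, offset = 100)
  cal <- calibrate_camera(simulate_dark_frames(cam, 500, seed = 31), k = 5)
  crit <- calibrate_ratio_band(1)
  noise <- simulate_dark_frames(cam, 200, seed = 32)
  ph <- count_frames(noise, cal, crit)
  # expected false events <= n_pixels * frames * P(Z > 5) plus estimation
  # slack; with the shape criterion the observed rate collapses to ~0
  bound <- 64 * 64 * 200 * pnorm(5, lower.tail = FALSE)
  expect_lt(nrow(ph), max(5, 10 * bound))
})

test_that("nearby clusters are both rejected by the isolation rule", {
  cam <- tiny_camera(rows = 24, cols = 24, read_noise = 0, offset = 0)
  cal <- calibrate_camera(simulate_dark_frames(cam, 5, seed = 1), k = 5)
  img <- matrix(0, 24, 24)
  # two clean peaks exactly 2 px apart with admissible neighbour ratios
  img[9:11, 9:11] <- 10
  img[9:11, 11:13] <- 10
  img[10, 10] <- 100
  img[10, 12] <- 100
  cand2 <- detect_events(img, cal, cluster_criteria(0, 1, isolation = FALSE))
  expect_equal(nrow(cand2), 2)
  cand <- detect_events(img, cal, cluster_criteria(0, 1, isolation = TRUE))
  expect_equal(nrow(cand), 0)
  expect_equal(attr(cand, "log")$n[attr(cand, "log")$cause == "isolation"], 2L)
})

test_that("localization is exact for symmetric patches and matches the grid-search oracle", {
  patch <- render_patch(0, 0, 1, 500)
  for (m in c("cog", "gauss")) {
    r <- localize_event(patch, method = m, spot_sigma = 1)
    expect_lt(abs(r$dx), 1e-6)
    expect_lt(abs(r$dy), 1e-6)
  }
  # noiseless offset spot: gauss within 0.02 px of the truth
  patch2 <- render_patch(0.30, -0.20, 1, 500)
  r2 <- localize_event(patch2, method = "gauss", spot_sigma = 1)
  expect_lt(abs(r2$dx - 0.30), 0.02)
  expect_lt(abs(r2$dy + 0.20), 0.02)
  # and agrees with the independent dense grid search
  o <- oracle_localize(patch2, spot_sigma = 1, step = 0.01)
  expect_lt(abs(r2$dx - o$dx), 0.02)
  expect_lt(abs(r2$dy - o$dy), 0.02)
  expect_error(localize_event(matrix(0, 3, 3)), "zero")
})

test_that("localization error stays below 0.1 px RMS at peak SNR 50", {
  set.seed(77)
  n_rep <- 500
  err <- matrix(NA_real_, n_rep, 2)
  err_vs_oracle <- numeric(50)
  for (i in seq_len(n_rep)) {
    dx <- runif(1, -0.5, 0.5); dy <- runif(1, -0.5, 0.5)
    clean <- render_patch(dx, dy, 1, 1000)
    noise_sd <- max(clean) / 50
    patch <- clean + matrix(rnorm(9, sd = noise_sd), 3, 3)
    r <- localize_event(patch, method = "gauss", spot_sigma = 1)
    err[i, ] <- c(r$dx - dx, r$dy - dy)
    if (i <= 50) {
      o <- oracle_localize(patch, spot_sigma = 1, step = 0.01)
      err_vs_oracle[i] <- max(abs(r$dx - o$dx), abs(r$dy - o$dy))
    }
  }
  expect_lt(sqrt(mean(err^2)), 0.1)
  # the optimiser agrees with the dense grid search to the grid step
  expect_lt(median(err_vs_oracle), 0.02)
  # and is unbiased over symmetric offsets
  expect_lt(abs(mean(err)), 0.02)
})

test_that("batch localization agrees with the single-event optimiser", {
  set.seed(55)
  P <- matrix(0, 30, 9)
  truth <- matrix(0, 30, 2)
  for (i in 1:30) {
    truth[i, ] <- runif(2, -0.5, 0.5)
    P[i, ] <- render_patch(truth[i, 1], truth[i, 2], 1, 1000) +
      matrix(rnorm(9, sd = 5), 3, 3)
  }
  lb <- photonrestore:::localize_batch(P, 1)
  for (i in 1:30) {
    le <- localize_event(matrix(P[i, ], 3, 3), "gauss", spot_sigma = 1)
    expect_lt(abs(le$dx - lb$dx[i]), 2e-3)
    expect_lt(abs(le$dy - lb$dy[i]), 2e-3)
  }
})

test_that("the simulate-render-count round trip has high recall and low FDR", {
  cam <- tiny_camera(rows = 48, cols = 48, read_noise = 2, offset = 100)
  ii <- tiny_ii(gain_mean = 1500)
  psf <- default_psf()
  wf <- scan_waveform("static")
  set.seed(5)
  em <- generate_emitters("point", positions = cbind(
    runif(6, 200, 760), runif(6, 200, 760), 0), brightness = 0.05)
  truth <- simulate_photons(em, psf, wf, duration = 400, seed = 51)
  fs <- render_frames(truth, ii, cam, n_frames = 400, seed = 52)
  cal <- calibrate_camera(simulate_dark_frames(cam, 300, seed = 53), k = 5)
  det <- count_frames(fs, cal, calibrate_ratio_band(1), method = "gauss")
  # nearest-neighbour matching within 1 px, frame by frame
  n_match <- 0
  for (f in unique(det$frame)) {
    d <- det[det$frame == f, ]
    tr <- truth[truth$frame == f, ]
    if (!nrow(tr)) next
    used <- rep(FALSE, nrow(tr))
    for (q in seq_len(nrow(d))) {
      dist <- sqrt((tr$x_nm - d$x_nm[q])^2 + (tr$y_nm - d$y_nm[q])^2)
      dist[used] <- Inf
      j <- which.min(dist)
      if (dist[j] <= cam$pixel_size) { n_match <- n_match + 1; used[j] <- TRUE }
    }
  }
  recall <- n_match / nrow(truth)
  fdr <- 1 - n_match / nrow(det)
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.01)
})

test_that("doubling the gain leaves detected positions unchanged within localization error", {
  cam <- tiny_camera(rows = 48, cols = 48, read_noise = 1, offset = 100)
  psf <- default_psf()
  wf <- scan_waveform("static")
  em <- generate_emitters("point", positions = cbind(c(300, 600), c(300, 600), 0),
                          brightness = 0.02)
  truth <- simulate_photons(em, psf, wf, duration = 300, seed = 61)
  cal <- calibrate_camera(simulate_dark_frames(cam, 300, seed = 63), k = 5)
  crit <- calibrate_ratio_band(1)
  d1 <- count_frames(render_frames(truth, tiny_ii(gain_mean = 1000), cam,
                                   n_frames = 300, seed = 62), cal, crit)
  d2 <- count_frames(render_frames(truth, tiny_ii(gain_mean = 2000), cam,
                                   n_frames = 300, seed = 62), cal, crit)
  # same seed, same spot shapes up to amplitude: match events within 1 px
  dists <- numeric(0)
  for (f in unique(d1$frame)) {
    a <- d1[d1$frame == f, ]; b <- d2[d2$frame == f, ]
    if (!nrow(b)) next
    for (q in seq_len(nrow(a))) {
      dd <- sqrt((b$x_nm - a$x_nm[q])^2 + (b$y_nm - a$y_nm[q])^2)
      dists <- c(dists, min(dd))
    }
  }
  matched <- dists <= cam$pixel_size
  expect_gt(mean(matched), 0.95)
  expect_lt(median(dists[matched]), 0.1 * cam$pixel_size)
})

test_that("dark-only input yields an empty photon table", {
  cam <- tiny_camera(rows = 64, cols = 64, read_noise = 3, offset = 100)
  cal <- calibrate_camera(simulate_dark_frames(cam, 400, seed = 71), k = 5)
  dark <- simulate_dark_frames(cam, 100, seed = 72)
  ph <- count_frames(dark, cal, calibrate_ratio_band(1))
  expect_equal(nrow(ph), 0)
})
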