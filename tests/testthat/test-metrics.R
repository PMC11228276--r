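make_profile_grid <- function() {
  voxel_grid(c(0, 1000), c(0, 1000), c(0, 100), voxel_size = c(10, 10, 100))
}

# analytic double-Gaussian volume on a grid (uniform along x and z)
double_gauss_volume <- function(grid, centres, sigma, weights = c(1, 1)) {
  y <- grid_centers(grid, 2)
  prof <- weights[1] * exp(-(y - centres[1])^2 / (2 * sigma^2)) +
          weights[2] * exp(-(y - centres[2])^2 / (2 * sigma^2))
  array(rep(prof, each = grid$shape[1]), dim = grid$shape)
}

test_that("line profiles interpolate analytic volumes to within 1%", {
  grid <- make_profile_grid()
  vol <- double_gauss_volume(grid, c(400, 600), 80)
  prof <- line_profile(vol, start = c(500, 0, 50), end = c(500, 1000, 50),
                       grid = grid)
  truth <- exp(-(prof$position_nm - 400)^2 / (2 * 80^2)) +
           exp(-(prof$position_nm - 600)^2 / (2 * 80^2))
  inside <- prof$position_nm > 50 & prof$position_nm < 950
  expect_lt(max(abs(prof$intensity - truth)[inside]) / max(truth), 0.01)
  # sampling step is at most half the smallest non-slab voxel
  expect_lte(max(diff(prof$position_nm)), 5)
})

test_that("profiles of degenerate volumes behave as expected", {
  grid <- make_profile_grid()
  vol <- array(0, grid$shape)
  vol[50, 50, 1] <- 10  # one bright voxel at (495, 495)
  prof <- line_profile(vol, start = c(495, 0, 50), end = c(495, 1000, 50),
                       grid = grid)
  expect_equal(prof$position_nm[which.max(prof$intensity)], 495)
  expect_equal(sum(prof$intensity > 0.5 * max(prof$intensity) +
                     .Machine$double.eps) <= 3, TRUE)

  const <- array(3, grid$shape)
  pc <- line_profile(const, start = c(100, 100, 50), end = c(900, 900, 50),
                     grid = grid)
  inside <- pc$position_nm > 20 & pc$position_nm < max(pc$position_nm) - 20
  expect_true(all(abs(pc$intensity[inside] - 3) < 1e-9))
  expect_error(line_profile(const, start = c(1, 1, 1), end = c(1, 1, 1),
                            grid = grid), "zero-length")
})

test_that("peak separation matches the analytic two-Gaussian answer", {
  grid <- make_profile_grid()
  vol <- double_gauss_volume(grid, c(464.5, 535.5), 20)  # 71 nm apart
  prof <- line_profile(vol, start = c(500, 0, 50), end = c(500, 1000, 50),
                       grid = grid)
  ps <- peak_separation(prof)
  expect_true(ps$resolved)
  expect_lt(abs(ps$separation - 71), 2)

  # a single Gaussian is not resolved
  v1 <- double_gauss_volume(grid, c(500, 500), 50)
  p1 <- line_profile(v1, start = c(500, 0, 50), end = c(500, 1000, 50),
                     grid = grid)
  expect_false(peak_separation(p1)$resolved)

  # two Gaussians 0.3 sigma apart fail the dip criterion
  v2 <- double_gauss_volume(grid, c(500 - 0.15 * 100, 500 + 0.15 * 100), 100)
  p2 <- line_profile(v2, start = c(500, 0, 50), end = c(500, 1000, 50),
                     grid = grid)
  expect_false(peak_separation(p2)$resolved)
})

test_that("peak separation is symmetric under profile reversal", {
  grid <- make_profile_grid()
  vol <- double_gauss_volume(grid, c(430, 580), 40, weights = c(1, 0.7))
  fwd <- line_profile(vol, start = c(500, 0, 50), end = c(500, 1000, 50),
                      grid = grid)
  rev <- line_profile(vol, start = c(500, 1000, 50), end = c(500, 0, 50),
                      grid = grid)
  sf <- peak_separation(fwd); sr <- peak_separation(rev)
  expect_equal(sf$resolved, sr$resolved)
  expect_equal(sf$separation, sr$separation, tolerance = 1e-6)
})

test_that("FWHM matches the Gaussian closed form and is scale invariant", {
  grid <- voxel_grid(c(0, 2000), c(0, 2000), c(0, 100),
                     voxel_size = c(10, 10, 100))
  y <- grid_centers(grid, 2)
  prof_arr <- exp(-(y - 1000)^2 / (2 * 100^2))
  vol <- array(rep(prof_arr, each = grid$shape[1]), dim = grid$shape)
  prof <- line_profile(vol, start = c(1000, 0, 50), end = c(1000, 2000, 50),
                       grid = grid)
  expect_lt(abs(fwhm(prof) - 235.48), 1)
  prof10 <- prof
  prof10$intensity <- prof10$intensity * 10
  expect_equal(fwhm(prof10), fwhm(prof))
  # a profile that never falls below half maximum on one side is an error
  ramp <- tibble::tibble(position_nm = 0:4, intensity = c(1, 2, 3, 4, 5))
  expect_error(fwhm(ramp), "half")
})

test_that("bead PSF estimation recovers the widths with size correction", {
  set.seed(41)
  n <- 10000
  ph <- tibble::tibble(
    x_nm = rnorm(n, 0, 100), y_nm = rnorm(n, 0, 100),
    z_nm = rnorm(n, 0, 250), t_ms = runif(n), emitter = 1L)
  est <- measure_psf(ph, tibble::tibble(x_nm = 0, y_nm = 0, z_nm = 0))
  expect_lt(abs(est$sigma_xy - 100), 3)
  expect_lt(abs(est$sigma_z - 250), 8)

  # finite bead: photon spread is PSF (+) uniform sphere; correction removes it
  d <- 25
  r <- d / 2
  set.seed(42)
  nb <- 1e5
  u <- matrix(rnorm(3 * nb), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * r * runif(nb)^(1 / 3)
  phb <- tibble::tibble(
    x_nm = rnorm(nb, 0, 100) + u[, 1], y_nm = rnorm(nb, 0, 100) + u[, 2],
    z_nm = rnorm(nb, 0, 250) + u[, 3], t_ms = runif(nb), emitter = 1L)
  est_b <- measure_psf(phb, tibble::tibble(x_nm = 0, y_nm = 0, z_nm = 0),
                       bead_diameter = d)
  expect_lt(abs(est_b$sigma_xy - 100), 1.5)

  # pooling two identical beads equals a single-bead estimate in expectation
  ph2 <- dplyr::bind_rows(
    dplyr::mutate(ph, emitter = 1L),
    dplyr::mutate(ph, x_nm = x_nm + 2000, emitter = 2L))
  est2 <- measure_psf(ph2, tibble::tibble(x_nm = c(0, 2000), y_nm = c(0, 0),
                                          z_nm = c(0, 0)))
  expect_equal(est2$sigma_xy, est$sigma_xy, tolerance = 1e-9)
  expect_error(measure_psf(ph[1:10, ],
                           tibble::tibble(x_nm = 0, y_nm = 0, z_nm = 0)),
               "photons")
})

test_that("expected-value image FWHM of a line source shrinks with photon count", {
  # the apparent width of the restored image narrows as signal accumulates;
  # measured on the bootstrap expected-value image, the method's output
  psf <- psf_model(sigma_xy = 110, sigma_z = 50)
  grid <- voxel_grid(c(0, 1000), c(0, 1000), c(0, 50),
                     voxel_size = c(1000, 20, 50))
  widths <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n + 3)
    ph <- manual_photons(x = runif(n, 0, 1000), y = rnorm(n, 500, 110),
                         t = runif(n, 0, 1), z = rep(25, n))
    rec <- interval_reconstruct(ph, grid, psf, B = 20, seed = n,
                                n_iter = 2000, tol = 0,
                                support = list(ylim = c(200, 800)))
    prof <- line_profile(rec, start = c(500, 0, 25), end = c(500, 1000, 25))
    fwhm(prof)
  }, numeric(1))
  expect_true(widths[1] > widths[3])
})
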