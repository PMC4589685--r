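test_that("pore spectrum validates input and handles the empty case", {
  expect_error(pore_spectrum(matrix(0.5, 64, 64), 5), "binary")
  expect_error(pore_spectrum(matrix(0, 64, 64), 40), "half")
  expect_warning(ps <- pore_spectrum(matrix(1, 64, 64), 5), "empty")
  expect_true(ps$empty)
  expect_true(is.na(ps$mean_radius_px))
  expect_true(all(ps$I_r[-1] == 0))
})

test_that("a single disk pore of radius 10 is recovered", {
  m <- matrix(1, 64, 64)
  d2 <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
  m[d2 <= 10.5^2] <- 0
  ps <- pore_spectrum(m, max_radius_px = 15)
  expect_lt(abs(ps$mean_radius_px - 10), 1)
  expect_gt(sum(ps$f_r[ps$radii_px %in% 9:11]), 0.95)
  expect_equal(sum(ps$f_r), 1, tolerance = 1e-9)
})

test_that("regular fiber grid matches the brute-force opening oracle", {
  m <- matrix(0, 128, 128)
  m[seq(1, 128, 21), ] <- 1; m[, seq(1, 128, 21)] <- 1
  ps <- pore_spectrum(m, max_radius_px = 15)
  oracle_I <- brute_pore_retained(m, 15)
  expect_identical(ps$I_r, oracle_I)
  # spectrum support ends where a disk no longer fits the 20 px square pore
  expect_true(all(ps$P_r[ps$radii_px > 10] == 0))
  # oracle-derived mean (disk opening rounds the square corners, spreading
  # mass below the half-width)
  oracle_mean <- sum(0:14 * (-diff(oracle_I))) / sum(-diff(oracle_I))
  expect_equal(ps$mean_radius_px, oracle_mean, tolerance = 1e-12)
})

test_that("granulometry is anti-extensive and unit conversion holds", {
  set.seed(33)
  m <- matrix(rbinom(64 * 64, 1, 0.5), 64, 64)
  ps <- pore_spectrum(m, max_radius_px = 8, pixel_size_um = 0.2)
  expect_true(all(diff(ps$I_r) <= 0))
  expect_true(all(ps$f_r >= 0))
  expect_equal(ps$mean_diameter_um, 2 * ps$mean_radius_px * 0.2)

  # removing a dividing wall merges pores and cannot shrink the mean
  wall <- matrix(1, 64, 64)
  wall[10:54, 10:30] <- 0; wall[10:54, 34:54] <- 0  # two pores, 3 px wall
  merged <- wall; merged[10:54, 31:33] <- 0
  ps_two <- pore_spectrum(wall, 20)
  ps_one <- pore_spectrum(merged, 20)
  expect_gte(ps_one$mean_radius_px, ps_two$mean_radius_px)
})

test_that("Fourier magnitude: DC removal, symmetry, Parseval", {
  expect_lt(max(ft_magnitude(matrix(4.2, 32, 32), TRUE)$magnitude), 1e-9)
  # horizontal sinusoid: two point-symmetric peaks on the vertical axis
  y <- matrix(rep(sin(2 * pi * 5 * (0:63) / 64), each = 64), 64, 64,
              byrow = FALSE)
  sp <- ft_magnitude(t(y), dc_remove = TRUE)  # rows vary -> vertical freq
  pk <- which(sp$magnitude > max(sp$magnitude) / 2, arr.ind = TRUE)
  expect_equal(nrow(pk), 2)
  expect_true(all(pk[, 2] == sp$center[2]))  # on the vertical frequency axis
  expect_equal(sort(abs(pk[, 1] - sp$center[1])), c(5, 5))
  # Parseval with the DC retained
  set.seed(7)
  im <- matrix(runif(48 * 48), 48, 48)
  sp2 <- ft_magnitude(im, dc_remove = FALSE)
  expect_equal(sum(im^2), sum(sp2$magnitude^2) / (48 * 48),
               tolerance = 1e-6)
  # point symmetry through the origin for real input
  m <- sp2$magnitude[2:48, 2:48]
  expect_lt(max(abs(m - m[47:1, 47:1])), 1e-6 * max(m))
})

test_that("angular power integrates lines through the spectrum center", {
  # centered ring: rotationally symmetric, F_I constant to within 2%
  n <- 129
  r <- sqrt(outer((1:n - 65)^2, (1:n - 65)^2, "+"))
  ring <- exp(-(r - 20)^2 / 8)
  sp <- structure(list(magnitude = ring, center = c(65, 65),
                       origin_centered = TRUE, dc_removed = TRUE,
                       dims = c(n, n)), class = "spectrum_ft")
  pp <- angular_power(sp, 90)
  expect_lt(diff(range(pp$power)) / mean(pp$power), 0.02)
  # two point-symmetric peaks on the vertical axis -> argmax at pi/2
  pk <- matrix(0, n, n); pk[65 + 20, 65] <- 1; pk[65 - 20, 65] <- 1
  sp$magnitude <- pk
  pp2 <- angular_power(sp, 180)
  expect_equal(pp2$thetas_rad[which.max(pp2$power)], pi / 2)
  expect_error(angular_power(structure(list(origin_centered = FALSE),
                                       class = "spectrum_ft")), "centered")
})

test_that("alignment index limits from the eigenvalue construction", {
  th <- pi * (0:179) / 180
  delta <- rep(0, 180); delta[35] <- 3
  res <- alignment_index(polar_power(th, delta))
  expect_equal(res$alpha, 1)
  expect_equal(res$lambda2, 0)
  expect_equal(res$principal_orientation_rad, th[35], tolerance = 1e-9)

  unif <- alignment_index(polar_power(th, rep(2, 180)))
  expect_lt(abs(unif$alpha), 1e-9)
  expect_equal(unif$lambda1, unif$lambda2, tolerance = 1e-9)

  # equal deltas at 0 and pi/2: second-moment matrix proportional to identity
  two <- rep(0, 180); two[1] <- 5; two[91] <- 5
  expect_lt(abs(alignment_index(polar_power(th, two))$alpha), 1e-12)

  expect_error(alignment_index(polar_power(th, rep(0, 180))), "zero")
  expect_error(polar_power(th[1:4], rep(1, 4)), "at least 8")
})

test_that("image alignment is bounded, rotation-invariant and axis-true", {
  ff <- make_fiber_field(kappa = 4, seed = 3, orientation_center_rad = 0.6)
  a1 <- image_alignment(ff$image)
  expect_gte(a1$alpha, 0); expect_lte(a1$alpha, 1)
  a2 <- image_alignment(rot90(ff$image$values))
  expect_lt(abs(a1$alpha - a2$alpha), 0.02)

  # horizontal fibers: angular power peaks orthogonal to the fiber axis
  ffh <- generate_fiber_image(fiber_field_params(
    image_size_px = 256, n_fibers = 100, mean_length_px = 150, width_px = 3,
    orientation_kappa = Inf, orientation_center_rad = 0, seed = 4))
  pp <- attr(image_alignment(ffh$image), "polar_power")
  peak <- pp$thetas_rad[which.max(pp$power)]
  expect_lt(abs(peak - pi / 2), 5 * pi / 180)
})

test_that("full microstructure analysis orders aligned vs isotropic fields", {
  mk <- function(kappa) generate_fiber_image(
    fiber_field_params(image_size_px = 320, n_fibers = 220,
                       mean_length_px = 140, width_px = 3,
                       orientation_kappa = kappa, seed = 21,
                       fiber_intensity = 0.6),
    bg = background_params(center_intensity = 0.5, falloff_scale_px = 220,
                           floor_intensity = 0.05, speckle_sd = 0.05,
                           seed = 21))
  r_iso <- analyze_microstructure(mk(0)$image, max_radius_px = 20)
  r_al <- analyze_microstructure(mk(16)$image, max_radius_px = 20)
  expect_gt(r_al$alignment$alpha, r_iso$alignment$alpha)
  # 61 um crop at 0.2 um/px
  expect_equal(dim(r_iso$stages$raw$values), c(305, 305))
  # deterministic: identical summaries on rerun
  r_iso2 <- analyze_microstructure(mk(0)$image, max_radius_px = 20)
  expect_identical(summary(r_iso), summary(r_iso2))
  # reported diameters are in um: 2 * radius_px * um/px
  expect_equal(r_iso$pore$mean_diameter_um,
               2 * r_iso$pore$mean_radius_px * 0.2)
})
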