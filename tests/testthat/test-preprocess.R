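test_that("radial background estimation recovers known surfaces", {
  # constant image -> constant background
  est <- estimate_background(matrix(3.5, 64, 64))
  expect_lt(max(abs(est$values - 3.5)), 1e-12)

  # pure radial Gaussian recovered to < 1% of peak
  bgp <- background_params(center_intensity = 1, falloff_scale_px = 100,
                           floor_intensity = 0.1, speckle_sd = 0)
  clean <- generate_background(bgp, c(128, 128), speckle = FALSE)
  est <- estimate_background(clean)
  expect_lt(max(abs(est$values - clean$values)) / max(clean$values), 0.01)

  # sparse bright fibers (< 5% coverage) barely perturb the estimate
  ff <- generate_fiber_image(fiber_field_params(
    image_size_px = 128, n_fibers = 6, mean_length_px = 60, width_px = 2,
    orientation_kappa = 0, seed = 5, fiber_intensity = 1))
  expect_lt(mean(ff$image$values > 0), 0.05)
  est <- estimate_background(ff$image$values + clean$values)
  expect_lt(max(abs(est$values - clean$values)) / max(clean$values), 0.03)

  expect_error(estimate_background(matrix(1, 1, 1)), "too small")
})

test_that("flat-field normalization preserves the global scale", {
  r <- matrix(runif(64 * 64), 64, 64)
  # uniform background: identity
  n1 <- normalize_image(r, matrix(0.7, 64, 64))
  expect_lt(max(abs(n1$values - r)), 1e-12)
  # pure background: constant equal to the background mean
  bg <- generate_background(background_params(speckle_sd = 0), c(64, 64))
  n2 <- normalize_image(bg$values, bg$values)
  expect_lt(max(abs(n2$values - mean(bg$values))), 1e-9)
  expect_equal(mean(n2$values), mean(bg$values), tolerance = 1e-12)
  expect_error(normalize_image(r, matrix(1, 32, 32)), "shape")
})

test_that("normalization equalizes fiber contrast across radii", {
  # multiplicative vignette: fibers at a fixed contrast over a constant base,
  # the whole field attenuated radially; after flat-fielding the
  # fiber-to-local-background contrast must be uniform in radius
  ff <- generate_fiber_image(fiber_field_params(
    image_size_px = 128, n_fibers = 25, mean_length_px = 50, width_px = 2,
    orientation_kappa = 0, seed = 8, fiber_intensity = 0.5))
  vignette <- generate_background(background_params(
    center_intensity = 1, falloff_scale_px = 80, floor_intensity = 0.2,
    speckle_sd = 0), c(128, 128), speckle = FALSE)$values
  raw <- (0.5 + ff$image$values) * vignette
  norm <- normalize_image(raw, estimate_background(raw))$values
  fib <- ff$image$meta$fiber_mask
  r <- sqrt(outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, "+"))
  inner <- r < 40
  contrast <- function(sel) mean(norm[fib & sel]) / mean(norm[!fib & sel])
  expect_lt(abs(contrast(inner) / contrast(!inner) - 1), 0.05)
})

test_that("filter bank geometry: line masks, normalization, symmetry", {
  bank <- build_filter_bank(5, 15, 0.7)
  expect_length(bank$filters, 15)
  sums <- vapply(bank$filters, function(f) c(sum(f$GF), sum(f$AF)),
                 numeric(2))
  expect_lt(max(abs(sums - 1)), 1e-12)
  # theta = 0: the middle row of the mask, Gaussian-symmetric about center
  gf0 <- bank$filters[[1]]$GF
  expect_true(all(gf0[c(1, 2, 4, 5), ] == 0))
  expect_equal(gf0, gf0[, 5:1])
  # theta = pi/2 is the transpose of theta = 0 (present for n = 2)
  bank2 <- build_filter_bank(5, 2, 0.7)
  expect_equal(bank2$filters[[2]]$GF, t(bank2$filters[[1]]$GF))
  expect_equal(bank2$filters[[2]]$AF, t(bank2$filters[[1]]$AF))
  expect_error(build_filter_bank(4, 15, 0.7), "odd")
})

test_that("fiber enhancement responds to lines and cancels constants", {
  bank <- build_filter_bank()
  # constant image -> exactly zero (normalized filters cancel)
  expect_lt(max(abs(fiber_enhance(matrix(2.7, 32, 32), bank)$values)), 1e-12)
  # single horizontal line: response on the line exceeds response 3 px away
  img <- matrix(0, 32, 32); img[16, ] <- 1
  fe <- fiber_enhance(img, bank)$values
  expect_gt(fe[16, 16], fe[19, 16])
  # cross-check the full enhanced image against a direct convolution oracle
  small <- img[9:24, 9:24]
  oracle <- Reduce(pmax, lapply(bank$filters, function(f)
    brute_conv_reflect(small, f$GF - f$AF)))
  expect_lt(max(abs(fiber_enhance(small, bank)$values - oracle)), 1e-12)
  expect_error(fiber_enhance(img, structure(list(filters = list()),
                                            class = "filter_bank")),
               "non-empty")
})

test_that("enhancement separates fiber from background across kappa", {
  bank <- build_filter_bank()
  for (k in c(0, 2, 8)) {
    ff <- make_fiber_field(kappa = k, seed = 20 + k, size = 128,
                           n_fibers = 60, length = 60)
    fe <- fiber_enhance(ff$image$values, bank)$values
    fib <- ff$image$meta$fiber_mask
    expect_gt(mean(fe[fib]), mean(fe[!fib]))
  }
})

test_that("enhancement is 90-degree equivariant and positively homogeneous", {
  # orientation set must contain 90 deg for exact equivariance: n = 10 gives
  # 0, 18, ..., 90, ... deg
  bank <- build_filter_bank(5, 10, 0.7)
  set.seed(2)
  im <- matrix(runif(64 * 64), 64, 64)
  expect_lt(max(abs(fiber_enhance(rot90(im), bank)$values -
                    rot90(fiber_enhance(im, bank)$values))), 1e-9)
  bank15 <- build_filter_bank()
  expect_lt(max(abs(fiber_enhance(3.7 * im, bank15)$values -
                    3.7 * fiber_enhance(im, bank15)$values)), 1e-9)
})

test_that("binarization thresholds and records its threshold", {
  img <- matrix(runif(400), 20, 20)
  expect_true(all(binarize(img, "fixed", value = 2)$values == 0))
  expect_true(all(binarize(img, "fixed", value = -1)$values == 1))
  expect_error(binarize(img, "fixed", value = NA), "finite")
  # idempotent on an already binary image at threshold 0.5
  bw <- matrix(rbinom(400, 1, 0.4), 20, 20)
  expect_equal(binarize(bw, "fixed", value = 0.5)$values, bw + 0)
  q <- binarize(img, "quantile", value = 0.9)
  expect_equal(mean(q$values), 0.1, tolerance = 0.01)
  expect_true(is.finite(q$meta$threshold))
})

test_that("Otsu segmentation of a noisy synthetic field matches ground truth", {
  # fixed-seed fixture: width 3 px, kappa 4, radial background with speckle
  ff <- generate_fiber_image(
    fiber_field_params(image_size_px = 256, n_fibers = 120,
                       mean_length_px = 100, width_px = 3,
                       orientation_kappa = 4, seed = 11,
                       fiber_intensity = 0.6),
    bg = background_params(center_intensity = 0.5, falloff_scale_px = 180,
                           floor_intensity = 0.05, speckle_sd = 0.05,
                           seed = 11))
  st <- preprocess_image(ff$image)
  gt <- ff$image$meta$fiber_mask
  pred <- st$binary$values > 0
  tp <- sum(pred & gt); fp <- sum(pred & !gt); fn <- sum(!pred & gt)
  expect_gte(2 * tp / (2 * tp + fp + fn), 0.7)
  # pixel size survives the whole chain
  expect_equal(st$binary$pixel_size_um, ff$image$pixel_size_um)
  expect_equal(st$enhanced$pixel_size_um, ff$image$pixel_size_um)
})
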