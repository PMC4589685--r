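test_that("cell speed: limit cases, exact recovery, sampling checks", {
  still <- trajectory("a", c(0, 2, 4), c(1, 1, 1), c(2, 2, 2))
  expect_equal(cell_speed(still), 0)
  # 1 um per 2-min step -> 0.5 um/min
  straight <- trajectory("b", seq(0, 20, 2), seq(0, 10, 1), rep(0, 11))
  expect_equal(cell_speed(straight), 0.5)
  # generator at known speed: recovered exactly (constant step length)
  tr <- generate_trajectory(walk_params(n_steps = 100, dt_min = 2,
                                        speed_um_per_min = 1.23,
                                        persistence = 0.5, seed = 6))
  expect_equal(cell_speed(tr), 1.23, tolerance = 1e-12)
  # dropped frame -> rejected, not interpolated
  gap <- trajectory("c", c(0, 2, 6, 8), 1:4, 1:4)
  expect_error(cell_speed(gap), "non-uniform")
  expect_error(cell_speed(trajectory("d", 0, 1, 1)), "two points")
})

test_that("net invasion is the maximum displacement from the origin point", {
  out_back <- trajectory("a", 0:4, c(0, 5, 10, 5, 0), rep(0, 5))
  expect_equal(net_invasion(out_back), 10)
  expect_equal(net_invasion(trajectory("b", 0, 3, 4)), 0)
  # exhaustive oracle on a random track
  set.seed(9)
  x <- cumsum(rnorm(1000)); y <- cumsum(rnorm(1000))
  tr <- trajectory("c", 1:1000, x, y)
  expect_equal(net_invasion(tr),
               max(sqrt((x - x[1])^2 + (y - y[1])^2)))
})

test_that("speed and invasion are rigid-motion invariant and consistent", {
  tr <- generate_trajectory(walk_params(n_steps = 60, dt_min = 2,
                                        speed_um_per_min = 0.8,
                                        persistence = 0.3, seed = 12))
  phi <- 0.77; dx <- 13.2; dy <- -4.4
  tr2 <- trajectory(tr$cell_id, tr$times_min,
                    cos(phi) * tr$x_um - sin(phi) * tr$y_um + dx,
                    sin(phi) * tr$x_um + cos(phi) * tr$y_um + dy)
  expect_equal(cell_speed(tr2), cell_speed(tr), tolerance = 1e-9)
  expect_equal(net_invasion(tr2), net_invasion(tr), tolerance = 1e-9)
  # net invasion can never exceed speed x total duration
  expect_lte(net_invasion(tr),
             cell_speed(tr) * diff(range(tr$times_min)) + 1e-9)
})

test_that("protrusion partitioning: sectors, boundaries, fractions", {
  # all events at the anterior angle land in sector 1
  ev <- data.frame(time_min = 1:5, angle_rad = rep(0.3, 5),
                   length_um = rep(6, 5))
  rec <- protrusion_record("a", ev, anterior_axis_rad = 0.3)
  pe <- partition_events(rec)
  expect_equal(pe$fractions[1], 1)
  expect_equal(pe$C1, 5); expect_equal(pe$C2, 0)

  # boundary tie at +22.5 deg goes to the counter-clockwise sector (2)
  evb <- data.frame(time_min = 1, angle_rad = pi / 8, length_um = 6)
  peb <- partition_events(protrusion_record("b", evb, anterior_axis_rad = 0))
  expect_equal(which(peb$fractions == 1), 2L)
  # just inside the boundary stays in sector 1
  evi <- data.frame(time_min = 1, angle_rad = pi / 8 - 1e-9, length_um = 6)
  pei <- partition_events(protrusion_record("c", evi, anterior_axis_rad = 0))
  expect_equal(which(pei$fractions == 1), 1L)

  # uniform angles: all eight fractions near 1/8 (n = 8000; 99.9% binomial
  # band 3.29 * sqrt(p(1-p)/n) ~ 0.012)
  set.seed(4)
  evu <- data.frame(time_min = seq_len(8000),
                    angle_rad = runif(8000, 0, 2 * pi),
                    length_um = rep(6, 8000))
  peu <- partition_events(protrusion_record("d", evu, anterior_axis_rad = 1))
  expect_true(all(abs(peu$fractions - 0.125) < 0.012))
  expect_equal(sum(peu$fractions), 1, tolerance = 1e-9)

  # empty record: fractions missing, counts zero
  pe0 <- partition_events(protrusion_record(
    "e", data.frame(time_min = numeric(0), partition = integer(0),
                    length_um = numeric(0))))
  expect_true(all(is.na(pe0$fractions)))
  expect_equal(pe0$C1 + pe0$C2, 0)
})

test_that("polarization index limits and antisymmetry", {
  expect_equal(polarization_index(12, 0), 1)
  expect_equal(polarization_index(6, 6), 0)
  expect_equal(polarization_index(0, 9), -1)
  expect_true(is.na(polarization_index(0, 0)))
})

test_that("protrusion rate scales counts to the reporting window", {
  ev <- data.frame(time_min = seq(30, 700, length.out = 8),
                   partition = rep(1L, 8), length_um = rep(6, 8))
  rec <- protrusion_record("a", ev, duration_min = 720)
  expect_equal(protrusion_rate(rec), 1.0)  # 8 * 90 / 720
  rec0 <- protrusion_record(
    "b", data.frame(time_min = numeric(0), partition = integer(0),
                    length_um = numeric(0)), duration_min = 720)
  expect_equal(protrusion_rate(rec0), 0)
  # generator at rate lambda: estimate within 3 s.e. of the Poisson mean
  pr <- generate_protrusion_stream(protrusion_stream_params(
    duration_min = 720 * 30, rate_per_90min = 5, axial_bias = 0.5,
    seed = 13))
  n_exp <- 5 * 720 * 30 / 90
  expect_lt(abs(protrusion_rate(pr) - 5), 3 * sqrt(n_exp) * 90 / (720 * 30))
})

test_that("motility summary assembles per-cell metrics", {
  tr <- generate_trajectory(walk_params(n_steps = 50, seed = 2), "cellA")
  pr <- generate_protrusion_stream(protrusion_stream_params(
    axial_bias = 0.8, seed = 2), "cellA")
  ms <- motility_summary(tr, pr)
  expect_s3_class(ms, "motility_summary")
  expect_equal(ms$cell_id, "cellA")
  expect_equal(ms$speed_um_per_min, cell_speed(tr))
  expect_gte(ms$polarization_index, -1)
  expect_lte(ms$polarization_index, 1)
  df <- as.data.frame(ms)
  expect_equal(nrow(df), 1)
  expect_true(all(c("speed_um_per_min", "net_invasion_um",
                    "polarization_index") %in% names(df)))
})
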