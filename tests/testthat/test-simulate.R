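test_that("default array is 7 receivers with the published mean spacing", {
  arr <- default_array()
  expect_equal(nrow(arr), 7)
  # centre receiver equidistant from all six outer ones
  d_centre <- plane_distance(arr$x_m[1], arr$y_m[1], arr$x_m[-1], arr$y_m[-1])
  expect_equal(d_centre, rep(77.1, 6))
  # mean nearest-neighbour distance equals the spacing
  dm <- as.matrix(dist(arr[, c("x_m", "y_m")]))
  diag(dm) <- Inf
  expect_equal(mean(apply(dm, 1, min)), 77.1)
})

test_that("transmission gaps are uniform on the period range", {
  set.seed(21)
  t <- gen_transmission_times(5000, 3, 5)
  gaps <- diff(t)
  expect_true(all(gaps >= 3 & gaps <= 5))
  expect_true(all(t < 5000))
  expect_true(t[1] <= 5) # first transmission within one max period
  # mean gap over many draws matches the uniform expectation
  set.seed(22)
  big <- diff(gen_transmission_times(4.0 * 1e5, 3, 5))
  expect_equal(mean(big), 4.0, tolerance = 0.01 / 4.0)
  # count over 900 s close to duration / mean gap
  set.seed(23)
  counts <- replicate(50, length(gen_transmission_times(900, 3, 5)))
  expect_equal(mean(counts), 900 / 4, tolerance = 0.02)
})

test_that("noise-free arrivals equal emission time plus travel time", {
  arr <- tibble::tibble(receiver_id = "R1", x_m = 145, y_m = 0)
  arr <- dplyr::bind_rows(arr, tibble::tibble(receiver_id = c("R2", "R3"),
                                              x_m = c(0, 0), y_m = c(100, -100)))
  tr <- stationary_trajectory(0, 0, 10)
  mod <- propagation_model(c_ms = 1450, sigma_t = 0, d50 = 1e4)
  det <- simulate_detections(arr, tr, times = 2, mod)
  r1 <- det$time_s[det$receiver_id == "R1"]
  expect_equal(r1 - 2, 0.100, tolerance = 1e-12)
})

test_that("well within range every receiver detects; far outside almost none", {
  arr <- default_array()
  tr <- stationary_trajectory(5, 5, 100)
  set.seed(24)
  near <- simulate_detections(arr, tr, gen_transmission_times(100, 1, 2),
                              propagation_model(sigma_t = 0, d50 = 150, k = 0.5))
  n_tx <- length(unique(round(near$time_s)))
  expect_equal(nrow(near) / length(unique(group_transmissions(near, arr)$transmission)), 7)

  far <- stationary_trajectory(5000, 5000, 100)
  set.seed(25)
  det_far <- simulate_detections(arr, far, gen_transmission_times(100, 1, 2),
                                 propagation_model(d50 = 150, k = 0.5))
  expect_equal(nrow(det_far), 0)
})

test_that("seeded simulation is reproducible", {
  arr <- default_array()
  tr <- stationary_trajectory(10, 0, 30)
  run <- function() {
    set.seed(99)
    simulate_detections(arr, tr, gen_transmission_times(30, 1, 2))
  }
  expect_identical(run(), run())
})

test_that("trajectories behave as specified", {
  # single segment at speed 1 for 10 s ends 10 m from start
  wp <- tibble::tibble(x_m = c(0, 10), y_m = c(0, 0))
  tr <- waypoint_trajectory(wp, speed_ms = 1, dt_s = 1)
  last <- tr[nrow(tr), ]
  expect_equal(plane_distance(0, 0, last$x_m, last$y_m), 10)
  expect_error(waypoint_trajectory(wp[1, ], 1), "2 waypoints")

  # zero turning SD gives a straight line
  set.seed(26)
  straight <- crw_trajectory(50, speed_mean = 0.5, turn_sd_deg = 0)
  expect_equal(movement_metrics(straight)$angle_median, 0, tolerance = 1e-10)

  # CRW mean step length equals speed * dt
  set.seed(27)
  crw <- crw_trajectory(10000, speed_mean = 0.3, turn_sd_deg = 25, dt_s = 2)
  steps <- sqrt(diff(crw$x_m)^2 + diff(crw$y_m)^2)
  expect_equal(mean(steps), 0.6, tolerance = 1e-9)

  # asking for a time outside the trajectory errors
  expect_error(trajectory_at(straight, -1), "cover")
})

test_that("a tag heard by only two receivers yields no positions", {
  # two receivers close to the tag, the rest far outside detection range
  arr <- tibble::tibble(
    receiver_id = paste0("R", 1:7),
    x_m = c(0, 60, 5000, 5100, 5200, 5300, 5400),
    y_m = c(0, 0, 5000, 5000, 5000, 5000, 5000)
  )
  tr <- stationary_trajectory(30, 10, 120)
  set.seed(28)
  det <- simulate_detections(arr, tr, gen_transmission_times(120, 1, 2),
                             propagation_model(d50 = 150, k = 0.5))
  expect_true(all(det$receiver_id %in% c("R1", "R2")))
  fixes <- position_run(det, arr)
  expect_equal(nrow(fixes), 0)
})

test_that("simulated fish fix sequences have a lightly lossy ~4 s period", {
  set.seed(29)
  meds <- replicate(50, {
    t <- simulate_fix_times()
    median(diff(t))
  })
  # 8% omission lifts the median period slightly above the 4 s mean gap
  expect_gt(mean(meds), 4.0)
  expect_lt(mean(meds), 4.4)
})
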