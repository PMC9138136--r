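test_that("pump calibration reproduces an exact line and rejects degenerate designs", {
  pts <- data.frame(set_rate_ml_min = c(1, 2, 3), mass_g = c(1, 2, 3))
  cal <- calibrate_pump(pts)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  expect_error(calibrate_pump(data.frame(set_rate_ml_min = c(2, 2, 2),
                                         mass_g = c(2, 2.1, 1.9))),
               "degenerate design")
})

test_that("pump calibration recovers the true rate from noisy replicates", {
  # water at 1 g/mL, 1-min collections: true slope 1 g per (mL/min)
  set.seed(1)
  rates <- rep(c(0.5, 1, 2, 4), each = 3)
  pts <- data.frame(set_rate_ml_min = rates,
                    replicate = rep(1:3, times = 4),
                    mass_g = rates * 1.0 + rnorm(length(rates), 0, 0.02))
  cal <- calibrate_pump(pts)
  expect_gt(cal$slope, 0.95)
  expect_lt(cal$slope, 1.05)
  expect_gt(cal$r_squared, 0.99)
})

test_that("volume/steps conversion is exact and range-checked", {
  cfg <- pump_config(steps_per_ml = 800)
  expect_identical(volume_to_steps(2, cfg), 1600L)
  expect_identical(volume_to_steps(10, cfg), 8000L)
  expect_error(volume_to_steps(0, cfg), "positive")
  expect_error(volume_to_steps(10.5, cfg), "exceeds syringe capacity")
  # round trip within half a step
  for (v in c(0.123, 1.9997, 7.77)) {
    expect_lt(abs(v - steps_to_volume(volume_to_steps(v, cfg), cfg)), 0.5 / 800)
  }
})

test_that("simulated bus moves media as a drain/refill sequence dictates", {
  cfg <- br_config()
  bus <- simulated_bus(cfg)
  bus$set_channel("W1")
  bus$run_pump(2, "B")                   # drain 2 mL of cultured media
  expect_equal(bus$wells$W1$volume_ml, 3)
  expect_equal(bus$syringe_ml, 2)
  bus$set_channel("WASTE")
  bus$run_pump(2, "F")                   # dispose via the sensor line
  expect_equal(bus$syringe_ml, 0)
  expect_equal(bus$waste_ml, 2)
  expect_equal(nrow(bus_sensor_log(bus)), 1)  # disposal passed the sensor
  bus$set_channel("FRESH")
  bus$run_pump(2, "B")
  bus$set_channel("W1")
  bus$run_pump(2, "F")                   # refill
  expect_equal(bus$wells$W1$volume_ml, 5)
  expect_equal(bus$reservoir_ml, cfg$reservoir_ml - 2)
})

test_that("simulated bus rejects impossible transfers", {
  bus <- simulated_bus(br_config())
  bus$set_channel("W1")
  expect_error(bus$run_pump(2, "F"), "underflow")          # empty syringe
  expect_error(bus$run_pump(6, "B"), "overdraw")           # 5-mL well
  expect_error(bus$run_pump(11, "B"), "overfill")          # 10-mL syringe
  bus$set_channel("WASTE")
  expect_error(bus$run_pump(1, "B"), "cannot withdraw")
  bus$set_channel("FRESH")
  bus$run_pump(1, "B")  # fill the syringe so only the routing is at fault
  expect_error(bus$run_pump(1, "F"), "cannot dispense")
  expect_error(bus$run_pump(1, "B", channel = "XX"), "unknown channel")
  expect_error(bus$read_green_intensity(), "sensor line is empty")
})

test_that("pump-run durations follow volume / rate", {
  bus <- simulated_bus(br_config())  # default rate 2 mL/min
  bus$set_channel("W1")
  expect_equal(bus$run_pump(2, "B"), 60)
  expect_equal(bus$run_pump(1, "B", rate_ml_min = 4), 15)
})

test_that("volume is conserved over long random pump sequences", {
  cfg <- br_config()
  set.seed(7)
  bus <- simulated_bus(cfg)
  total0 <- bus_total_volume(bus)
  channels <- cfg$channels$channel
  n_ok <- 0
  for (i in 1:2000) {
    ch <- sample(channels, 1)
    dir <- sample(c("F", "B"), 1)
    v <- round(runif(1, 0.1, 3), 3)
    ok <- !inherits(try(
      { bus$set_channel(ch); bus$run_pump(v, dir) }, silent = TRUE), "try-error")
    n_ok <- n_ok + ok
    expect_equal(bus_total_volume(bus), total0, tolerance = 1e-9)
    expect_gte(bus$syringe_ml, -1e-12)
    expect_lte(bus$syringe_ml, cfg$pump$capacity_ml + 1e-12)
  }
  expect_gt(n_ok, 100)  # the walk actually moved liquid
})

test_that("pump calibration CSV reader enforces its columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("set_rate_ml_min,replicate,mass_g\n1,1,1.01\n2,1,1.98", path)
  pts <- read_pump_points(path)
  expect_equal(nrow(pts), 2)
  writeLines("rate,mass\n1,1", path)
  expect_error(read_pump_points(path), "must have columns")
})
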