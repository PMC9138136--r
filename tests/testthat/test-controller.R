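test_that("the generated refresh script has the expected shape and validates", {
  cfg <- br_config()

  one <- build_refresh_script(refresh_protocol(wells = "W1", volume_ml = 2,
                                               period_h = 6, cycles = 1), cfg)
  ops <- vapply(one$commands, `[[`, character(1), "opcode")
  expect_equal(sum(ops == "START"), 4)   # drain, dispose, draw, refill
  expect_equal(sum(ops == "WAIT"), 1)

  full <- build_refresh_script(refresh_protocol(), cfg)  # 6 wells, 8 cycles
  expect_equal(nrow(validate_script(full, cfg)), 0)
  tr <- run_script(full, null_bus(cfg), cfg)
  pumps <- tr[tr$event_type == "pump", ]
  expect_equal(nrow(pumps), 192)         # 6 wells x 8 cycles x 4 transfers
  # drain-dispose-draw-refill quadruples, in fixed well order each cycle
  expect_equal(pumps$channel[1:8],
               c("W1", "WASTE", "FRESH", "W1", "W2", "WASTE", "FRESH", "W2"))
  expect_equal(pumps$direction[1:4], c("B", "F", "B", "F"))
  # scripted delay totals 8 x 6 h
  fops <- vapply(full$commands, `[[`, character(1), "opcode")
  waits <- vapply(full$commands[fops == "WAIT"], `[[`, numeric(1), "arg")
  expect_equal(sum(waits) * 8, 172800)

  expect_error(refresh_protocol(cycles = 0), "cycles")
  expect_error(build_refresh_script(refresh_protocol(volume_ml = 12), cfg),
               "exceeds syringe capacity")
  expect_error(build_refresh_script(refresh_protocol(wells = "W9"), cfg),
               "not in channel table")
})

test_that("the default 48-h run logs one in-band reading per well per cycle", {
  rep <- run_protocol(refresh_protocol(), br_config(), seed = 1)
  expect_equal(nrow(rep$ph_log), 48)     # 6 wells x 8 cycles
  expect_true(all(rep$ph_log$ph_estimate >= 7.2 &
                  rep$ph_log$ph_estimate <= 7.6))
  expect_equal(rep$summary$mean_ph, 7.4, tolerance = 0.2 / 7.4)
  expect_equal(rep$summary$frac_in_band, 1)
  expect_false(is.unsorted(rep$ph_log$elapsed_s))
  # sensor timestamps coincide with pump events on the trace
  expect_true(all(rep$ph_log$elapsed_s %in% rep$events$elapsed_s))
})

test_that("a protocol left unrefreshed for a long period goes acidic", {
  cfg <- br_config()
  rep <- run_protocol(refresh_protocol(wells = "W1", period_h = 500, cycles = 1),
                      cfg, seed = 1)
  # the single end-of-period refresh reads media spent over ~500 h
  expect_lt(well_ph(rep$wells$W1, cfg$twin), 7.2)
})

test_that("runs are reproducible from the seed alone", {
  a <- run_protocol(refresh_protocol(), seed = 99)
  b <- run_protocol(refresh_protocol(), seed = 99)
  expect_identical(a$ph_log, b$ph_log)
  expect_identical(bare_trace(a$events), bare_trace(b$events))
  c <- run_protocol(refresh_protocol(), seed = 100)
  expect_false(identical(a$ph_log$green_intensity, c$ph_log$green_intensity))
})

test_that("media accounting closes over a full run", {
  cfg <- br_config()
  rep <- run_protocol(refresh_protocol(), cfg, seed = 3)
  used <- rep$summary$media_used_ml
  expect_equal(used, 6 * 8 * 2)                  # wells x cycles x volume
  expect_equal(rep$summary$waste_ml, used)       # disposed equals drawn
  for (w in rep$wells) expect_equal(w$volume_ml, 5)  # wells end refilled
})

test_that("report summaries match independent recomputation from exported CSVs", {
  rep <- run_protocol(refresh_protocol(wells = c("W1", "W2"), cycles = 3),
                      seed = 5)
  dir <- withr::local_tempdir()
  write_run_report(rep, dir)
  log <- read_ph_log(file.path(dir, "ph_log.csv"))
  expect_equal(mean(log$ph_estimate), rep$summary$mean_ph)
  expect_equal(range(log$ph_estimate),
               c(rep$summary$min_ph, rep$summary$max_ph))
  expect_equal(mean(log$ph_estimate >= 7.2 & log$ph_estimate <= 7.6),
               rep$summary$frac_in_band)
  events <- read_event_trace(file.path(dir, "events.csv"))
  expect_equal(nrow(events[events$event_type == "pump", ]), 2 * 3 * 4)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$summary$mean_ph, rep$summary$mean_ph)
})

test_that("YAML configuration merges with defaults and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pump:", "  capacity_ml: 20", "twin:", "  q: 1.0e-6",
               "sim:", "  seed: 7"), path)
  cfg <- read_br_config(path)
  expect_equal(cfg$pump$capacity_ml, 20)
  expect_equal(cfg$pump$steps_per_ml, 800)   # untouched default
  expect_equal(cfg$twin$q, 1e-6)
  expect_equal(cfg$seed, 7)

  writeLines(c("pump:", "  capacty_ml: 20"), path)
  expect_error(read_br_config(path), "unknown key")
  writeLines(c("pmup:", "  capacity_ml: 20"), path)
  expect_error(read_br_config(path), "unknown config section")

  writeLines(c("channels:", "  A: well", "  B: well", "  F1: fresh_media",
               "  WST: waste"), path)
  cfg <- read_br_config(path)
  expect_equal(cfg$fresh_channel, "F1")
  expect_equal(sum(cfg$channels$role == "well"), 2)
})
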