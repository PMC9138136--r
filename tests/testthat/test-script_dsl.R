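test_that("parsing handles the full command set, case and comments", {
  s <- parse_script(c("# refresh protocol", "", "vol 2", "WAIT 06:00:00",
                      "Dir b", "Ch W1", "Loop 3", "Goto 2", "Stir A",
                      "Start", "Msgbox cycle done"))
  expect_s3_class(s, "br_script")
  expect_length(s, 9)
  ops <- vapply(s$commands, `[[`, character(1), "opcode")
  expect_equal(ops, c("VOL", "WAIT", "DIR", "CH", "LOOP", "GOTO", "STIR",
                      "START", "MSGBOX"))
  expect_identical(s$commands[[1]]$arg, 2)          # mL
  expect_identical(s$commands[[2]]$arg, 21600)      # 6 h in seconds
  expect_identical(s$commands[[3]]$arg, "B")
  expect_identical(s$commands[[9]]$arg, "cycle done")
  expect_length(parse_script(""), 0)
})

test_that("malformed commands give parse errors naming line and field", {
  expect_error(parse_script("Dir X"), "line 1.*direction")
  expect_error(parse_script(c("Vol 2", "Frobnicate 1")), "line 2.*unknown opcode")
  expect_error(parse_script("Vol many"), "field volume")
  expect_error(parse_script("Vol -1"), "field volume")
  expect_error(parse_script("Wait 1:99:00"), "not hh:mm:ss")
  expect_error(parse_script("Loop 0"), "field count")
  expect_error(parse_script("Loop 2.5"), "field count")
  expect_error(parse_script("Goto -3"), "field target")
  expect_error(parse_script("Start now"), "takes no value")
})

test_that("format/parse round-trips random scripts", {
  set.seed(101)
  for (i in 1:50) {
    s <- parse_script(random_script_text())
    s2 <- parse_script(format_script(s))
    expect_identical(s2$commands, s$commands)
  }
  # long Wait survives the hh:mm:ss formatter (hours > 99 allowed)
  s <- parse_script("Wait 1000:00:00")
  expect_identical(parse_script(format_script(s))$commands, s$commands)
})

test_that("validation flags dangling jumps, capacity and channel problems", {
  cfg <- br_config()
  expect_equal(nrow(validate_script(
    parse_script(c("Vol 2", "Dir B", "Ch W1", "Start")), cfg)), 0)

  d <- validate_script(parse_script("Goto 5"), cfg)
  expect_equal(d$severity, "error")
  expect_match(d$message, "unresolved Goto target 5")

  d <- validate_script(parse_script(c("Vol 12", "Dir B", "Ch W1", "Start")), cfg)
  expect_match(d$message, "Vol 12 exceeds capacity 10")

  d <- validate_script(parse_script("Start"), cfg)
  expect_match(d$message, "Start before any Vol/Dir/Ch")

  d <- validate_script(parse_script(c("Ch NOPE", "Stir FRESH")), cfg)
  expect_equal(nrow(d), 2)  # unknown channel; FRESH has no stirrer

  d <- validate_script(parse_script(c("Loop 2", "Loop 3", "Msgbox x", "Goto 3")), cfg)
  expect_equal(d$severity, "warning")
  expect_match(d$message, "nesting unsupported")
})

test_that("step executes single-command semantics", {
  cfg <- br_config()
  bus <- null_bus(cfg)

  # Wait advances the clock by the parsed duration
  res <- step_script(new_interp_state(), parse_script("Wait 00:10:00"), bus, cfg)
  expect_equal(res$state$clock_s, 600)
  expect_equal(res$state$pc, 2L)
  expect_null(res$events)

  # Start emits one pump event carrying the registers
  s <- parse_script(c("Vol 2", "Dir B", "Ch W1", "Start"))
  st <- new_interp_state()
  for (i in 1:4) { res <- step_script(st, s, bus, cfg); st <- res$state }
  expect_equal(res$events$event_type, "pump")
  expect_equal(res$events$volume_ml, 2)
  expect_equal(res$events$direction, "B")
  expect_equal(res$events$channel, "W1")
  expect_equal(st$clock_s, 60)  # 2 mL at 2 mL/min

  # Start without a channel is a runtime error
  s <- parse_script(c("Vol 2", "Dir B", "Start"))
  st <- new_interp_state()
  for (i in 1:2) st <- step_script(st, s, bus, cfg)$state
  expect_error(step_script(st, s, bus, cfg), "no channel selected")
})

test_that("Loop/Goto gives n total passes and Stir toggles", {
  tr <- run_script(parse_script(c("Loop 3", "Stir A", "Goto 2")))
  stirs <- tr[tr$event_type == "stir", ]
  expect_equal(nrow(stirs), 3)
  expect_equal(stirs$detail, c("ON", "OFF", "ON"))  # 3 toggles from off
  final <- attr(tr, "final_state")
  expect_true(final$stirrers[["A"]])

  # Goto with a drained counter falls through (no infinite loop)
  tr <- run_script(parse_script(c("Loop 1", "Msgbox once", "Goto 2")))
  expect_equal(sum(tr$event_type == "message"), 1)
})

test_that("runaway scripts hit the max-steps guard instead of hanging", {
  cfg <- br_config(max_steps = 500)
  # unconditional backward jump re-armed by a fresh Loop every pass
  s <- parse_script(c("Loop 2", "Goto 1"))
  expect_error(run_script(s, null_bus(cfg), cfg), "max-steps guard")
})

test_that("run returns a complete, monotone, empty-safe trace", {
  expect_equal(nrow(run_script(parse_script(""))), 0)
  expect_equal(attr(run_script(parse_script("")), "final_clock_s"), 0)

  tr <- run_script(parse_script("Msgbox done"))
  expect_equal(tr$event_type, "message")
  expect_equal(tr$detail, "done")

  set.seed(202)
  for (i in 1:25) {
    tr <- run_script(parse_script(random_script_text()))
    expect_false(is.unsorted(tr$elapsed_s))
  }
})

test_that("interpreter matches the brute-force reference on random scripts", {
  cfg <- br_config()
  set.seed(303)
  for (i in 1:200) {
    s <- parse_script(random_script_text())
    mine <- run_script(s, null_bus(cfg), cfg)
    ref <- oracle_run(s, cfg)
    expect_identical(bare_trace(mine), bare_trace(ref))
    expect_identical(attr(mine, "final_clock_s"), attr(ref, "clock"))
  }
})

test_that("event traces round-trip through CSV", {
  tr <- run_script(parse_script(c("Vol 1", "Dir F", "Ch W1", "Start",
                                  "Stir W1", "Msgbox hello world")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_trace(tr, path)
  expect_equal(read_event_trace(path), bare_trace(tr))
})
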