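#' The bioreactor protocol language
#'
#' Protocols are plain-text scripts, one command per line, in a nine-command
#' language: `Loop n` (arm a repeat counter), `Vol v` (set the syringe volume
#' in mL), `Goto l` (jump, consuming one Loop pass), `Wait hh:mm:ss` (delay),
#' `Dir F|B` (pump direction, Forward = dispense / Backward = withdraw),
#' `Ch c` (select a flow channel), `Stir c` (toggle a well stirrer), `Start`
#' (run the pump with the current Vol/Dir/Ch registers) and `Msgbox text`
#' (log a message). Opcodes are case-insensitive; blank lines and lines
#' starting with `#` are ignored.
#'
#' Loop/Goto convention: `Loop n` arms a counter with n-1 remaining passes;
#' the next `Goto` executed jumps while the counter is positive (decrementing
#' it) and falls through once it reaches zero, so the block between `Loop`'s
#' successor and the `Goto` runs exactly n times. There is a single loop
#' register; nesting is unsupported and the validator warns about it.
#'
#' @name script-dsl
NULL

OPCODES <- c("LOOP", "VOL", "GOTO", "WAIT", "DIR", "CH", "STIR", "START", "MSGBOX")

parse_hms <- function(value, line) {
  m <- regmatches(value, regexec("^([0-9]+):([0-5][0-9]):([0-5][0-9])$", value))[[1]]
  if (length(m) != 4L)
    stop(sprintf("parse error at line %d, field duration: '%s' is not hh:mm:ss",
                 line, value), call. = FALSE)
  as.numeric(m[2]) * 3600 + as.numeric(m[3]) * 60 + as.numeric(m[4])
}

format_hms <- function(seconds) {
  sprintf("%02d:%02d:%02d", seconds %/% 3600, (seconds %% 3600) %/% 60,
          round(seconds %% 60))
}

parse_command <- function(opcode_raw, value, line) {
  opcode <- toupper(opcode_raw)
  if (!opcode %in% OPCODES)
    stop(sprintf("parse error at line %d: unknown opcode '%s'", line, opcode_raw),
         call. = FALSE)
  arg <- switch(opcode,
    LOOP = {
      n <- suppressWarnings(as.numeric(value))
      if (is.na(n) || n < 1 || n != round(n))
        stop(sprintf("parse error at line %d, field count: Loop needs an integer >= 1, got '%s'",
                     line, value), call. = FALSE)
      as.integer(n)
    },
    VOL = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v) || v <= 0)
        stop(sprintf("parse error at line %d, field volume: Vol needs a number > 0 mL, got '%s'",
                     line, value), call. = FALSE)
      v
    },
    GOTO = {
      l <- suppressWarnings(as.numeric(value))
      if (is.na(l) || l < 1 || l != round(l))
        stop(sprintf("parse error at line %d, field target: Goto needs a positive line number, got '%s'",
                     line, value), call. = FALSE)
      as.integer(l)
    },
    WAIT = parse_hms(value, line),
    DIR = {
      d <- toupper(value)
      if (!d %in% c("F", "B"))
        stop(sprintf("parse error at line %d, field direction: expected F or B, got '%s'",
                     line, value), call. = FALSE)
      d
    },
    CH = ,
    STIR = {
      if (!nzchar(value) || grepl("\\s", value))
        stop(sprintf("parse error at line %d, field channel: expected a single channel id, got '%s'",
                     line, value), call. = FALSE)
      value
    },
    START = {
      if (nzchar(value))
        stop(sprintf("parse error at line %d: Start takes no value, got '%s'",
                     line, value), call. = FALSE)
      NULL
    },
    MSGBOX = value)
  structure(list(opcode = opcode, arg = arg), class = "br_command")
}

#' Parse a protocol script
#'
#' @param text Script source: a single string (possibly multi-line) or a
#'   character vector of lines.
#' @return A `br_script`: commands numbered 1..n in file order, with the raw
#'   source retained. Empty input gives a zero-line script.
#' @seealso [format_script()], [validate_script()], [run_script()]
#' @export
parse_script <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  commands <- list()
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    sp <- regexpr("\\s", line)
    if (sp == -1L) {
      opcode_raw <- line; value <- ""
    } else {
      opcode_raw <- substr(line, 1, sp - 1L)
      value <- trimws(substr(line, sp + 1L, nchar(line)))
    }
    commands[[length(commands) + 1L]] <- parse_command(opcode_raw, value, i)
  }
  structure(list(commands = commands, source_text = paste(text, collapse = "\n")),
            class = "br_script")
}

#' Render a script back to canonical text
#'
#' One command per line, title-case opcodes, `Wait` durations as hh:mm:ss.
#' Comments and blank lines of the original source are not reproduced;
#' `parse_script(format_script(s))` yields a script whose commands are
#' identical to `s`'s.
#'
#' @param script A `br_script`.
#' @return A single string.
#' @export
format_script <- function(script) {
  stopifnot(inherits(script, "br_script"))
  lines <- vapply(script$commands, function(cmd) {
    op <- paste0(substr(cmd$opcode, 1, 1), tolower(substr(cmd$opcode, 2, 99)))
    val <- switch(cmd$opcode,
      WAIT = format_hms(cmd$arg),
      START = NULL,
      VOL = format(cmd$arg, scientific = FALSE, trim = TRUE),
      as.character(cmd$arg))
    if (is.null(val) || !nzchar(val)) op else paste(op, val)
  }, character(1))
  paste(lines, collapse = "\n")
}

#' @export
print.br_script <- function(x, ...) {
  n <- length(x$commands)
  cat(sprintf("protocol script: %d line%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    txt <- strsplit(format_script(x), "\n")[[1]]
    cat(sprintf("%3d  %s", seq_len(n), txt), sep = "\n")
  }
  invisible(x)
}

#' @export
length.br_script <- function(x) length(x$commands)

diagnostic <- function(line, severity, message) {
  data.frame(line = line, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a script against a device configuration
#'
#' Static checks, returned as a diagnostics data frame (`line`, `severity`,
#' `message`), never raised as errors: unresolved `Goto` targets; `Vol`
#' exceeding the syringe capacity; any `Start` not preceded (anywhere earlier
#' in line order) by a `Vol`, a `Dir` and a `Ch`; `Ch`/`Stir` channel ids
#' absent from the channel table; and a warning for a second `Loop` armed
#' before the previous counter can have drained.
#'
#' @param script A `br_script`.
#' @param config A [br_config()].
#' @return Diagnostics data frame; zero rows means the script is clean.
#' @export
validate_script <- function(script, config = br_config()) {
  stopifnot(inherits(script, "br_script"))
  diags <- list()
  add <- function(d) diags[[length(diags) + 1L]] <<- d
  n <- length(script$commands)
  ops <- vapply(script$commands, `[[`, character(1), "opcode")
  chan_ids <- config$channels$channel
  well_ids <- config$channels$channel[config$channels$role == "well"]

  seen_vol <- seen_dir <- seen_ch <- FALSE
  loop_armed <- FALSE
  for (i in seq_len(n)) {
    cmd <- script$commands[[i]]
    switch(cmd$opcode,
      GOTO = {
        if (cmd$arg > n)
          add(diagnostic(i, "error",
                         sprintf("unresolved Goto target %d (script has %d lines)",
                                 cmd$arg, n)))
        loop_armed <- FALSE
      },
      VOL = {
        if (cmd$arg > config$pump$capacity_ml)
          add(diagnostic(i, "error",
                         sprintf("Vol %s exceeds capacity %s",
                                 format(cmd$arg), format(config$pump$capacity_ml))))
        seen_vol <- TRUE
      },
      DIR = seen_dir <- TRUE,
      CH = {
        if (!cmd$arg %in% chan_ids)
          add(diagnostic(i, "error",
                         sprintf("unknown channel '%s'", cmd$arg)))
        seen_ch <- TRUE
      },
      STIR = {
        if (!cmd$arg %in% well_ids)
          add(diagnostic(i, "error",
                         sprintf("unknown stirrer channel '%s'", cmd$arg)))
      },
      START = {
        missing <- c("Vol", "Dir", "Ch")[!c(seen_vol, seen_dir, seen_ch)]
        if (length(missing))
          add(diagnostic(i, "error",
                         sprintf("Start before any %s command",
                                 paste(missing, collapse = "/"))))
      },
      LOOP = {
        if (loop_armed)
          add(diagnostic(i, "warning",
                         "second Loop armed before the previous counter drained (nesting unsupported)"))
        loop_armed <- TRUE
      },
      NULL)
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(line = integer(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Fresh interpreter state
#'
#' Program counter at line 1, no pending volume/direction/channel, loop
#' counter 0, all stirrers off, clock 0.
#' @return An `interp_state` list.
#' @export
new_interp_state <- function() {
  structure(list(pc = 1L, pending_volume = 0, direction = NA_character_,
                 channel = NA_character_, stirrers = logical(0),
                 loop_counter = 0L, clock_s = 0, steps = 0L),
            class = "interp_state")
}

make_event <- function(clock_s, event_type, channel = NA_character_,
                       volume_ml = NA_real_, direction = NA_character_,
                       detail = "") {
  data.frame(elapsed_s = clock_s, event_type = event_type, channel = channel,
             volume_ml = volume_ml, direction = direction, detail = detail,
             stringsAsFactors = FALSE)
}

#' A device bus that drives nothing
#'
#' Satisfies the device-bus contract with no-ops: useful for dry-running and
#' timing scripts without a simulated culture. `run_pump` still reports the
#' transfer duration implied by the configured default flow rate.
#'
#' @param config A [br_config()].
#' @return An environment with the bus contract functions.
#' @export
null_bus <- function(config = br_config()) {
  bus <- new.env(parent = emptyenv())
  bus$set_channel <- function(channel) invisible(channel)
  bus$set_stirrer <- function(channel, on) invisible(on)
  bus$elapse <- function(dt_s) invisible(NULL)
  bus$run_pump <- function(volume_ml, direction, channel,
                           rate_ml_min = config$pump$default_rate_ml_min) {
    volume_ml / rate_ml_min * 60
  }
  bus
}

#' Execute a single command
#'
#' Advances the interpreter by exactly one instruction, returning the
#' successor state and any device events emitted (time-stamped with the clock
#' value at which the command began). See the package DSL reference
#' (`?script-dsl`) for the Loop/Goto convention. `Start` runs the pump
#' through the bus with the current registers and advances the clock by the
#' transfer duration; `Wait` advances the clock (and the bus, via
#' `bus$elapse`) by its delay; `Msgbox` logs without blocking.
#'
#' @param state An `interp_state` with `pc` inside the script.
#' @param script A validated `br_script`.
#' @param bus A device bus ([simulated_bus()] or [null_bus()]).
#' @param config A [br_config()].
#' @return List with elements `state` and `events` (data frame, possibly
#'   zero-row).
#' @export
step_script <- function(state, script, bus, config = br_config()) {
  stopifnot(inherits(state, "interp_state"),
            state$pc >= 1L, state$pc <= length(script$commands))
  cmd <- script$commands[[state$pc]]
  line <- state$pc
  state$steps <- state$steps + 1L
  if (state$steps > config$max_steps)
    stop(sprintf("max-steps guard: %d instructions executed without terminating (line %d)",
                 config$max_steps, line))
  events <- NULL
  next_pc <- state$pc + 1L

  switch(cmd$opcode,
    LOOP = {
      state$loop_counter <- cmd$arg - 1L
    },
    GOTO = {
      if (state$loop_counter > 0L) {
        state$loop_counter <- state$loop_counter - 1L
        next_pc <- cmd$arg
      }
    },
    WAIT = {
      bus$elapse(cmd$arg)
      state$clock_s <- state$clock_s + cmd$arg
    },
    DIR = state$direction <- cmd$arg,
    VOL = state$pending_volume <- cmd$arg,
    CH = {
      bus$set_channel(cmd$arg)
      state$channel <- cmd$arg
      events <- make_event(state$clock_s, "channel", channel = cmd$arg)
    },
    STIR = {
      on <- !isTRUE(state$stirrers[cmd$arg])
      state$stirrers[cmd$arg] <- on
      bus$set_stirrer(cmd$arg, on)
      events <- make_event(state$clock_s, "stir", channel = cmd$arg,
                           detail = if (on) "ON" else "OFF")
    },
    START = {
      if (is.na(state$channel))
        stop(sprintf("runtime error at line %d: no channel selected", line))
      if (is.na(state$direction))
        stop(sprintf("runtime error at line %d: no pump direction set", line))
      if (state$pending_volume <= 0)
        stop(sprintf("runtime error at line %d: no volume set", line))
      duration <- bus$run_pump(state$pending_volume, state$direction,
                               state$channel)
      events <- make_event(state$clock_s, "pump", channel = state$channel,
                           volume_ml = state$pending_volume,
                           direction = state$direction,
                           detail = sprintf("%gs", duration))
      state$clock_s <- state$clock_s + duration
    },
    MSGBOX = {
      events <- make_event(state$clock_s, "message", detail = cmd$arg)
    })

  state$pc <- next_pc
  list(state = state, events = events)
}

#' Run a script to completion
#'
#' Steps the interpreter until the program counter passes the last line,
#' collecting every emitted device event into a time-stamped trace. The
#' configured `max_steps` guard turns runaway loops into an error rather than
#' a hang. Errors raised mid-run are annotated with the offending line.
#'
#' @inheritParams step_script
#' @param state Optional starting state (defaults to [new_interp_state()]).
#' @return The event trace: a data frame with columns
#'   `elapsed_s, event_type, channel, volume_ml, direction, detail`, with
#'   attributes `final_state` (the closing `interp_state`) and `final_clock_s`.
#' @export
run_script <- function(script, bus = null_bus(config), config = br_config(),
                       state = new_interp_state()) {
  stopifnot(inherits(script, "br_script"))
  n <- length(script$commands)
  chunks <- list()
  while (state$pc >= 1L && state$pc <= n) {
    res <- step_script(state, script, bus, config)
    state <- res$state
    if (!is.null(res$events)) chunks[[length(chunks) + 1L]] <- res$events
  }
  trace <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(elapsed_s = numeric(0), event_type = character(0),
               channel = character(0), volume_ml = numeric(0),
               direction = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  rownames(trace) <- NULL
  attr(trace, "final_state") <- state
  attr(trace, "final_clock_s") <- state$clock_s
  trace
}

#' Write / read an event trace CSV
#'
#' Columns: `elapsed_s,event_type,channel,volume_ml,direction,detail`.
#' @param trace Event trace from [run_script()].
#' @param path CSV path.
#' @export
write_event_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_event_trace
#' @export
read_event_trace <- function(path) {
  utils::read.csv(path, colClasses = c(elapsed_s = "numeric",
                                       event_type = "character",
                                       channel = "character",
                                       volume_ml = "numeric",
                                       direction = "character",
                                       detail = "character"))
}
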