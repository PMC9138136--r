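# Independent reference evaluator for protocol scripts: a plain line-by-line
# walk over the command list with an explicit jump table, sharing no code
# with the package interpreter. Uses the same null-bus timing convention
# (pump duration = volume / default rate) so traces are directly comparable.
oracle_run <- function(script, config = br_config()) {
  cmds <- script$commands
  jump <- vapply(cmds, function(c) if (c$opcode == "GOTO") c$arg else NA_integer_,
                 integer(1))
  pc <- 1L; clock <- 0; loop_left <- 0L
  vol <- 0; dir <- NA_character_; ch <- NA_character_
  stir_on <- character(0)
  steps <- 0L
  out <- data.frame(elapsed_s = numeric(0), event_type = character(0),
                    channel = character(0), volume_ml = numeric(0),
                    direction = character(0), detail = character(0),
                    stringsAsFactors = FALSE)
  emit <- function(type, channel = NA_character_, volume = NA_real_,
                   direction = NA_character_, detail = "") {
    out[nrow(out) + 1L, ] <<- list(clock, type, channel, volume, direction, detail)
  }
  repeat {
    if (pc < 1L || pc > length(cmds)) break
    steps <- steps + 1L
    if (steps > config$max_steps) stop("oracle: max steps exceeded")
    cmd <- cmds[[pc]]
    advance <- TRUE
    if (cmd$opcode == "LOOP") {
      loop_left <- cmd$arg - 1L
    } else if (cmd$opcode == "GOTO") {
      if (loop_left > 0L) { loop_left <- loop_left - 1L; pc <- jump[pc]; advance <- FALSE }
    } else if (cmd$opcode == "WAIT") {
      clock <- clock + cmd$arg
    } else if (cmd$opcode == "DIR") {
      dir <- cmd$arg
    } else if (cmd$opcode == "VOL") {
      vol <- cmd$arg
    } else if (cmd$opcode == "CH") {
      ch <- cmd$arg
      emit("channel", channel = cmd$arg)
    } else if (cmd$opcode == "STIR") {
      if (cmd$arg %in% stir_on) {
        stir_on <- setdiff(stir_on, cmd$arg); emit("stir", cmd$arg, detail = "OFF")
      } else {
        stir_on <- c(stir_on, cmd$arg); emit("stir", cmd$arg, detail = "ON")
      }
    } else if (cmd$opcode == "START") {
      if (is.na(ch)) stop("oracle: no channel")
      dur <- vol / config$pump$default_rate_ml_min * 60
      emit("pump", ch, vol, dir, sprintf("%gs", dur))
      clock <- clock + dur
    } else if (cmd$opcode == "MSGBOX") {
      emit("message", detail = cmd$arg)
    }
    if (advance) pc <- pc + 1L
  }
  attr(out, "clock") <- clock
  out
}
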