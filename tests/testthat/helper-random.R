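# Random well-formed protocol scripts for property tests: at most n_max
# lines, Loop counts <= 3, Waits <= 10 s. Scripts always open with
# Vol/Dir/Ch so any later Start has its registers set, and any Loop/Goto
# pair is generated together (Goto jumps back to the first line of the loop
# body), so every generated script terminates and passes validation.
random_script_text <- function(n_max = 10) {
  head <- c(sprintf("Vol %g", sample(c(0.5, 1, 2), 1)),
            sample(c("Dir B", "Dir F"), 1),
            sprintf("Ch %s", sample(c("W1", "W2", "FRESH"), 1)))
  rand_cmd <- function() {
    switch(sample.int(5, 1),
           sprintf("Wait 00:00:%02d", sample(0:9, 1)),
           sprintf("Stir W%d", sample.int(3, 1)),
           sprintf("Msgbox note%d", sample.int(50, 1)),
           sprintf("Ch %s", sample(c("W1", "W2", "W3", "WASTE"), 1)),
           "Start")
  }
  budget <- n_max - length(head)
  with_loop <- runif(1) < 0.6 && budget >= 3
  if (with_loop) {
    body_n <- sample.int(budget - 2, 1)
    body <- replicate(body_n, rand_cmd())
    target <- length(head) + 2L  # first line of the loop body
    c(head, sprintf("Loop %d", sample.int(3, 1)), body, sprintf("Goto %d", target))
  } else {
    c(head, if (budget > 0) replicate(sample.int(budget, 1), rand_cmd()))
  }
}

# Strip run_script's attributes so traces compare cleanly against the oracle.
bare_trace <- function(trace) {
  attr(trace, "final_state") <- NULL
  attr(trace, "final_clock_s") <- NULL
  attr(trace, "clock") <- NULL
  rownames(trace) <- NULL
  trace
}
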