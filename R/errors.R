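# Classed conditions; every detector failure names its pipeline stage so the
# orchestrator (and CLI) can report which stage failed.

abort <- function(msg, class, stage = NULL, ...) {
  stop(errorCondition(msg, ..., stage = stage,
                      class = c(class, "aorticroot_error", "error", "condition")))
}

#' @noRd
condition_stage <- function(e) {
  st <- e$stage
  if (is.null(st)) NA_character_ else st
}
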