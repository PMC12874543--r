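# RNG hygiene: functions that accept an explicit `seed` must not disturb
# the caller's random stream, otherwise replication loops that seed once
# at the top would see the same data over and over. Callers do:
#   old <- push_seed(seed); on.exit(pop_seed(old))
push_seed <- function(seed) {
  if (is.null(seed)) return(NULL)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  if (is.null(old)) list(unset = TRUE) else list(unset = FALSE, state = old)
}

pop_seed <- function(old) {
  if (is.null(old)) return(invisible())
  if (old$unset) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old$state, envir = globalenv())
  }
  invisible()
}
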