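# Shared fixtures and independent oracles used across the test files.

# a small hand-built dataset with known truth
toy_data <- function() {
  replicate_data(id = c("A", "B", "C", "D", "E"),
                 n = c(4L, 3L, 6L, 1L, 5L),
                 s = c(3L, 0L, 3L, 1L, 4L),
                 t_true = c(1L, 0L, 0L, 1L, 1L))
}

# brute-force risk-minimizing decision for P(T = 1) = v under a loss table:
# the oracle against which the threshold formulas are checked
oracle_decision <- function(v, loss) {
  risks <- c(`0` = v * loss$c,                       # decide 0
             `0.5` = (1 - v) * loss$a + v * loss$d,  # indecision
             `1` = (1 - v) * loss$b)                 # decide 1
  best <- min(risks)
  cand <- as.numeric(names(risks)[risks <= best + 1e-12])
  if (0.5 %in% cand) 0.5 else cand[which.min(risks[as.character(cand)])]
}

# random loss specifications satisfying the indecision condition
random_indecision_loss <- function() {
  repeat {
    l <- loss_spec(a = runif(1, 0.01, 0.6), b = runif(1, 0.3, 2),
                   c = runif(1, 0.3, 2), d = runif(1, 0.01, 0.6))
    if (indecision_condition(l)) return(l)
  }
}

# lean sampler settings for repeated fits inside sweeps
lean_bayes <- list(n_iter = 1500L, burn_in = 500L, chains = 1L)
lean_em <- list(n_starts = 4L, seed = 1L)
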