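# Independent oracles, coded separately from the package internals.

# per-trial Bernoulli log-likelihood, summed in an explicit loop
# (log1p for the incorrect-response term so the comparison with the
# package is not decided by sub-ulp rounding in near-flat regions)
oracle_loglik <- function(history, alpha, beta, gamma) {
  total <- 0
  for (i in seq_len(nrow(history))) {
    p <- gamma + (1 - gamma) / (1 + exp(-beta * (history$level[i] - alpha)))
    total <- total + if (history$correct[i]) log(p) else log1p(-p)
  }
  total
}

# exhaustive argmax over grid midpoints, ties to the lowest midpoint
oracle_select_index <- function(alphas, beta, gamma, history) {
  ll <- vapply(alphas, function(a) oracle_loglik(history, a, beta, gamma), 0)
  which(ll == max(ll))[1]
}

# random trial history on the 0-100 coherence scale
random_history <- function(n, hemifield = "left") {
  trial_record(level = runif(n, 0, 100),
               correct = runif(n) < 0.7,
               hemifield = hemifield)
}

# a difference vector with exactly the requested mean and SEM
diff_vector <- function(mean, sem, n, seed = 1) {
  set.seed(seed)
  z <- as.numeric(scale(rnorm(n)))       # exact mean 0, sd 1
  mean + sem * sqrt(n) * z
}

# two-pass mean / SEM computed independently
oracle_mean_sem <- function(y) {
  m <- sum(y) / length(y)
  s <- sqrt(sum((y - m)^2) / (length(y) - 1))
  c(mean = m, sem = s / sqrt(length(y)))
}

# run one single-hemifield adaptive track against a simulated observer
run_recovery_track <- function(true_level, n_trials, seed) {
  obs <- sim_observer(psychfun(true_level - 1.301175))
  cfg <- session_config(trials_per_hemifield = n_trials,
                        blocks = 1, seed = seed)
  fit <- mlp_session(obs, obs, cfg)
  coef(fit)   # two independent track estimates of the same observer
}
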