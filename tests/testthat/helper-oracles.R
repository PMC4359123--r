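# Independent reference implementations used as oracles. These are written
# as plainly as possible (scalar loops, direct numerical integration) and
# deliberately share no code with the package internals they check.

# Brute-force marginal log-likelihood of the random-effects 3AFC model for
# one response table: trapezoid integration over ability on a wide grid.
brute_force_loglik <- function(data, beta, mu, var_alpha, n_grid = 40001) {
  sigma <- sqrt(var_alpha)
  a <- seq(mu - 10 * sigma, mu + 10 * sigma, length.out = n_grid)
  h <- a[2] - a[1]
  total <- 0
  for (s in unique(data$subject_id)) {
    rows <- data[data$subject_id == s, ]
    y <- as.integer(rows$response == "correct")
    lik <- vapply(a, function(ai) {
      p <- 1 / 3 + (2 / 3) * stats::plogis(ai - beta * rows$step)
      prod(ifelse(y == 1, p, 1 - p))
    }, numeric(1))
    total <- total + log(sum(lik * stats::dnorm(a, mu, sigma)) * h)
  }
  total
}

# Reference single-subject staircase: a readable scalar state machine
# following the published rules (start weak, confirmation presentation after
# a correct, two consecutive corrects -> one step weaker, incorrect -> one
# step stronger, reversal on direction change, stop at `nstop` reversals).
# `responses` is a logical vector consumed one presentation at a time.
oracle_staircase <- function(responses, start, lo = -Inf, hi = 16,
                             nstop = 7, kscore = 4, cap = 60) {
  cur <- start
  dir <- 0L
  consec <- 0L
  revs <- numeric(0)
  steps_seen <- numeric(0)
  for (t in seq_len(cap)) {
    if (t > length(responses)) break
    steps_seen <- c(steps_seen, cur)
    y <- responses[t]
    if (y) {
      consec <- consec + 1L
      if (consec < 2L) next
      d <- 1L
    } else {
      consec <- 0L
      d <- -1L
    }
    target <- cur + d
    if (target < lo || target > hi) { consec <- 0L; next }
    if (dir != 0L && dir != d) {
      revs <- c(revs, cur)
      if (length(revs) == nstop) {
        return(list(reversals = revs, score = mean(utils::tail(revs, kscore)),
                    presentations = steps_seen, terminated = "reversals"))
      }
    }
    cur <- target
    dir <- d
    consec <- 0L
  }
  list(reversals = revs, score = NA_real_, presentations = steps_seen,
       terminated = "cap")
}

# Small simulated constant-stimuli cohort used by several tests.
make_cohort <- function(n = 60, steps = 1:16, pop = population_preset("normosmic"),
                        seed = 4242) {
  thresholds <- sample_thresholds(pop, n, seed = seed)
  responses <- simulate_constant_stimuli(thresholds, pop$beta,
                                         constant_stimuli(steps),
                                         seed = seed + 1)
  list(thresholds = thresholds, responses = responses, pop = pop)
}
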