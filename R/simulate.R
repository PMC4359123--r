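#' Simulate a constant-stimuli administration
#'
#' Draws one Bernoulli response per subject and presentation from the 3AFC
#' response model: a subject with true threshold `t` has ability
#' `alpha = beta * t` and answers correctly with probability
#' `p_correct(alpha, step, beta)`. Every subject receives the same multiset
#' of steps.
#'
#' @param thresholds Numeric vector of true thresholds (step units), one per
#'   subject.
#' @param beta Positive response-curve slope.
#' @param protocol An [constant_stimuli()] protocol.
#' @param seed Optional integer for a reproducible draw.
#' @return A response table: tibble with columns `subject_id`,
#'   `presentation_index`, `step`, `target_position` (NA when the protocol
#'   carries no schedule) and `response` (`"correct"` / `"incorrect"`).
#' @examples
#' pop <- population_preset("normosmic")
#' tr <- sample_thresholds(pop, 20, seed = 1)
#' simulate_constant_stimuli(tr, pop$beta, constant_stimuli(1:16), seed = 2)
#' @export
simulate_constant_stimuli <- function(thresholds, beta, protocol, seed = NULL) {
  stopifnot(inherits(protocol, "olf_constant"))
  check_beta(beta)
  if (length(thresholds) == 0) {
    abort("`thresholds` must be non-empty.", class = "olf_invalid_parameter")
  }
  local_rng(seed)
  sim <- sim_constant_engine(thresholds, beta, protocol)
  tp <- protocol$target_positions
  tibble(
    subject_id = sim$subject,
    presentation_index = sim$presentation,
    step = sim$step,
    target_position = if (is.null(tp)) NA_integer_ else tp[sim$presentation],
    response = ifelse(sim$y == 1L, "correct", "incorrect")
  )
}

# Fast path shared with the replication engine: plain vectors, no tibble.
sim_constant_engine <- function(thresholds, beta, protocol) {
  n <- length(thresholds)
  J <- length(protocol$steps)
  subject <- rep(seq_len(n), each = J)
  presentation <- rep(seq_len(J), times = n)
  if (protocol$order_policy == "random_per_subject") {
    ord <- unlist(lapply(seq_len(n), function(i) sample.int(J)), use.names = FALSE)
    step <- protocol$steps[ord]
  } else {
    step <- rep(protocol$steps, times = n)
  }
  p <- p_correct(beta * thresholds[subject], step, beta)
  y <- as.integer(runif(n * J) < p)
  list(subject = subject, presentation = presentation, step = step, y = y)
}

#' Simulate staircase administrations
#'
#' Runs the adaptive single-staircase procedure for each subject: start at a
#' random choice among `protocol$start_steps`; after a correct response the
#' same step is re-presented; after two consecutive correct responses the
#' test moves one step weaker; after any incorrect response it moves one step
#' stronger. A reversal is logged at the step being presented when the
#' movement direction flips (the first movement only establishes direction).
#' Boundary behaviour follows `protocol$clamp`: a blocked move re-presents
#' the same step and is not a reversal. Runs stop at
#' `protocol$reversals_to_stop` reversals, or are censored at
#' `protocol$max_presentations`.
#'
#' @param thresholds Numeric vector of true thresholds (step units).
#' @param beta Positive response-curve slope.
#' @param protocol A [staircase()] protocol.
#' @param seed Optional integer for a reproducible draw.
#' @param responder Optional deterministic response source for testing: a
#'   `function(subject_index, step, presentation_number)` returning a logical
#'   vector (`TRUE` = correct). When supplied, `thresholds` only sets the
#'   number of subjects and no random responses are drawn.
#' @param keep_history Keep the full per-presentation history as a
#'   list-column (default `TRUE`; turn off for large simulations).
#' @return A tibble with one row per subject: `subject_id`, `threshold`,
#'   `score` (mean of the last `reversals_to_score` reversal steps; censored
#'   runs fall back to the available reversals or the final step),
#'   `n_reversals`, `n_presentations`, `terminated_by` (`"reversals"` or
#'   `"cap"`), `censored`, `reversal_steps` (list-column) and, if requested,
#'   `history` (list-column of step/response tibbles).
#' @export
simulate_staircase <- function(thresholds, beta, protocol = staircase(),
                               seed = NULL, responder = NULL,
                               keep_history = TRUE) {
  stopifnot(inherits(protocol, "olf_staircase"))
  check_beta(beta)
  if (length(thresholds) == 0) {
    abort("`thresholds` must be non-empty.", class = "olf_invalid_parameter")
  }
  local_rng(seed)
  eng <- sim_staircase_engine(thresholds, beta, protocol, responder = responder,
                              keep_history = keep_history)
  n <- length(thresholds)
  out <- tibble(
    subject_id = seq_len(n),
    threshold = as.numeric(thresholds),
    score = eng$score,
    n_reversals = eng$n_reversals,
    n_presentations = eng$n_presentations,
    terminated_by = eng$terminated_by,
    censored = eng$censored,
    reversal_steps = lapply(seq_len(n), function(i) {
      k <- eng$n_reversals[i]
      if (k == 0) numeric(0) else eng$reversals[i, seq_len(k)]
    })
  )
  if (keep_history) {
    out$history <- lapply(seq_len(n), function(i) {
      k <- eng$n_presentations[i]
      tibble(step = eng$step_hist[i, seq_len(k)],
             response = ifelse(eng$resp_hist[i, seq_len(k)] == 1L,
                               "correct", "incorrect"))
    })
  }
  out
}

# Vectorized state machine over all subjects at once; one loop iteration per
# presentation round.
sim_staircase_engine <- function(thresholds, beta, protocol, responder = NULL,
                                 keep_history = FALSE) {
  n <- length(thresholds)
  clamp <- protocol$clamp %||% "ceiling"
  lo <- if (clamp == "both") min(protocol$step_set) else -Inf
  hi <- if (clamp == "none") Inf else max(protocol$step_set)
  nstop <- protocol$reversals_to_stop
  cap <- protocol$max_presentations
  alpha <- beta * thresholds

  # index-based draw so a single candidate start step is used as-is
  starts <- protocol$start_steps
  cur <- starts[sample.int(length(starts), n, replace = TRUE)]
  dir <- integer(n)      # 0 none, +1 moving weaker, -1 moving stronger
  consec <- integer(n)   # consecutive corrects at the current step
  nrev <- integer(n)
  revs <- matrix(NA_real_, n, nstop)
  active <- rep(TRUE, n)
  npres <- integer(n)
  if (keep_history) {
    step_hist <- matrix(NA_real_, n, cap)
    resp_hist <- matrix(NA_integer_, n, cap)
  }

  for (t in seq_len(cap)) {
    idx <- which(active)
    if (length(idx) == 0) break
    st <- cur[idx]
    if (is.null(responder)) {
      y <- runif(length(idx)) < p_correct(alpha[idx], st, beta)
    } else {
      y <- as.logical(responder(idx, st, t))
    }
    npres[idx] <- t
    if (keep_history) {
      step_hist[cbind(idx, t)] <- st
      resp_hist[cbind(idx, t)] <- as.integer(y)
    }

    consec[idx] <- ifelse(y, consec[idx] + 1L, 0L)
    # intended movement: +1 (weaker) on the second consecutive correct,
    # -1 (stronger) on an incorrect, 0 after a single correct
    d_int <- integer(length(idx))
    d_int[y & consec[idx] == 2L] <- 1L
    d_int[!y] <- -1L

    moving <- d_int != 0L
    target <- st + d_int
    can_move <- moving & target >= lo & target <= hi
    # boundary: re-present the same step; not a movement, not a reversal
    consec[idx][moving & !can_move] <- 0L

    mv <- idx[can_move]
    if (length(mv)) {
      dmv <- d_int[can_move]
      flip <- dir[mv] != 0L & dir[mv] != dmv
      fl <- mv[flip]
      if (length(fl)) {
        nrev[fl] <- nrev[fl] + 1L
        revs[cbind(fl, nrev[fl])] <- cur[fl]
        done <- fl[nrev[fl] == nstop]
        active[done] <- FALSE
      }
      still <- active[mv]
      cur[mv[still]] <- cur[mv[still]] + dmv[still]
      dir[mv[still]] <- dmv[still]
      consec[mv[still]] <- 0L
    }
  }

  terminated_by <- ifelse(nrev == nstop, "reversals", "cap")
  censored <- terminated_by == "cap"
  score <- staircase_scores(revs, nrev, protocol$reversals_to_score, cur)
  out <- list(score = score, n_reversals = nrev, n_presentations = npres,
              terminated_by = terminated_by, censored = censored,
              reversals = revs)
  if (keep_history) {
    out$step_hist <- step_hist
    out$resp_hist <- resp_hist
  }
  out
}

# Score every run, with the censoring fallbacks used by the replication
# engine: mean of the last k reversals when available, otherwise the mean of
# whatever reversals exist, otherwise the step the run ended on (so an
# always-correct run caps at the weakest step).
staircase_scores <- function(revs, nrev, k, final_step) {
  vapply(seq_along(nrev), function(i) {
    m <- nrev[i]
    if (m >= k) {
      mean(revs[i, (m - k + 1L):m])
    } else if (m >= 1L) {
      mean(revs[i, seq_len(m)])
    } else {
      final_step[i]
    }
  }, numeric(1))
}

#' Score a staircase run
#'
#' The standard score is the arithmetic mean of the dilution steps at the
#' last `reversals_to_score` reversals. A run with fewer reversals (for
#' example one censored at the presentation cap) has no standard score and
#' raises a censored-result condition.
#'
#' @param run Either a numeric vector of reversal steps, or one row (or all
#'   rows) of the tibble returned by [simulate_staircase()]. When a tibble is
#'   given a numeric vector of scores is returned with `NA` for runs with too
#'   few reversals.
#' @param reversals_to_score Number of final reversals to average (default 4).
#' @return A threshold estimate in step units (or a vector of them).
#' @examples
#' score_staircase(c(5, 6, 5, 6, 5, 6, 5)) # 5.5
#' @export
score_staircase <- function(run, reversals_to_score = 4) {
  if (is.data.frame(run)) {
    return(vapply(run$reversal_steps, function(rs) {
      if (length(rs) < reversals_to_score) NA_real_ else mean(tail(rs, reversals_to_score))
    }, numeric(1)))
  }
  stopifnot(is.numeric(run))
  if (length(run) < reversals_to_score) {
    abort(sprintf("Run has %d reversals but %d are needed for a score; result is censored.",
                  length(run), reversals_to_score),
          class = "olf_censored")
  }
  mean(tail(run, reversals_to_score))
}
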