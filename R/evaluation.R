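#' Correlation and reliability of threshold estimates
#'
#' Reliability of a protocol is measured within a simulated replication as
#' the squared Pearson correlation between the estimated and true thresholds
#' of the same subjects.
#'
#' @param estimates,truths Paired numeric vectors (length >= 3,
#'   non-constant).
#' @return A one-row tibble with `correlation` and `reliability`
#'   (`correlation^2`). A negative correlation still yields a positive
#'   reliability and triggers a warning.
#' @export
reliability <- function(estimates, truths) {
  stopifnot(is.numeric(estimates), is.numeric(truths))
  if (length(estimates) != length(truths) || length(estimates) < 3) {
    abort("`estimates` and `truths` must be paired vectors of length >= 3.",
          class = "olf_invalid_parameter")
  }
  if (sd(estimates) == 0 || sd(truths) == 0) {
    abort("Correlation is undefined for a constant vector.",
          class = "olf_undefined_result")
  }
  r <- cor(estimates, truths)
  if (r < 0) warning("Negative correlation between estimates and truths.")
  tibble(correlation = r, reliability = r^2)
}

resolve_estimator <- function(estimator, protocol) {
  if (is.function(estimator)) return(list(fn = estimator, name = "custom"))
  if (is.null(estimator)) {
    estimator <- if (inherits(protocol, "olf_staircase")) "staircase_score" else "irt_eb"
  }
  estimator <- match.arg(estimator, c("irt_eb", "staircase_score"))
  if (estimator == "staircase_score" && !inherits(protocol, "olf_staircase")) {
    abort("`staircase_score` estimation requires a staircase protocol.",
          class = "olf_invalid_parameter")
  }
  list(fn = NULL, name = estimator)
}

# One replication: draw, administer, estimate. Returns list(correlation,
# converged). Shared by run_replications() and method_correlation().
replicate_once <- function(pop, protocol, n_subjects, est, n_quadrature) {
  thresholds <- sample_thresholds(pop, n_subjects)
  est_values <- NULL
  converged <- TRUE
  if (!is.null(est$fn)) {
    responses <- if (inherits(protocol, "olf_staircase")) {
      sim_staircase_engine(thresholds, pop$beta, protocol)
    } else {
      sim_constant_engine(thresholds, pop$beta, protocol)
    }
    est_values <- est$fn(thresholds, responses)
  } else if (est$name == "staircase_score") {
    eng <- sim_staircase_engine(thresholds, pop$beta, protocol)
    est_values <- eng$score
  } else if (inherits(protocol, "olf_staircase")) {
    # model-based estimation from the full staircase response history
    eng <- sim_staircase_engine(thresholds, pop$beta, protocol, keep_history = TRUE)
    keep <- !is.na(as.vector(t(eng$step_hist)))
    data <- tibble(
      subject_id = rep(seq_len(n_subjects), each = ncol(eng$step_hist))[keep],
      step = as.vector(t(eng$step_hist))[keep],
      response = ifelse(as.vector(t(eng$resp_hist))[keep] == 1L,
                        "correct", "incorrect")
    )
    res <- irt_eb_estimates(data, seq_len(n_subjects), n_quadrature)
    est_values <- res$values
    converged <- res$converged
  } else {
    sim <- sim_constant_engine(thresholds, pop$beta, protocol)
    data <- tibble(subject_id = sim$subject, step = sim$step,
                   response = ifelse(sim$y == 1L, "correct", "incorrect"))
    res <- irt_eb_estimates(data, seq_len(n_subjects), n_quadrature)
    est_values <- res$values
    converged <- res$converged
  }
  if (!converged || sd(thresholds) == 0 || sd(est_values) == 0) {
    return(list(correlation = NA_real_, converged = FALSE))
  }
  list(correlation = cor(est_values, thresholds), converged = TRUE)
}

irt_eb_estimates <- function(data, subjects, n_quadrature) {
  fit <- fit_irt(data, n_quadrature = n_quadrature)
  if (!isTRUE(fit$converged)) {
    return(list(values = rep(NA_real_, length(subjects)), converged = FALSE))
  }
  eb <- empirical_bayes(fit, data, subjects = subjects)
  list(values = eb$threshold_eb, converged = TRUE)
}

#' Monte-Carlo reliability of a threshold protocol
#'
#' The replication engine: in each replication, `n_subjects` true thresholds
#' are drawn from the population model, the protocol is administered by
#' simulation, thresholds are estimated (empirical-Bayes IRT for constant
#' stimuli or staircase histories; last-4-reversal scoring for
#' `estimator = "staircase_score"`), and the Pearson correlation with the
#' true thresholds is recorded. Reliability is the squared correlation,
#' averaged over replications. Replications whose model fit fails to
#' converge are excluded from the aggregates and reported as a failure
#' percentage.
#'
#' Each replication consumes its own RNG sub-stream derived from `seed`, so
#' results are reproducible and independent of execution order.
#'
#' @param pop An `olf_population`.
#' @param protocol An `olf_constant` or `olf_staircase` protocol.
#' @param n_subjects Subjects per replication (>= 10).
#' @param n_reps Number of replications (>= 1).
#' @param seed Integer master seed.
#' @param estimator `"irt_eb"`, `"staircase_score"`, `NULL` (protocol
#'   default: IRT for constant stimuli, last-4-reversal score for the
#'   staircase), or a `function(thresholds, responses)` returning estimates
#'   (useful for testing).
#' @param n_quadrature Gauss-Hermite nodes for the IRT fits.
#' @return An object of class `olf_replication`; see [tidy.olf_replication()]
#'   for the per-replication table and [glance.olf_replication()] for the
#'   aggregate summary.
#' @examples
#' \donttest{
#' rel <- run_replications(population_preset("normosmic"),
#'                         constant_stimuli(1:16),
#'                         n_subjects = 100, n_reps = 20, seed = 1)
#' glance(rel)
#' }
#' @export
run_replications <- function(pop, protocol, n_subjects, n_reps, seed,
                             estimator = NULL, n_quadrature = 61) {
  stopifnot(inherits(pop, "olf_population"), inherits(protocol, "olf_protocol"),
            n_subjects >= 10, n_reps >= 1)
  est <- resolve_estimator(estimator, protocol)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  rows <- lapply(seq_len(n_reps), function(r) {
    withr::with_seed(rep_seeds[r], replicate_once(pop, protocol, n_subjects,
                                                  est, n_quadrature))
  })
  per_rep <- tibble(
    rep = seq_len(n_reps),
    seed = rep_seeds,
    correlation = vapply(rows, `[[`, numeric(1), "correlation"),
    converged = vapply(rows, `[[`, logical(1), "converged")
  )
  per_rep$reliability <- per_rep$correlation^2
  structure(
    list(per_rep = per_rep, pop = pop, protocol = protocol,
         n_subjects = n_subjects, n_reps = n_reps, estimator = est$name),
    class = "olf_replication"
  )
}

#' @describeIn run_replications Per-replication results as a tibble.
#' @param x An `olf_replication`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.olf_replication <- function(x, ...) x$per_rep

#' @describeIn run_replications One-row aggregate summary: mean reliability
#'   and its SE, 5/50/95 percentiles, mean correlation, the percentage of
#'   convergence failures (which are excluded from all other aggregates), and
#'   `usable = FALSE` when no replication converged.
#' @exportS3Method generics::glance
glance.olf_replication <- function(x, ...) {
  ok <- x$per_rep$converged
  rel <- x$per_rep$reliability[ok]
  if (!any(ok)) {
    return(tibble(mean_reliability = NA_real_, se_mean_reliability = NA_real_,
                  p5 = NA_real_, p50 = NA_real_, p95 = NA_real_,
                  mean_correlation = NA_real_,
                  pct_convergence_failures = 100,
                  n_converged = 0L, n_reps = x$n_reps, usable = FALSE))
  }
  q <- quantile(rel, c(0.05, 0.5, 0.95), names = FALSE)
  tibble(
    mean_reliability = mean(rel),
    se_mean_reliability = if (length(rel) > 1) sd(rel) / sqrt(length(rel)) else 0,
    p5 = q[1], p50 = q[2], p95 = q[3],
    mean_correlation = mean(x$per_rep$correlation[ok]),
    pct_convergence_failures = 100 * mean(!ok),
    n_converged = sum(ok), n_reps = x$n_reps, usable = TRUE
  )
}

#' @export
print.olf_replication <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<olf_replication> %d reps x %d subjects; estimator: %s\n",
              x$n_reps, x$n_subjects, x$estimator))
  cat(sprintf("  mean reliability %.3f (SE %.3f); 5/50/95%%: %.3f, %.3f, %.3f\n",
              g$mean_reliability, g$se_mean_reliability, g$p5, g$p50, g$p95))
  cat(sprintf("  mean correlation %.3f; convergence failures %.1f%%\n",
              g$mean_correlation, g$pct_convergence_failures))
  invisible(x)
}

#' Correlation between staircase and constant-stimuli estimates
#'
#' Administers both protocols to the same simulated subjects (identical
#' ability draws, independent response noise) and reports the mean Pearson
#' correlation between the staircase scores and the constant-stimuli
#' empirical-Bayes thresholds across replications.
#'
#' @inheritParams run_replications
#' @param constant_protocol Constant-stimuli protocol (default all 16 steps).
#' @param staircase_protocol Staircase protocol (default [staircase()]).
#' @return A list with `mean_correlation` (over converged replications),
#'   `per_rep` (tibble) and `pct_convergence_failures`.
#' @export
method_correlation <- function(pop, n_subjects, n_reps, seed,
                               constant_protocol = constant_stimuli(1:16),
                               staircase_protocol = staircase(),
                               n_quadrature = 61) {
  stopifnot(inherits(pop, "olf_population"), n_subjects >= 10, n_reps >= 1)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  rows <- lapply(seq_len(n_reps), function(r) {
    withr::with_seed(rep_seeds[r], {
      thresholds <- sample_thresholds(pop, n_subjects)
      sc <- sim_staircase_engine(thresholds, pop$beta, staircase_protocol)$score
      sim <- sim_constant_engine(thresholds, pop$beta, constant_protocol)
      data <- tibble(subject_id = sim$subject, step = sim$step,
                     response = ifelse(sim$y == 1L, "correct", "incorrect"))
      res <- irt_eb_estimates(data, seq_along(thresholds), n_quadrature)
      if (!res$converged || sd(sc) == 0) {
        list(correlation = NA_real_, converged = FALSE)
      } else {
        list(correlation = cor(sc, res$values), converged = TRUE)
      }
    })
  })
  per_rep <- tibble(
    rep = seq_len(n_reps),
    correlation = vapply(rows, `[[`, numeric(1), "correlation"),
    converged = vapply(rows, `[[`, logical(1), "converged")
  )
  ok <- per_rep$converged
  list(mean_correlation = mean(per_rep$correlation[ok]),
       per_rep = per_rep,
       pct_convergence_failures = 100 * mean(!ok))
}

#' Agreement between two sets of paired threshold estimates
#'
#' Bland-Altman-style summary: mean and SD of the differences `a - b`,
#' overall and restricted to a quantile band of the reference estimates `b`
#' (by default the middle 50\%).
#'
#' @param estimates_a,estimates_b Paired numeric vectors; `estimates_b` is
#'   the reference.
#' @param band Two quantile levels of `estimates_b` delimiting the restricted
#'   band (default `c(0.25, 0.75)`).
#' @return A tibble with rows `overall` and `band`: `n`, `mean_difference`,
#'   `sd_difference`, and the band limits.
#' @export
agreement_summary <- function(estimates_a, estimates_b, band = c(0.25, 0.75)) {
  stopifnot(length(estimates_a) == length(estimates_b), length(band) == 2,
            band[1] < band[2])
  diffs <- estimates_a - estimates_b
  lims <- quantile(estimates_b, band, names = FALSE)
  inb <- estimates_b >= lims[1] & estimates_b <= lims[2]
  tibble(
    scope = c("overall", "band"),
    n = c(length(diffs), sum(inb)),
    mean_difference = c(mean(diffs), mean(diffs[inb])),
    sd_difference = c(sd(diffs), sd(diffs[inb])),
    band_lower = c(NA_real_, lims[1]),
    band_upper = c(NA_real_, lims[2])
  )
}

#' Compare candidate protocols in one table
#'
#' Runs the replication engine for each design and stacks the aggregate
#' summaries, one row per design, in the layout used for protocol-comparison
#' tables (mean reliability with SE, 5/50/95 percentiles, convergence
#' failures).
#'
#' @inheritParams run_replications
#' @param designs A named list of protocols.
#' @return A tibble with one row per design.
#' @export
protocol_table <- function(pop, designs, n_subjects, n_reps, seed,
                           estimator = NULL, n_quadrature = 61) {
  stopifnot(is.list(designs), length(designs) >= 1)
  if (is.null(names(designs)) || any(names(designs) == "")) {
    names(designs) <- paste0("design_", seq_along(designs))
  }
  design_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max, length(designs)))
  purrr::imap_dfr(designs, function(proto, nm) {
    i <- match(nm, names(designs))
    rr <- run_replications(pop, proto, n_subjects, n_reps, design_seeds[i],
                           estimator = estimator, n_quadrature = n_quadrature)
    g <- glance(rr)
    dplyr::bind_cols(
      tibble(design = nm,
             n_stimuli = if (inherits(proto, "olf_constant"))
               length(proto$steps) else NA_integer_,
             dilutions = if (inherits(proto, "olf_constant"))
               paste(proto$steps, collapse = ",") else "staircase"),
      g
    )
  })
}
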