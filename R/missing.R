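#' Multiple imputation of don't-know / refused responses
#'
#' Survey administrations allow respondents to answer "don't know" or to
#' refuse. Treating those as incorrect would bias thresholds downward, since
#' a forced guess is correct one third of the time in a 3AFC task. The
#' imputation model therefore replaces each `dont_know` / `refused` record
#' (the two codes are treated identically) with an independent Bernoulli(1/3)
#' correct/incorrect draw, repeated `m` times. Observed responses are never
#' touched.
#'
#' @param data A response table possibly containing `"dont_know"` /
#'   `"refused"` codes.
#' @param m Number of imputations (default 10).
#' @param seed Optional integer; imputations use distinct sub-streams so the
#'   full set is reproducible.
#' @return A list of `m` completed response tables. If `data` has no missing
#'   codes all `m` elements are identical to the input.
#' @export
impute_responses <- function(data, m = 10, seed = NULL) {
  stopifnot(is.data.frame(data), m >= 1)
  miss <- data$response %in% c("dont_know", "refused")
  if (!any(miss)) {
    return(replicate(m, data, simplify = FALSE))
  }
  local_rng(seed)
  lapply(seq_len(m), function(k) {
    out <- data
    out$response[miss] <- ifelse(runif(sum(miss)) < 1 / 3, "correct", "incorrect")
    out
  })
}

#' Pool fits and subject estimates across imputations
#'
#' Model parameters are combined by Rubin's rules: the pooled estimate is the
#' mean of the per-imputation estimates, and its total variance is the mean
#' within-imputation variance plus `(1 + 1/m)` times the between-imputation
#' variance. Per-subject thresholds are pooled by their mean across
#' imputations.
#'
#' @param fits A list of [fit_irt()] results, one per imputation.
#' @param subject_estimates Optional list of [empirical_bayes()] tibbles
#'   aligned with `fits`.
#' @return A list with `parameters` (tibble: term, estimate, std.error,
#'   within, between), `m`, `all_converged`, and (when subject estimates are
#'   supplied) `subjects` (tibble: subject_id, alpha_eb, threshold_eb pooled
#'   by mean).
#' @export
pool_estimates <- function(fits, subject_estimates = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "olf_irt_fit")))
  m <- length(fits)
  est <- vapply(fits, function(f) c(f$beta_hat, f$mu_alpha_hat, f$var_alpha_hat),
                numeric(3))
  ses <- vapply(fits, function(f) c(f$se_beta, f$se_mu_alpha, f$se_var_alpha),
                numeric(3))
  qbar <- rowMeans(est)
  within <- rowMeans(ses^2)
  between <- if (m > 1) apply(est, 1, var) else rep(0, 3)
  total <- within + (1 + 1 / m) * between
  out <- list(
    parameters = tibble(
      term = c("beta", "mu_alpha", "var_alpha"),
      estimate = qbar,
      std.error = sqrt(total),
      within = within,
      between = between
    ),
    m = m,
    all_converged = all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  )
  if (!is.null(subject_estimates)) {
    stopifnot(length(subject_estimates) == m)
    combined <- dplyr::bind_rows(subject_estimates)
    out$subjects <- combined |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(alpha_eb = mean(.data$alpha_eb),
                       threshold_eb = mean(.data$threshold_eb),
                       .groups = "drop")
  }
  out
}

#' Number of correct responses per subject
#'
#' The simple sum score: correct responses count 1; incorrect, don't-know and
#' refused all count 0. For a 6-item protocol this is the 0-6 score that
#' correlates highly with the model-estimated threshold and needs no model
#' fitting.
#'
#' @param data A response table.
#' @return A tibble with `subject_id` and integer `n_correct`.
#' @export
sum_score <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    return(tibble(subject_id = character(0), n_correct = integer(0)))
  }
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_correct = sum(.data$response == "correct"),
                     .groups = "drop")
}
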