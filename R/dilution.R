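#' The 3AFC psychometric response function
#'
#' Probability that a subject with olfactory ability `alpha` correctly
#' identifies the odorant pen among three (one target, two blanks) at a given
#' dilution step. The model is a logistic item response curve with a guessing
#' floor of 1/3 (the chance of picking the target at random) and an upper
#' asymptote of 1:
#' \deqn{P(\mathrm{correct}) = \tfrac13 + \tfrac23\,
#'   \mathrm{logit}^{-1}(\alpha - \beta d)}
#' where \eqn{d} is the dilution step and \eqn{\beta > 0} is the slope per
#' step. The probability increases with ability and decreases with step
#' (weaker concentrations have higher step numbers).
#'
#' @param alpha Numeric vector of subject abilities (logit scale).
#' @param step Numeric vector of dilution steps (step 1 = 4\% v/v n-butanol;
#'   each +1 step halves the concentration; steps at or below 0 denote
#'   stronger pens).
#' @param beta Positive slope per dilution step.
#' @return Numeric vector of probabilities, strictly inside (1/3, 1) for
#'   finite inputs.
#' @examples
#' p_correct(alpha = 10.5, step = 9.375, beta = 1.12) # exactly 2/3 at threshold
#' @seealso [threshold_from_ability()], [step_to_concentration()]
#' @export
p_correct <- function(alpha, step, beta) {
  check_beta(beta)
  stopifnot(is.numeric(alpha), is.numeric(step))
  1 / 3 + (2 / 3) * plogis(alpha - beta * step)
}

#' Threshold implied by an ability
#'
#' The threshold is the dilution step at which the probability of a correct
#' response equals 2/3, i.e. the midpoint between the 1/3 guessing floor and
#' the upper asymptote. Under the 3AFC logistic model this is `alpha / beta`.
#'
#' @inheritParams p_correct
#' @return Dilution step(s) at which `p_correct()` equals 2/3.
#' @export
threshold_from_ability <- function(alpha, beta) {
  check_beta(beta)
  alpha / beta
}

#' Dilution step to concentration and back
#'
#' Dilution steps index a doubling-dilution series of n-butanol: step 1 is a
#' 4\% v/v solution and each +1 step halves the concentration, so
#' `concentration = 0.04 * 2^(1 - step)`. Steps at or below zero denote pens
#' stronger than the standard set (step 0 = 8\%, -1 = 16\%, -2 = 32\%).
#' Concentrations are v/v fractions; multiply by 100 for percent or by 1e6
#' for ppm.
#'
#' @param step Numeric vector of dilution steps.
#' @param concentration Numeric vector of v/v fractions (> 0).
#' @return `step_to_concentration()`: v/v fraction(s);
#'   `concentration_to_step()`: dilution step(s).
#' @examples
#' step_to_concentration(c(1, 16)) # 4% and 1.22 ppm
#' concentration_to_step(0.08)     # pen 0
#' @export
step_to_concentration <- function(step) {
  stopifnot(is.numeric(step), all(is.finite(step)))
  0.04 * 2^(1 - step)
}

#' @rdname step_to_concentration
#' @export
concentration_to_step <- function(concentration) {
  stopifnot(is.numeric(concentration), all(concentration > 0))
  1 - log2(concentration / 0.04)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive finite number.",
          class = "olf_invalid_parameter")
  }
  invisible(beta)
}

# Seed the RNG for a reproducible draw and restore the caller's RNG state
# when the calling function exits.
local_rng <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(NULL)
}
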