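#' Marginal log-likelihood of the random-effects 3AFC model
#'
#' The random-effects model treats each subject's ability as a draw from
#' `N(mu_alpha, var_alpha)` and each response as Bernoulli with probability
#' given by [p_correct()]. The marginal likelihood integrates the Bernoulli
#' likelihood over the ability distribution:
#' \deqn{\ell = \sum_i \log \int \prod_j P_{ij}^{y_{ij}} (1-P_{ij})^{1-y_{ij}}
#'   \,\phi(\alpha;\mu,\sigma^2)\, d\alpha}
#' evaluated here by Gauss-Hermite quadrature with nodes placed under the
#' population distribution. Exposed mainly so the quadrature can be checked
#' against brute-force integration.
#'
#' @param data A response table (see [fit_irt()]) containing only
#'   correct/incorrect responses.
#' @param beta,mu_alpha,var_alpha Model parameters (`beta > 0`,
#'   `var_alpha >= 0`).
#' @param n_quadrature Number of Gauss-Hermite nodes (default 61).
#' @return The marginal log-likelihood (a single number).
#' @export
irt_marginal_loglik <- function(data, beta, mu_alpha, var_alpha,
                                n_quadrature = 61) {
  d <- as_response_vectors(data)
  gh <- gh_nodes(n_quadrature)
  sum(subject_logliks(d, beta, mu_alpha, sqrt(var_alpha), gh))
}

# Gauss-Hermite nodes/weights for integrals against exp(-x^2); cached.
gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) {
    g <- pracma::gaussHermite(n)
    gh_cache[[key]] <- list(x = g$x, logw = log(g$w) - 0.5 * log(pi))
  }
  gh_cache[[key]]
}

# data -> list(subject = integer index 1..n, step, y, ids) plus, when every
# subject received the same multiset of steps (the constant-stimuli case), a
# wide n x J response matrix aligned on within-subject step order, which lets
# the likelihood be computed with two matrix products.
as_response_vectors <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "step", "response") %in% names(data)))
  resp <- data$response
  bad <- !resp %in% c("correct", "incorrect")
  if (any(bad)) {
    abort(paste0("Response table contains non-binary codes (",
                 paste(unique(resp[bad]), collapse = ", "),
                 "); impute with `impute_responses()` first."),
          class = "olf_invalid_parameter")
  }
  ids <- unique(data$subject_id)
  subject <- match(data$subject_id, ids)
  step <- as.numeric(data$step)
  y <- as.integer(resp == "correct")
  out <- list(subject = subject, step = step, y = y, ids = ids)

  n <- length(ids)
  counts <- tabulate(subject, n)
  if (n > 0 && all(counts == counts[1])) {
    J <- counts[1]
    ord <- order(subject, step)
    sm <- matrix(step[ord], nrow = n, ncol = J, byrow = TRUE)
    if (all(abs(sweep(sm, 2, sm[1, ])) < 1e-12)) {
      out$wide <- TRUE
      out$steps_j <- sm[1, ]
      out$Y <- matrix(y[ord], nrow = n, ncol = J, byrow = TRUE)
      out$Yc <- 1L - out$Y
    }
  }
  out
}

# Per-subject marginal log-likelihoods; also returns the per-node posterior
# ingredients when `detail = TRUE` (used by empirical Bayes) or the analytic
# score when `grad = TRUE`. The wide path (same step multiset for every
# subject) reduces the per-subject sums to matrix products; the long path
# handles arbitrary designs such as staircase response histories. With
# s = logistic(alpha - beta*step), the response curve p = (1 + 2s)/3 gives
# the stable derivatives d log(p)/d eta = 2s(1-s)/(1+2s) and
# d log(1-p)/d eta = -s.
subject_logliks <- function(d, beta, mu, sigma, gh, detail = FALSE,
                            grad = FALSE) {
  alpha_k <- mu + sqrt(2) * sigma * gh$x       # K abilities
  if (isTRUE(d$wide)) {
    eta <- outer(-beta * d$steps_j, alpha_k, `+`)   # J x K
    s <- plogis(eta)
    logp <- log1p(2 * s) - log(3)
    log1mp <- log(2 / 3) + pmax(plogis(eta, log.p = TRUE) - eta, -700)
    S <- d$Y %*% logp + d$Yc %*% log1mp             # n x K
  } else {
    eta <- outer(-beta * d$step, alpha_k, `+`)
    s <- plogis(eta)
    llrec <- log1p(2 * s) - log(3)
    wrong <- d$y == 0L
    if (any(wrong)) {
      llrec[wrong, ] <- log(2 / 3) +
        pmax(plogis(eta[wrong, , drop = FALSE], log.p = TRUE) -
               eta[wrong, , drop = FALSE], -700)
    }
    S <- rowsum(llrec, group = d$subject)      # rows sorted by group 1..n
  }
  W <- sweep(S, 2, gh$logw, `+`)
  m <- W[, 1]
  for (k in seq_len(ncol(W))[-1]) m <- pmax(m, W[, k])
  ll <- m + log(rowSums(exp(W - m)))
  if (!detail && !grad) return(ll)
  out <- list(ll = ll, W = W, alpha_k = alpha_k)
  if (grad) {
    # score of (beta, mu, log sigma): posterior-weighted per-record
    # derivatives, assembled with the same matrix products
    stopifnot(isTRUE(d$wide))
    A <- 2 * s * (1 - s) / (1 + 2 * s)   # d log(p) / d eta,   J x K
    GY <- d$Y %*% A - d$Yc %*% s                      # n x K
    GD <- d$Y %*% (A * d$steps_j) - d$Yc %*% (s * d$steps_j)
    Wn <- exp(W - ll)
    out$grad <- c(
      beta = -sum(Wn * GD),
      mu = sum(Wn * GY),
      log_sigma = sum((Wn * GY) %*% (sqrt(2) * sigma * gh$x))
    )
  }
  out
}

#' Fit the random-effects 3AFC IRT model
#'
#' Maximizes the marginal likelihood over `(beta, mu_alpha, log sigma_alpha)`
#' with Gauss-Hermite quadrature (see [irt_marginal_loglik()]) using a
#' quasi-Newton optimizer. Standard errors come from the observed information
#' (numerically differentiated Hessian, delta method for `var_alpha`).
#' Non-convergence — optimizer failure, a variance collapsing to the boundary,
#' or a non-invertible information matrix — is reported through the
#' `converged` flag rather than an error, since in small designs (few items,
#' few subjects) a non-trivial fraction of simulated datasets cannot support
#' the variance parameter.
#'
#' @param data A response table: data frame with columns `subject_id`, `step`
#'   and `response` (`"correct"`/`"incorrect"` only; run
#'   [impute_responses()] first if don't-know/refused codes are present).
#'   Needs at least 2 subjects and 2 distinct steps.
#' @param n_quadrature Gauss-Hermite nodes (default 61).
#' @param start Optional named list with elements `beta`, `mu_alpha`,
#'   `sd_alpha` overriding the method-of-moments starting values.
#' @param control Passed to [stats::nlminb()] (defaults: tight tolerances).
#' @return An object of class `olf_irt_fit`: estimates `beta_hat`,
#'   `mu_alpha_hat`, `var_alpha_hat`, their standard errors, `loglik`,
#'   `converged`, `n_quadrature`, plus bookkeeping. Use [tidy()] /
#'   [glance()] / [empirical_bayes()] on it.
#' @examples
#' pop <- population_preset("normosmic")
#' tr <- sample_thresholds(pop, 150, seed = 1)
#' resp <- simulate_constant_stimuli(tr, pop$beta, constant_stimuli(1:16), seed = 2)
#' fit <- fit_irt(resp)
#' glance(fit)
#' @export
fit_irt <- function(data, n_quadrature = 61, start = NULL, control = list()) {
  d <- as_response_vectors(data)
  n_sub <- length(d$ids)
  if (n_sub < 2 || length(unique(d$step)) < 2) {
    abort("Need at least 2 subjects and 2 distinct dilution steps.",
          class = "olf_invalid_parameter")
  }
  gh <- gh_nodes(n_quadrature)

  pbar <- mean(d$y)
  degenerate <- pbar %in% c(0, 1)
  # method-of-moments start: invert the mean response at the mean step
  p0 <- min(max(pbar, 0.35), 0.99)
  mu0 <- qlogis(pmin(pmax((p0 - 1 / 3) * 1.5, 0.02), 0.98)) + mean(d$step)
  th0 <- c(beta = 1, mu = mu0, log_sigma = 0)
  if (!is.null(start)) {
    if (!is.null(start$beta)) th0["beta"] <- start$beta
    if (!is.null(start$mu_alpha)) th0["mu"] <- start$mu_alpha
    if (!is.null(start$sd_alpha)) th0["log_sigma"] <- log(start$sd_alpha)
  }

  # objective and analytic score evaluated jointly and memoized, since the
  # optimizer requests them separately at the same point
  memo <- new.env(parent = emptyenv())
  evaluate <- function(th) {
    if (!is.null(memo$th) && identical(memo$th, th)) return(memo$res)
    res <- if (isTRUE(d$wide)) {
      r <- subject_logliks(d, th[1], th[2], exp(th[3]), gh, grad = TRUE)
      list(value = -sum(r$ll), grad = -r$grad)
    } else {
      list(value = -sum(subject_logliks(d, th[1], th[2], exp(th[3]), gh)),
           grad = NULL)
    }
    memo$th <- th
    memo$res <- res
    res
  }
  negll <- function(th) evaluate(th)$value
  grfun <- if (isTRUE(d$wide)) function(th) evaluate(th)$grad else NULL
  lower <- c(1e-6, -Inf, log(1e-4))
  upper <- c(50, Inf, log(50))
  ctrl <- utils::modifyList(list(rel.tol = 1e-12, abs.tol = 0, iter.max = 500,
                                 eval.max = 1000), control)

  opt <- tryCatch(
    nlminb(th0, negll, gradient = grfun, lower = lower, upper = upper,
           control = ctrl),
    error = function(e) NULL
  )

  if (is.null(opt) || degenerate) {
    fit <- irt_fit_result(
      beta_hat = NA_real_, mu_alpha_hat = if (degenerate) sign(pbar - 0.5) * Inf else NA_real_,
      var_alpha_hat = NA_real_, se = rep(NA_real_, 3), loglik = NA_real_,
      converged = FALSE, n_quadrature = n_quadrature, n_subjects = n_sub,
      nobs = length(d$y), note = if (degenerate) "degenerate (all-correct or all-incorrect data)" else "optimizer error"
    )
    fit$data_ids <- d$ids
    return(fit)
  }

  th <- opt$par
  beta_hat <- th[1]
  mu_hat <- th[2]
  sigma_hat <- exp(th[3])
  loglik <- -opt$objective

  # explicit convergence criterion: finite interior solution with a (scaled)
  # gradient norm near zero; the optimizer's own code is advisory only, as
  # at very tight tolerances it reports spurious "false convergence"
  grad <- if (isTRUE(d$wide)) {
    tryCatch(evaluate(th)$grad, error = function(e) rep(NA_real_, 3))
  } else {
    tryCatch(num_grad(negll, th), error = function(e) rep(NA_real_, 3))
  }
  grad_ok <- all(is.finite(grad)) &&
    sqrt(sum(grad^2)) < 1e-5 * max(1, abs(loglik))
  interior <- beta_hat > lower[1] * 2 && beta_hat < upper[1] * 0.99 &&
    th[3] > lower[3] + 0.01 && th[3] < upper[3] - 0.01
  converged <- is.finite(loglik) && grad_ok && interior

  se <- rep(NA_real_, 3)
  if (converged) {
    H <- tryCatch(optimHess(th, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V) && all(diag(V) > 0)) {
      se_th <- sqrt(diag(V))
      # delta method: var_alpha = exp(2 * log_sigma)
      se <- c(se_th[1], se_th[2], se_th[3] * 2 * sigma_hat^2)
    } else {
      converged <- FALSE
    }
  }

  fit <- irt_fit_result(
    beta_hat = beta_hat, mu_alpha_hat = mu_hat, var_alpha_hat = sigma_hat^2,
    se = se, loglik = loglik, converged = converged,
    n_quadrature = n_quadrature, n_subjects = n_sub, nobs = length(d$y),
    note = NULL
  )
  fit$data_ids <- d$ids
  fit
}

irt_fit_result <- function(beta_hat, mu_alpha_hat, var_alpha_hat, se, loglik,
                           converged, n_quadrature, n_subjects, nobs, note) {
  structure(
    list(beta_hat = unname(beta_hat), mu_alpha_hat = unname(mu_alpha_hat),
         var_alpha_hat = unname(var_alpha_hat),
         se_beta = se[1], se_mu_alpha = se[2], se_var_alpha = se[3],
         loglik = unname(loglik), converged = converged,
         n_quadrature = n_quadrature, n_subjects = n_subjects, nobs = nobs,
         note = note),
    class = "olf_irt_fit"
  )
}

# central-difference gradient, step scaled to parameter magnitude
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    (f(xp) - f(xm)) / (2 * hj)
  }, numeric(1))
}

#' @export
print.olf_irt_fit <- function(x, ...) {
  cat("<olf_irt_fit> random-effects 3AFC logistic IRT\n")
  cat(sprintf("  beta = %.4f (SE %.4f)\n", x$beta_hat, x$se_beta))
  cat(sprintf("  mu_alpha = %.4f (SE %.4f)\n", x$mu_alpha_hat, x$se_mu_alpha))
  cat(sprintf("  var_alpha = %.4f (SE %.4f)\n", x$var_alpha_hat, x$se_var_alpha))
  cat(sprintf("  logLik %.3f | %d subjects, %d responses | %s\n",
              x$loglik, x$n_subjects, x$nobs,
              if (isTRUE(x$converged)) "converged" else paste0("NOT converged",
                if (!is.null(x$note)) paste0(" (", x$note, ")") else "")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.olf_irt_fit <- function(x, ...) {
  tibble(
    term = c("beta", "mu_alpha", "var_alpha"),
    estimate = c(x$beta_hat, x$mu_alpha_hat, x$var_alpha_hat),
    std.error = c(x$se_beta, x$se_mu_alpha, x$se_var_alpha)
  )
}

#' @exportS3Method generics::glance
glance.olf_irt_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, converged = x$converged,
    n_quadrature = x$n_quadrature, n_subjects = x$n_subjects, nobs = x$nobs
  )
}

#' Empirical-Bayes subject thresholds
#'
#' Posterior mean and SD of each subject's ability under the fitted
#' population prior `N(mu_alpha_hat, var_alpha_hat)` and their observed
#' responses, by the same Gauss-Hermite rule used in fitting. The subject's
#' threshold estimate is the plug-in ratio `alpha_eb / beta_hat`. Subjects
#' listed in `subjects` but absent from the data receive the prior mean
#' (posterior = prior with no responses). These shrinkage estimates have
#' smaller variance than the true thresholds but are unconditionally
#' unbiased for the population mean, and avoid regression attenuation when
#' used as covariates downstream.
#'
#' @param fit A converged [fit_irt()] result.
#' @param data The response table the fit was based on (binary codes only).
#' @param subjects Optional vector of subject ids to report (defaults to the
#'   subjects present in `data`).
#' @return A tibble: `subject_id`, `alpha_eb`, `alpha_eb_sd`, `threshold_eb`.
#' @export
empirical_bayes <- function(fit, data, subjects = NULL) {
  stopifnot(inherits(fit, "olf_irt_fit"))
  if (!isTRUE(fit$converged)) {
    abort("Empirical Bayes requires a converged fit.", class = "olf_not_converged")
  }
  d <- as_response_vectors(data)
  gh <- gh_nodes(fit$n_quadrature)
  det <- subject_logliks(d, fit$beta_hat, fit$mu_alpha_hat,
                         sqrt(fit$var_alpha_hat), gh, detail = TRUE)
  Wn <- exp(det$W - det$ll)              # normalized posterior node weights
  a_mean <- as.numeric(Wn %*% det$alpha_k)
  a2 <- as.numeric(Wn %*% det$alpha_k^2)
  a_sd <- sqrt(pmax(a2 - a_mean^2, 0))
  out <- tibble(subject_id = d$ids, alpha_eb = a_mean, alpha_eb_sd = a_sd)
  if (!is.null(subjects)) {
    missing_ids <- setdiff(subjects, d$ids)
    if (length(missing_ids)) {
      out <- dplyr::bind_rows(out, tibble(
        subject_id = missing_ids,
        alpha_eb = fit$mu_alpha_hat,
        alpha_eb_sd = sqrt(fit$var_alpha_hat)
      ))
    }
    out <- out[match(subjects, out$subject_id), , drop = FALSE]
  }
  out$threshold_eb <- out$alpha_eb / fit$beta_hat
  out
}

#' Per-subject maximum-likelihood fit
#'
#' Fits the 3AFC logistic curve to one subject's responses alone, as is done
#' when each subject receives many items (16+). With `beta` fixed the only
#' parameter is the subject's ability; with `beta = NULL` both ability and
#' slope are estimated. All-correct or all-incorrect response sets give
#' complete separation and are flagged non-estimable rather than returning a
#' diverging estimate.
#'
#' @param data Response table rows for a single subject (binary codes).
#' @param beta Fixed slope, or `NULL` to estimate it too.
#' @return A list: `alpha` (ability MLE), `beta`, `threshold` (`alpha/beta`),
#'   `estimable` (FALSE under separation), `loglik`.
#' @export
fit_per_subject <- function(data, beta = NULL) {
  stopifnot(is.data.frame(data))
  if (length(unique(data$subject_id)) != 1) {
    abort("`fit_per_subject()` expects data for exactly one subject.",
          class = "olf_invalid_parameter")
  }
  resp <- data$response
  stopifnot(all(resp %in% c("correct", "incorrect")))
  y <- as.integer(resp == "correct")
  step <- as.numeric(data$step)
  if (all(y == 1) || all(y == 0)) {
    return(list(alpha = NA_real_, beta = beta %||% NA_real_,
                threshold = NA_real_, estimable = FALSE, loglik = NA_real_))
  }
  nll <- function(par) {
    b <- if (is.null(beta)) exp(par[2]) else beta
    p <- p_correct(par[1], step, b)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  p0 <- c(alpha = mean(step), log_beta = 0)
  par0 <- if (is.null(beta)) p0 else p0[1]
  opt <- nlminb(par0, nll, control = list(rel.tol = 1e-12))
  b_hat <- if (is.null(beta)) exp(opt$par[2]) else beta
  g <- tryCatch(num_grad(nll, opt$par), error = function(e) NA_real_)
  ok <- all(is.finite(opt$par)) && all(is.finite(g)) &&
    sqrt(sum(g^2)) < 1e-4 * max(1, abs(opt$objective))
  list(alpha = unname(opt$par[1]), beta = unname(b_hat),
       threshold = unname(opt$par[1] / b_hat),
       estimable = ok, loglik = -opt$objective)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
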