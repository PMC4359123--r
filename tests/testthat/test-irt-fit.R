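test_that("quadrature marginal likelihood matches brute-force integration", {
  ch <- make_cohort(n = 5, steps = c(2, 5, 8, 9, 12, 15))
  for (pars in list(c(1.12, 10.5, 16.6), c(0.76, 1.8, 5.2), c(2.0, 5.0, 1.0))) {
    bf <- brute_force_loglik(ch$responses, pars[1], pars[2], pars[3])
    q <- irt_marginal_loglik(ch$responses, pars[1], pars[2], pars[3],
                             n_quadrature = 101)
    expect_equal(q, bf, tolerance = 1e-6)
  }
  # one subject, three responses, six-decimal agreement
  one <- ch$responses[ch$responses$subject_id == 1, ][1:3, ]
  expect_equal(irt_marginal_loglik(one, 1.12, 10.5, 16.6, n_quadrature = 101),
               brute_force_loglik(one, 1.12, 10.5, 16.6),
               tolerance = 1e-6)
})

test_that("estimates are stable in the number of quadrature nodes", {
  # the quadrature grid spans the population distribution, so the default
  # node count is chosen dense enough that further refinement is idle
  ch <- make_cohort(n = 300)
  f61 <- fit_irt(ch$responses)
  f101 <- fit_irt(ch$responses, n_quadrature = 101)
  expect_true(f61$converged && f101$converged)
  expect_lt(abs(f61$beta_hat - f101$beta_hat), 1e-3)
  expect_lt(abs(f61$mu_alpha_hat - f101$mu_alpha_hat), 1e-2)
})

test_that("the fit recovers its generating parameters", {
  pop <- population_preset("normosmic")
  tr <- sample_thresholds(pop, 1000, seed = 61)
  resp <- simulate_constant_stimuli(tr, pop$beta, constant_stimuli(1:16), seed = 62)
  fit <- fit_irt(resp)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta_hat - 1.12), 3 * fit$se_beta)
  expect_lt(abs(fit$mu_alpha_hat - 10.5), 3 * fit$se_mu_alpha)
  expect_lt(abs(fit$var_alpha_hat - 16.6), 3 * fit$se_var_alpha)
  # broom-style accessors
  td <- tidy(fit)
  expect_equal(td$term, c("beta", "mu_alpha", "var_alpha"))
  expect_equal(glance(fit)$n_subjects, 1000L)
})

test_that("a homogeneous cohort drives the variance to zero", {
  # every subject shares the same ability; mu is recovered, sigma^2 collapses
  resp <- simulate_constant_stimuli(rep(8, 400), 1.12, constant_stimuli(1:16),
                                    seed = 63)
  fit <- fit_irt(resp)
  expect_lt(abs(fit$mu_alpha_hat - 8 * 1.12), 0.4)
  expect_lt(fit$var_alpha_hat, 0.05)
})

test_that("degenerate and malformed tables are flagged, not fit", {
  all_right <- tibble::tibble(subject_id = rep(1:3, each = 2),
                              step = rep(c(2, 5), 3),
                              response = "correct")
  fit <- fit_irt(all_right)
  expect_false(fit$converged)
  expect_match(fit$note, "degenerate")
  dk <- all_right
  dk$response[1] <- "dont_know"
  expect_error(fit_irt(dk), class = "olf_invalid_parameter")
  expect_error(fit_irt(all_right[1:2, ]), class = "olf_invalid_parameter")
})

test_that("empirical Bayes shrinks, stays unbiased, and respects the prior", {
  pop <- population_preset("normosmic")
  tr <- sample_thresholds(pop, 1500, seed = 71)
  resp <- simulate_constant_stimuli(tr, pop$beta,
                                    constant_stimuli(c(2, 5, 8, 9, 12, 15)),
                                    seed = 72)
  fit <- fit_irt(resp)
  expect_true(fit$converged)
  eb <- empirical_bayes(fit, resp)
  # shrinkage toward the mean: less dispersed than the truth
  expect_lt(var(eb$threshold_eb), var(tr))
  # unconditionally unbiased for the population mean
  expect_lt(abs(mean(eb$threshold_eb) - mean(tr)), 4 * sd(tr) / sqrt(length(tr)))
  # posterior SD never exceeds the prior SD
  expect_true(all(eb$alpha_eb_sd <= sqrt(fit$var_alpha_hat) + 1e-8))
  # a subject with no responses sits at the prior mean
  eb2 <- empirical_bayes(fit, resp, subjects = c(1, 2, 99999))
  expect_equal(eb2$alpha_eb[eb2$subject_id == 99999], fit$mu_alpha_hat)
})

test_that("six-item estimates depend on data only through the 64 patterns", {
  fit <- structure(
    list(beta_hat = 0.76, mu_alpha_hat = 1.82, var_alpha_hat = 5.2,
         se_beta = 0.1, se_mu_alpha = 0.1, se_var_alpha = 0.5,
         loglik = 0, converged = TRUE, n_quadrature = 41,
         n_subjects = 64L, nobs = 384L, note = NULL),
    class = "olf_irt_fit"
  )
  steps <- c(6, 5, 4, 2, 1, 0)
  patt <- expand.grid(rep(list(0:1), 6))
  tab <- tibble::tibble(
    subject_id = rep(seq_len(64), each = 6),
    step = rep(steps, 64),
    response = ifelse(as.vector(t(as.matrix(patt))) == 1, "correct", "incorrect")
  )
  eb <- empirical_bayes(fit, tab)
  # all-correct is the unique maximum
  idx_all <- which(rowSums(patt) == 6)
  expect_equal(which.max(eb$threshold_eb), idx_all)
  # monotonicity: flipping any single item to correct never lowers the
  # ability estimate
  for (s in seq_len(64)) {
    for (j in which(patt[s, ] == 0)) {
      flipped <- patt[s, ]
      flipped[j] <- 1
      s2 <- which(apply(patt, 1, function(r) all(r == unlist(flipped))))
      expect_gt(eb$alpha_eb[s2], eb$alpha_eb[s])
    }
  }
})

test_that("per-subject fits handle separation and recover known abilities", {
  steps16 <- 1:16
  all_c <- tibble::tibble(subject_id = 1, step = steps16, response = "correct")
  res <- fit_per_subject(all_c, beta = 1.12)
  expect_false(res$estimable)
  # long item series: maximum-likelihood ability close to truth
  alpha_true <- 9
  set.seed(81)
  steps <- rep(1:16, length.out = 200)
  y <- runif(200) < p_correct(alpha_true, steps, 1.12)
  tab <- tibble::tibble(subject_id = "s1", step = steps,
                        response = ifelse(y, "correct", "incorrect"))
  res2 <- fit_per_subject(tab, beta = 1.12)
  expect_true(res2$estimable)
  expect_lt(abs(res2$alpha - alpha_true), 1.5)
  expect_equal(res2$threshold, res2$alpha / 1.12)
  expect_equal(p_correct(res2$alpha, res2$threshold, 1.12), 2 / 3)
  # joint (alpha, beta) estimation also works
  res3 <- fit_per_subject(tab)
  expect_true(res3$estimable)
  expect_lt(abs(res3$threshold - alpha_true / 1.12), 1.5)
})

test_that("imputation replaces only the missing codes at rate one third", {
  tab <- tibble::tibble(
    subject_id = rep(1:2, each = 3),
    step = rep(c(6, 5, 4), 2),
    response = c("correct", "dont_know", "refused",
                 "incorrect", "correct", "dont_know")
  )
  imps <- impute_responses(tab, m = 3, seed = 5)
  expect_length(imps, 3)
  for (im in imps) {
    expect_true(all(im$response %in% c("correct", "incorrect")))
    # observed records untouched
    obs <- tab$response %in% c("correct", "incorrect")
    expect_identical(im$response[obs], tab$response[obs])
  }
  # reproducible under the seed, with distinct sub-streams across imputations
  imps2 <- impute_responses(tab, m = 3, seed = 5)
  expect_identical(imps, imps2)
  # a table with no missing codes passes through unchanged
  clean <- imps[[1]]
  expect_identical(impute_responses(clean, m = 2, seed = 1), list(clean, clean))
  # imputed correct fraction is 1/3
  big <- tibble::tibble(subject_id = 1, step = 1,
                        response = rep("dont_know", 1e5))
  frac <- mean(impute_responses(big, m = 1, seed = 9)[[1]]$response == "correct")
  expect_lt(abs(frac - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 1e5))
})

test_that("pooling follows Rubin's rules", {
  mk <- function(est, se) structure(
    list(beta_hat = est, mu_alpha_hat = 0, var_alpha_hat = 1,
         se_beta = se, se_mu_alpha = 0, se_var_alpha = 0,
         loglik = 0, converged = TRUE, n_quadrature = 21,
         n_subjects = 2L, nobs = 4L, note = NULL),
    class = "olf_irt_fit")
  # m = 1: pooled equals the single fit
  p1 <- pool_estimates(list(mk(1.5, 0.2)))
  expect_equal(p1$parameters$estimate[1], 1.5)
  expect_equal(p1$parameters$std.error[1], 0.2)
  # identical fits: zero between-imputation variance
  p2 <- pool_estimates(list(mk(1.5, 0.2), mk(1.5, 0.2)))
  expect_equal(p2$parameters$between[1], 0)
  # worked example: estimates 1 and 2, within-variances 0.1 each ->
  # pooled 1.5, total variance 0.1 + 1.5 * 0.5 = 0.85
  p3 <- pool_estimates(list(mk(1, sqrt(0.1)), mk(2, sqrt(0.1))))
  expect_equal(p3$parameters$estimate[1], 1.5)
  expect_equal(p3$parameters$std.error[1]^2, 0.85)
  # subject thresholds pool by the mean across imputations
  se_a <- tibble::tibble(subject_id = c("a", "b"), alpha_eb = c(1, 2),
                         threshold_eb = c(1, 2))
  se_b <- tibble::tibble(subject_id = c("a", "b"), alpha_eb = c(3, 2),
                         threshold_eb = c(3, 2))
  p4 <- pool_estimates(list(mk(1, 0.1), mk(1, 0.1)), list(se_a, se_b))
  expect_equal(p4$subjects$threshold_eb[p4$subjects$subject_id == "a"], 2)
})

test_that("sum scores count correct responses only", {
  tab <- tibble::tibble(
    subject_id = c(rep("a", 6), rep("b", 6)),
    step = rep(c(6, 5, 4, 2, 1, 0), 2),
    response = c(rep("correct", 6),
                 "correct", "correct", "correct", "incorrect", "incorrect", "refused")
  )
  sc <- sum_score(tab)
  expect_equal(sc$n_correct[sc$subject_id == "a"], 6L)
  expect_equal(sc$n_correct[sc$subject_id == "b"], 3L)
  expect_equal(nrow(sum_score(tab[0, ])), 0L)
})
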