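test_that("reliability is the squared Pearson correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(reliability(x, x), tibble::tibble(correlation = 1, reliability = 1))
  expect_warning(res <- reliability(-x, x), "Negative")
  expect_equal(res$correlation, -1)
  expect_equal(res$reliability, 1)
  # a correlation of 0.75 gives reliability 0.5625 (prints as 0.56)
  set.seed(3)
  repeat {
    a <- rnorm(4000)
    b <- 0.75 / sqrt(1 - 0.75^2) * a + rnorm(4000)
    if (abs(cor(a, b) - 0.75) < 1e-3) break
  }
  expect_equal(reliability(b, a)$reliability, 0.5625, tolerance = 0.01)
  expect_error(reliability(rep(1, 5), x), class = "olf_undefined_result")
  expect_error(reliability(1:2, 1:2), class = "olf_invalid_parameter")
})

test_that("a perfect estimator yields unit reliability in every replication", {
  oracle_estimator <- function(thresholds, responses) thresholds
  rr <- run_replications(population_preset("normosmic"), constant_stimuli(1:4),
                         n_subjects = 25, n_reps = 4, seed = 1,
                         estimator = oracle_estimator)
  expect_true(all(tidy(rr)$reliability == 1))
  g <- glance(rr)
  expect_equal(g$mean_reliability, 1)
  expect_equal(g$mean_correlation, 1)
  expect_equal(g$pct_convergence_failures, 0)
})

test_that("per-replication reliability equals the squared correlation exactly", {
  rr <- run_replications(population_preset("normosmic"), constant_stimuli(1:16),
                         n_subjects = 40, n_reps = 6, seed = 2)
  pr <- tidy(rr)
  expect_identical(pr$reliability, pr$correlation^2)
  # replication streams are reproducible from the master seed
  rr2 <- run_replications(population_preset("normosmic"), constant_stimuli(1:16),
                          n_subjects = 40, n_reps = 6, seed = 2)
  expect_identical(tidy(rr), tidy(rr2))
})

test_that("aggregates exclude non-converged replications and flag unusable runs", {
  mk <- function(per_rep) {
    structure(list(per_rep = per_rep, n_reps = nrow(per_rep), n_subjects = 10,
                   estimator = "irt_eb"), class = "olf_replication")
  }
  pr <- tibble::tibble(rep = 1:4, seed = 1:4,
                       correlation = c(0.8, NA, 0.6, 0.9),
                       converged = c(TRUE, FALSE, TRUE, TRUE))
  pr$reliability <- pr$correlation^2
  g <- glance(mk(pr))
  expect_equal(g$mean_reliability, mean(c(0.64, 0.36, 0.81)))
  expect_equal(g$mean_correlation, mean(c(0.8, 0.6, 0.9)))
  expect_equal(g$pct_convergence_failures, 25)
  expect_true(g$p5 <= g$p50 && g$p50 <= g$p95)
  # all failed -> unusable
  pr_bad <- pr
  pr_bad$converged <- FALSE
  g2 <- glance(mk(pr_bad))
  expect_false(g2$usable)
  expect_equal(g2$pct_convergence_failures, 100)
})

test_that("model-based estimation works on staircase response histories", {
  rr <- run_replications(population_preset("normosmic"), staircase(),
                         n_subjects = 60, n_reps = 2, seed = 3,
                         estimator = "irt_eb")
  g <- glance(rr)
  expect_true(g$usable)
  expect_gt(g$mean_reliability, 0.5)
  expect_error(
    run_replications(population_preset("normosmic"), constant_stimuli(1:6),
                     n_subjects = 20, n_reps = 1, seed = 1,
                     estimator = "staircase_score"),
    class = "olf_invalid_parameter"
  )
})

test_that("repeating six dilutions beats presenting them once", {
  pop <- population_preset("normosmic")
  six <- c(2, 5, 8, 9, 12, 15)
  r1 <- run_replications(pop, constant_stimuli(six), 100, 25, seed = 4)
  r2 <- run_replications(pop, constant_stimuli(rep(six, 2)), 100, 25, seed = 5)
  expect_gt(glance(r2)$mean_reliability, glance(r1)$mean_reliability)
})

test_that("method correlation responds to the quality of both estimators", {
  mc <- method_correlation(population_preset("normosmic"), 80, 4, seed = 6)
  expect_true(mc$mean_correlation > 0.6 && mc$mean_correlation < 1)
  expect_equal(nrow(mc$per_rep), 4)
})

test_that("agreement summaries report differences overall and in a band", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  s <- agreement_summary(a, a)
  expect_equal(s$mean_difference, c(0, 0))
  expect_equal(s$sd_difference, c(0, 0))
  s2 <- agreement_summary(a + 1, a)
  expect_equal(s2$mean_difference, c(1, 1))
  # band restricts to the middle quantiles of the reference
  b <- rnorm(500)
  withr::with_seed(7, d <- rnorm(500, sd = 0.1))
  s3 <- agreement_summary(b + d, b, band = c(0.25, 0.75))
  lims <- quantile(b, c(0.25, 0.75), names = FALSE)
  expect_equal(s3$n[2], sum(b >= lims[1] & b <= lims[2]))
})

test_that("larger samples stabilise reliability without moving its mean", {
  pop <- population_preset("normosmic")
  proto <- constant_stimuli(1:16)
  g100 <- glance(run_replications(pop, proto, 100, 30, seed = 11))
  g1000 <- glance(run_replications(pop, proto, 1000, 30, seed = 12))
  se_joint <- sqrt(g100$se_mean_reliability^2 + g1000$se_mean_reliability^2)
  expect_lt(abs(g100$mean_reliability - g1000$mean_reliability),
            4 * se_joint + 0.01)
  expect_lt(g1000$p95 - g1000$p5, g100$p95 - g100$p5)
})

test_that("staircase scores overestimate the poorest smellers", {
  # strong-concentration end of an older-adult population: erroneous early
  # reversals leave scores too high
  pop <- population_preset("nshap_gamma")
  tr <- sample_thresholds(pop, 6000, seed = 8)
  runs <- simulate_staircase(tr, pop$beta, staircase(), seed = 9,
                             keep_history = FALSE)
  low <- tr <= quantile(tr, 0.25)
  expect_gt(mean(runs$score[low] - tr[low]), 0)
})

test_that("protocol tables stack one summary row per design", {
  pop <- population_preset("normosmic")
  designs <- list(
    full = constant_stimuli(1:16),
    six = constant_stimuli(c(2, 5, 8, 9, 12, 15)),
    stair = staircase()
  )
  tab <- protocol_table(pop, designs, n_subjects = 60, n_reps = 3, seed = 10)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$design, c("full", "six", "stair"))
  expect_equal(tab$n_stimuli[1:2], c(16L, 6L))
  expect_equal(tab$dilutions[3], "staircase")
  expect_true(all(c("mean_reliability", "se_mean_reliability", "p5", "p50",
                    "p95", "pct_convergence_failures") %in% names(tab)))
})
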