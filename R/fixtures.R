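#' Generate small deterministic example datasets
#'
#' Writes three small CSV fixtures into `dir`:
#'
#' * `responses_nshap_synthetic.csv` — 5 subjects on the 6-step in-home
#'   protocol, including at least one don't-know and one refused response
#'   (the target-position schedule is a synthetic stand-in for the
#'   unpublished field schedule);
#' * `responses_normosmic20.csv` — 20 subjects on the 16-dilution constant
#'   stimuli protocol, simulated from the normosmic population preset;
#' * `staircase_trace.csv` — a hand-traced staircase response sequence whose
#'   reversal steps are 9, 11, 9, 11, 9, 11, 9, so the standard last-4 score
#'   is exactly 10.0.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the same seed always regenerates identical
#'   files.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 20260101) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  withr::with_seed(seed, {
    # (a) survey-style 6-item table with non-response codes
    nshap <- protocol_preset("nshap")
    tr <- sample_thresholds(population_preset("nshap_gamma"), 5)
    tab <- simulate_constant_stimuli(tr, 0.76, nshap)
    tab$subject_id <- sprintf("S%02d", tab$subject_id)
    tab$response[tab$presentation_index == 1 & tab$subject_id == "S01"] <- "dont_know"
    tab$response[tab$presentation_index == 2 & tab$subject_id == "S03"] <- "refused"
    p1 <- file.path(dir, "responses_nshap_synthetic.csv")
    write_responses(tab, p1)

    # (b) 20 normosmics on the full 16-dilution series
    pop <- population_preset("normosmic")
    tr2 <- sample_thresholds(pop, 20)
    tab2 <- simulate_constant_stimuli(tr2, pop$beta, constant_stimuli(1:16))
    tab2$subject_id <- sprintf("N%02d", tab2$subject_id)
    p2 <- file.path(dir, "responses_normosmic20.csv")
    write_responses(tab2, p2)

    # (c) hand-traced staircase run: descend 15..10 on incorrects, then
    # oscillate 9/10/11; reversals land on 9,11,9,11,9,11,9
    steps <- c(15, 14, 13, 12, 11, 10,
               9, 9, 10, 10, 11, 10, 9, 9, 10, 10, 11, 10, 9, 9,
               10, 10, 11, 10, 9, 9)
    resp <- c(0, 0, 0, 0, 0, 0,
              1, 1, 1, 1, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1,
              1, 1, 0, 0, 1, 1)
    trace <- tibble(
      subject_id = "T01",
      presentation_index = seq_along(steps),
      step = steps,
      target_position = NA_integer_,
      response = ifelse(resp == 1, "correct", "incorrect")
    )
    p3 <- file.path(dir, "staircase_trace.csv")
    write_responses(trace, p3)
    paths <- c(p1, p2, p3)
  })
  invisible(paths)
}
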