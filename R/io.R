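#' Read and write response tables
#'
#' Response files are plain CSV with header columns `subject_id`,
#' `presentation_index`, `dilution_step`, `target_position` (optional, 1-3 or
#' empty) and `response`, where the response token is one of `1` (correct),
#' `0` (incorrect), `DK` (don't know) or `REF` (refused). `DK` and `REF` are
#' kept distinct in files (they record different survey events) even though
#' the imputation model treats them identically. The read/write round trip is
#' lossless.
#'
#' @param path File path.
#' @param data A response table as produced by [read_responses()] or
#'   [simulate_constant_stimuli()].
#' @return `read_responses()` returns a tibble with columns `subject_id`
#'   (character), `presentation_index` (integer), `step` (numeric),
#'   `target_position` (integer or NA) and `response` (one of `"correct"`,
#'   `"incorrect"`, `"dont_know"`, `"refused"`). `write_responses()` returns
#'   `path` invisibly.
#' @export
read_responses <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    presentation_index = readr::col_integer(),
    dilution_step = readr::col_double(),
    target_position = readr::col_integer(),
    response = readr::col_character()
  ))
  tokens <- c(`1` = "correct", `0` = "incorrect", DK = "dont_know", REF = "refused")
  bad <- !raw$response %in% names(tokens)
  if (any(bad)) {
    lines <- which(bad)[1] + 1L  # +1 for the header line
    abort(sprintf("Unknown response token '%s' at line %d of %s.",
                  raw$response[which(bad)[1]], lines, path),
          class = "olf_malformed_file")
  }
  dup <- duplicated(raw[c("subject_id", "presentation_index")])
  if (any(dup)) {
    abort(sprintf("Duplicate (subject_id, presentation_index) at line %d of %s.",
                  which(dup)[1] + 1L, path),
          class = "olf_malformed_file")
  }
  tibble(
    subject_id = raw$subject_id,
    presentation_index = raw$presentation_index,
    step = raw$dilution_step,
    target_position = raw$target_position,
    response = unname(tokens[raw$response])
  )
}

#' @rdname read_responses
#' @export
write_responses <- function(data, path) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "step", "response") %in% names(data)))
  tokens <- c(correct = "1", incorrect = "0", dont_know = "DK", refused = "REF")
  stopifnot(all(data$response %in% names(tokens)))
  out <- tibble(
    subject_id = as.character(data$subject_id),
    presentation_index = if ("presentation_index" %in% names(data)) {
      as.integer(data$presentation_index)
    } else {
      stats::ave(seq_len(nrow(data)), data$subject_id, FUN = seq_along)
    },
    dilution_step = data$step,
    target_position = if ("target_position" %in% names(data)) {
      as.integer(data$target_position)
    } else NA_integer_,
    response = unname(tokens[data$response])
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and write run configurations
#'
#' A run configuration is a YAML file that fully determines a simulation run:
#' a `population` block (either `preset: <name>` or explicit
#' `family`/parameters/`beta`), one or more `protocol` blocks (`type:
#' constant` with `steps`, or `type: staircase` with optional rule fields),
#' and scalars `n_subjects`, `n_reps`, `seed`, `estimator`, `m_imputations`,
#' `n_quadrature`. [write_run_config()] serializes a resolved configuration
#' next to any output it produced so the run can be reproduced exactly.
#'
#' @param path YAML file path.
#' @param config A list as returned by `read_run_config()`.
#' @return `read_run_config()`: a list with elements `population`
#'   (`olf_population`), `protocols` (named list of protocols), `n_subjects`,
#'   `n_reps`, `seed`, `estimator`, `m_imputations`, `n_quadrature`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$population)) {
    abort("Config is missing a `population` block.", class = "olf_bad_config")
  }
  pop <- parse_population(cfg$population)
  pblocks <- cfg$protocols %||% (if (!is.null(cfg$protocol)) list(cfg$protocol) else NULL)
  if (is.null(pblocks)) {
    abort("Config is missing a `protocol` or `protocols` block.",
          class = "olf_bad_config")
  }
  if (is.null(names(pblocks)) || any(names(pblocks) == "")) {
    names(pblocks) <- paste0("protocol_", seq_along(pblocks))
  }
  protocols <- lapply(pblocks, parse_protocol)
  list(
    population = pop,
    protocols = protocols,
    n_subjects = cfg$n_subjects %||% 100L,
    n_reps = cfg$n_reps %||% 500L,
    seed = cfg$seed %||% 1L,
    estimator = cfg$estimator,
    m_imputations = cfg$m_imputations %||% 10L,
    n_quadrature = cfg$n_quadrature %||% 61L
  )
}

parse_population <- function(block) {
  if (!is.null(block$preset)) return(population_preset(block$preset))
  fam <- block$family %||% abort("Population block needs `preset` or `family`.",
                                 class = "olf_bad_config")
  if (fam == "normal") {
    population_normal(block$mean_t, block$sd_t, block$beta)
  } else if (fam %in% c("shifted_gamma", "gamma")) {
    population_gamma(block$shape, block$scale, block$location, block$beta)
  } else {
    abort(sprintf("Unknown population family '%s'.", fam), class = "olf_bad_config")
  }
}

parse_protocol <- function(block) {
  if (!is.null(block$preset)) return(protocol_preset(block$preset))
  type <- block$type %||% "constant"
  if (type == "constant") {
    constant_stimuli(unlist(block$steps),
                     order_policy = block$order_policy %||% "as_given",
                     target_positions = if (!is.null(block$target_positions))
                       unlist(block$target_positions) else NULL)
  } else if (type == "staircase") {
    staircase(
      step_set = if (!is.null(block$step_set)) unlist(block$step_set) else 1:16,
      start_steps = if (!is.null(block$start_steps)) unlist(block$start_steps) else c(15, 16),
      reversals_to_stop = block$reversals_to_stop %||% 7,
      reversals_to_score = block$reversals_to_score %||% 4,
      max_presentations = block$max_presentations %||% 60,
      clamp = block$clamp %||% "ceiling"
    )
  } else {
    abort(sprintf("Unknown protocol type '%s'.", type), class = "olf_bad_config")
  }
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  ser_pop <- function(pop) {
    if (pop$family == "normal") {
      list(family = "normal", mean_t = pop$mean_t, sd_t = pop$sd_t, beta = pop$beta)
    } else {
      list(family = "shifted_gamma", shape = pop$shape, scale = pop$scale,
           location = pop$location, beta = pop$beta)
    }
  }
  ser_proto <- function(p) {
    if (inherits(p, "olf_constant")) {
      out <- list(type = "constant", steps = p$steps, order_policy = p$order_policy)
      if (!is.null(p$target_positions)) out$target_positions <- p$target_positions
      out
    } else {
      list(type = "staircase", step_set = p$step_set, start_steps = p$start_steps,
           reversals_to_stop = p$reversals_to_stop,
           reversals_to_score = p$reversals_to_score,
           max_presentations = p$max_presentations, clamp = p$clamp)
    }
  }
  yaml::write_yaml(list(
    population = ser_pop(config$population),
    protocols = lapply(config$protocols, ser_proto),
    n_subjects = config$n_subjects, n_reps = config$n_reps, seed = config$seed,
    estimator = config$estimator, m_imputations = config$m_imputations,
    n_quadrature = config$n_quadrature
  ), path)
  invisible(path)
}
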