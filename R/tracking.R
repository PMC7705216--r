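# Trial-sequence procedures: the dynamic-range pre-phase and the four
# trackers (fixed-level, slope-adaptive, MEI-adaptive, uniform-random).
# All trackers run against any responder (simulated listener or plain
# function) and are deterministic given their seed.

#' Dynamic range of presentation levels
#'
#' @param lower,upper Bounds in dB SPL, `0 <= lower < upper <= 110`.
#' @return An object of class `dynamic_range`.
#' @export
dynamic_range <- function(lower, upper) {
  stopifnot(is_scalar_number(lower), is_scalar_number(upper))
  if (lower < 0 || upper > 110 || lower >= upper) {
    stop("dynamic range must satisfy 0 <= lower < upper <= 110",
         call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "dynamic_range")
}

#' @export
print.dynamic_range <- function(x, ...) {
  cat(sprintf("<dynamic_range> [%g, %g] dB SPL\n", x$lower, x$upper))
  invisible(x)
}

new_session_log <- function(trials, dr, procedure, frequency_hz, seed,
                            run_limits = NULL, posterior = NULL) {
  structure(list(trials = trials,
                 dynamic_range = dr,
                 procedure = procedure,
                 frequency_hz = frequency_hz,
                 seed = seed,
                 run_limits = run_limits,
                 posterior = posterior),
            class = "cls_session")
}

#' @export
print.cls_session <- function(x, ...) {
  cat("<cls_session>", x$procedure, "procedure,", nrow(x$trials), "trials,",
      sprintf("dynamic range [%g, %g] dB SPL\n",
              x$dynamic_range$lower, x$dynamic_range$upper))
  invisible(x)
}

make_trial_df <- function(n, procedure) {
  data.frame(index = seq_len(n),
             run = NA_integer_,
             level = NA_real_,
             response_cu = NA_integer_,
             procedure = procedure,
             entropy_after = NA_real_)
}

#' Estimate a listener's dynamic range
#'
#' First stage of every CLS session. Two sequences are interleaved
#' (ascending first), both starting at `start_level` and stepping by
#' `step` dB. The ascending sequence stops at the first "Too Loud"
#' (CU 50) judgement or at 110 dB SPL; the upper end of the dynamic range
#' is the last ascending level not judged "Too Loud". The descending
#' sequence stops at the first "Can't Hear" (CU 0) judgement or at 0 dB
#' SPL; the lower end is the last audible descending level. If the
#' starting level is already inaudible, the lowest audible level of the
#' ascending sequence is used instead; if nothing is audible anywhere the
#' range is degenerate and an error is raised.
#'
#' @param responder A `simulated_listener` or a function `f(level) -> CU`.
#' @param start_level Starting level for both sequences, dB SPL.
#' @param step Step size, dB.
#' @return A [dynamic_range()]. The midpoint of this range is the
#'   starting level for the second-stage adaptive procedures.
#' @export
estimate_dynamic_range <- function(responder, start_level = 60, step = 10) {
  stopifnot(is_scalar_number(start_level), is_scalar_number(step), step > 0)
  asc_levels <- numeric(0); asc_resp <- integer(0)
  desc_levels <- numeric(0); desc_resp <- integer(0)
  asc_next <- start_level; desc_next <- start_level
  asc_done <- FALSE; desc_done <- FALSE
  turn_asc <- TRUE
  while (!asc_done || !desc_done) {
    if (turn_asc && !asc_done) {
      r <- respond(responder, asc_next)
      asc_levels <- c(asc_levels, asc_next); asc_resp <- c(asc_resp, r)
      if (r == 50L || asc_next >= 110) {
        asc_done <- TRUE
      } else {
        asc_next <- min(asc_next + step, 110)
      }
    } else if (!turn_asc && !desc_done) {
      r <- respond(responder, desc_next)
      desc_levels <- c(desc_levels, desc_next); desc_resp <- c(desc_resp, r)
      if (r == 0L || desc_next <= 0) {
        desc_done <- TRUE
      } else {
        desc_next <- max(desc_next - step, 0)
      }
    }
    turn_asc <- !turn_asc
  }
  not_too_loud <- asc_levels[asc_resp < 50L]
  if (length(not_too_loud) == 0L) {
    stop("degenerate dynamic range: the starting level was already 'Too Loud'",
         call. = FALSE)
  }
  upper <- max(not_too_loud)
  audible_desc <- desc_levels[desc_resp >= 5L]
  lower <- if (length(audible_desc) > 0L) {
    min(audible_desc)
  } else {
    audible_asc <- asc_levels[asc_resp >= 5L]
    if (length(audible_asc) == 0L) {
      stop("degenerate dynamic range: no level was audible", call. = FALSE)
    }
    min(audible_asc)
  }
  if (lower >= upper) {
    stop("degenerate dynamic range: lower bound meets upper bound",
         call. = FALSE)
  }
  dynamic_range(lower, upper)
}

# Randomised level order for the fixed-level procedure: each grid level
# `reps` times, no immediate repeats, consecutive jumps bounded by
# `max_transition`. Sequential random construction with restarts.
constrained_level_sequence <- function(levels, reps = 10, max_transition = 45,
                                       max_attempts = 500L) {
  n_total <- length(levels) * reps
  for (attempt in seq_len(max_attempts)) {
    counts <- rep(reps, length(levels))
    out <- numeric(n_total)
    prev <- NA_integer_
    ok <- TRUE
    for (t in seq_len(n_total)) {
      allowed <- which(counts > 0L)
      if (!is.na(prev)) {
        allowed <- allowed[abs(levels[allowed] - levels[prev]) <=
                             max_transition + 1e-9 & allowed != prev]
      }
      if (length(allowed) == 0L) {
        ok <- FALSE
        break
      }
      pick <- allowed[sample.int(length(allowed), 1L)]
      counts[pick] <- counts[pick] - 1L
      out[t] <- levels[pick]
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("could not build a constraint-satisfying level order after ",
       max_attempts, " attempts", call. = FALSE)
}

#' Fixed-level (reference) procedure
#'
#' Presents every 5-dB grid level inside the dynamic range, each repeated
#' 10 times, in a randomised order in which the same level is never
#' presented consecutively and consecutive levels never differ by more
#' than 45 dB. A full-range listener receives up to 220 trials; this is
#' the time-consuming reference against which the adaptive procedures are
#' judged.
#'
#' @param responder A `simulated_listener` or function `f(level) -> CU`.
#' @param dr A [dynamic_range()].
#' @param seed Integer seed for the level randomisation.
#' @param frequency_hz Stimulus frequency label.
#' @param reps Presentations per level (default 10).
#' @return A `cls_session` log.
#' @export
run_fixed_level <- function(responder, dr, seed = 1L, frequency_hz = 1000,
                            reps = 10L) {
  stopifnot(inherits(dr, "dynamic_range"))
  levels <- seq(dr$lower, dr$upper, by = 5)
  order <- local_seed(seed,
                      constrained_level_sequence(levels, reps = reps,
                                                 max_transition = 45))
  trials <- make_trial_df(length(order), "fixed")
  trials$run <- 1L
  for (t in seq_along(order)) {
    trials$level[t] <- order[t]
    trials$response_cu[t] <- respond(responder, order[t])
  }
  new_session_log(trials, dr, "fixed", frequency_hz, seed)
}

# Per-run upper-limit rule shared by the adaptive procedures: any "Too
# Loud" response in the run lowers the next run's upper limit by 5 dB
# (never collapsing onto the lower limit); otherwise it rises by 5 dB,
# capped at 110 dB SPL.
next_upper_limit <- function(responses_cu, lower, upper) {
  if (any(responses_cu == 50L)) {
    max(lower + 5, upper - 5)
  } else {
    min(upper + 5, 110)
  }
}

#' Slope-adaptive procedure
#'
#' Five runs of nine trials. Within each run the nine levels evenly span
#' the current limits and are presented in seeded random order. After
#' each run the upper limit moves by the shared rule: down 5 dB after any
#' "Too Loud" response, otherwise up 5 dB but never above 110 dB SPL.
#'
#' @inheritParams run_fixed_level
#' @param n_runs,trials_per_run Run structure (defaults 5 x 9 = 45
#'   trials).
#' @return A `cls_session` log with per-run limits in `$run_limits`.
#' @export
run_slope_adaptive <- function(responder, dr, seed = 1L, frequency_hz = 1000,
                               n_runs = 5L, trials_per_run = 9L) {
  stopifnot(inherits(dr, "dynamic_range"))
  local_seed(seed, {
    lower <- dr$lower
    upper <- dr$upper
    trials <- make_trial_df(n_runs * trials_per_run, "slope")
    run_limits <- data.frame(run = seq_len(n_runs), lower = NA_real_,
                             upper = NA_real_)
    t <- 0L
    for (run in seq_len(n_runs)) {
      run_limits$lower[run] <- lower
      run_limits$upper[run] <- upper
      levels <- seq(lower, upper, length.out = trials_per_run)
      levels <- levels[sample.int(trials_per_run)]
      resp <- integer(trials_per_run)
      for (j in seq_len(trials_per_run)) {
        t <- t + 1L
        resp[j] <- respond(responder, levels[j])
        trials$run[t] <- run
        trials$level[t] <- levels[j]
        trials$response_cu[t] <- resp[j]
      }
      upper <- next_upper_limit(resp, lower, upper)
    }
    new_session_log(trials, dr, "slope", frequency_hz, seed, run_limits)
  })
}

#' MEI-adaptive procedure
#'
#' Five runs of nine trials. The first level is the midpoint of the
#' dynamic range (snapped to the 5-dB grid); every subsequent level is
#' chosen by [select_mei_level()] to minimise the expected posterior
#' entropy over the catalog, subject to the presentation constraints
#' (current run limits, maximum 45-dB transition, no immediate repeats).
#' The posterior persists across runs and the entropy after each update
#' is recorded in the log. The per-run upper-limit rule is the same as in
#' [run_slope_adaptive()].
#'
#' @inheritParams run_slope_adaptive
#' @param catalog The `cls_catalog` hypothesis space.
#' @param constraints Optional [selection_constraints()]; the limits and
#'   previous level are managed per trial, the remaining fields
#'   (transition cap, repeat rule, grid step) are taken from this object.
#' @return A `cls_session` log; the final posterior is in `$posterior`.
#' @export
run_mei_adaptive <- function(responder, catalog, dr, seed = 1L,
                             frequency_hz = 1000,
                             constraints = selection_constraints(),
                             n_runs = 5L, trials_per_run = 9L) {
  stopifnot(inherits(dr, "dynamic_range"), inherits(catalog, "cls_catalog"))
  step <- constraints$level_grid_step
  lik <- catalog_likelihoods(catalog, level_grid(0, 110, step))
  state <- init_posterior(catalog)
  lower <- dr$lower
  upper <- dr$upper
  trials <- make_trial_df(n_runs * trials_per_run, "mei")
  run_limits <- data.frame(run = seq_len(n_runs), lower = NA_real_,
                           upper = NA_real_)
  prev <- NULL
  t <- 0L
  for (run in seq_len(n_runs)) {
    run_limits$lower[run] <- lower
    run_limits$upper[run] <- upper
    resp <- integer(trials_per_run)
    for (j in seq_len(trials_per_run)) {
      t <- t + 1L
      if (is.null(prev)) {
        grid <- level_grid(lower, upper, step)
        level <- grid[which.min(abs(grid - (lower + upper) / 2))]
      } else {
        cons <- selection_constraints(
          level_grid_step = step,
          lower_limit = lower,
          upper_limit = upper,
          max_transition = constraints$max_transition,
          forbid_consecutive_repeat = constraints$forbid_consecutive_repeat,
          previous_level = prev)
        level <- as.numeric(select_mei_level(state, catalog, cons, lik = lik))
      }
      resp[j] <- respond(responder, level)
      state <- update_posterior(state, catalog, level, resp[j])
      trials$run[t] <- run
      trials$level[t] <- level
      trials$response_cu[t] <- resp[j]
      trials$entropy_after[t] <- entropy(state)
      prev <- level
    }
    upper <- next_upper_limit(resp, lower, upper)
  }
  new_session_log(trials, dr, "mei", frequency_hz, seed, run_limits,
                  posterior = state)
}

#' Uniform-random (URD) procedure
#'
#' Comparison tracker emulating an adaptive procedure without informed
#' level selection: each of the 45 levels is drawn uniformly from the
#' 5-dB grid within the current limits, with the same per-run upper-limit
#' rule as the other adaptive procedures.
#'
#' @inheritParams run_slope_adaptive
#' @return A `cls_session` log.
#' @export
run_urd <- function(responder, dr, seed = 1L, frequency_hz = 1000,
                    n_runs = 5L, trials_per_run = 9L) {
  stopifnot(inherits(dr, "dynamic_range"))
  local_seed(seed, {
    lower <- dr$lower
    upper <- dr$upper
    trials <- make_trial_df(n_runs * trials_per_run, "urd")
    run_limits <- data.frame(run = seq_len(n_runs), lower = NA_real_,
                             upper = NA_real_)
    t <- 0L
    for (run in seq_len(n_runs)) {
      run_limits$lower[run] <- lower
      run_limits$upper[run] <- upper
      resp <- integer(trials_per_run)
      for (j in seq_len(trials_per_run)) {
        t <- t + 1L
        level <- sample_one(level_grid(lower, upper, 5))
        resp[j] <- respond(responder, level)
        trials$run[t] <- run
        trials$level[t] <- level
        trials$response_cu[t] <- resp[j]
      }
      upper <- next_upper_limit(resp, lower, upper)
    }
    new_session_log(trials, dr, "urd", frequency_hz, seed, run_limits)
  })
}

#' Write / read a session log as CSV
#'
#' Columns `index,run,procedure,frequency_hz,level_db_spl,response_cu,`
#' `entropy_bits`; session metadata (procedure, seed, dynamic range) is
#' stored in `#`-prefixed header lines so a log round-trips.
#'
#' @param log A `cls_session`.
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly;
#'   `read_session_log` returns a `cls_session` (without the in-memory
#'   posterior).
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "cls_session"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# clsmei session log",
               paste("# procedure:", log$procedure),
               paste("# frequency_hz:", log$frequency_hz),
               paste("# seed:", log$seed),
               paste("# dynamic_range:", log$dynamic_range$lower,
                     log$dynamic_range$upper)), con)
  df <- data.frame(index = log$trials$index,
                   run = log$trials$run,
                   procedure = log$trials$procedure,
                   frequency_hz = log$frequency_hz,
                   level_db_spl = log$trials$level,
                   response_cu = log$trials$response_cu,
                   entropy_bits = log$trials$entropy_after)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "#")]
  meta <- function(key) {
    line <- grep(paste0("^# ", key, ":"), header, value = TRUE)
    if (length(line) == 0L) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", line[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("index", "run", "level_db_spl", "response_cu")
  if (!all(need %in% names(df))) {
    stop("not a session log CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  drs <- strsplit(meta("dynamic_range"), "\\s+")[[1]]
  trials <- data.frame(index = df$index,
                       run = df$run,
                       level = df$level_db_spl,
                       response_cu = df$response_cu,
                       procedure = if ("procedure" %in% names(df)) df$procedure else meta("procedure"),
                       entropy_after = if ("entropy_bits" %in% names(df)) df$entropy_bits else NA_real_)
  new_session_log(trials,
                  dynamic_range(as.numeric(drs[1]), as.numeric(drs[2])),
                  meta("procedure"),
                  as.numeric(meta("frequency_hz")),
                  as.integer(meta("seed")))
}
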