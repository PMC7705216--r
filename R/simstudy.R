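# Monte-Carlo simulation study: hundreds of simulated listeners are run
# through the MEI and uniform-random (URD) trackers, and posterior
# entropy plus the error of the running maximum-likelihood CLS estimate
# are recorded after every trial. This is the framework that separates
# "the tracker reduces catalog uncertainty" (entropy) from "the tracker
# produces a more accurate loudness function" (rmse) — two claims the
# entropy criterion does not tie together.

#' Configuration for a simulation study
#'
#' @param n_listeners Number of simulated listeners.
#' @param catalog The `cls_catalog` used both as tracking hypothesis
#'   space and (for `listener_mode = "from_catalog"`) as the population
#'   the listeners are drawn from.
#' @param trackers Subset of `c("mei", "urd")`.
#' @param trials_per_track Trials per session; must be a multiple of the
#'   9-trial run length (default 45 = 5 runs).
#' @param seed Integer master seed; every listener and track derives its
#'   randomness from it.
#' @param listener_mode `"from_catalog"` or `"perturbed"` (see
#'   [sample_listeners()]).
#' @param perturb_sd Boundary jitter SD (dB) for perturbed listeners.
#' @return An object of class `sim_study_config`.
#' @export
sim_study_config <- function(n_listeners, catalog,
                             trackers = c("mei", "urd"),
                             trials_per_track = 45L,
                             seed = 1L,
                             listener_mode = c("from_catalog", "perturbed"),
                             perturb_sd = 3) {
  stopifnot(is_scalar_number(n_listeners), n_listeners >= 1,
            inherits(catalog, "cls_catalog"),
            is_scalar_number(trials_per_track), trials_per_track %% 9 == 0,
            is_scalar_number(seed))
  trackers <- match.arg(trackers, c("mei", "urd"), several.ok = TRUE)
  structure(list(n_listeners = as.integer(n_listeners),
                 catalog = catalog,
                 trackers = trackers,
                 trials_per_track = as.integer(trials_per_track),
                 seed = as.integer(seed),
                 listener_mode = match.arg(listener_mode),
                 perturb_sd = perturb_sd),
            class = "sim_study_config")
}

# Fallback presentation range when the stochastic pre-phase degenerates
# (e.g. a near-threshold listener answering "Can't Hear" at every probe):
# the true boundary span widened by 5 dB and clipped to the instrument
# limits.
true_range_fallback <- function(true_mcpf) {
  lv <- true_mcpf$boundary_levels
  dynamic_range(max(0, snap_to_grid(lv[1] - 5)),
                min(110, max(snap_to_grid(lv[10] + 5), snap_to_grid(lv[1]) + 10)))
}

# One traced track: runs the selector, maintaining the posterior (for
# entropy) and the cumulative per-entry log-likelihood (for the running
# ML-CLS estimate). Returns per-trial entropy and rmse of the ML estimate
# against the listener's true boundary levels over CU 5-45.
traced_track <- function(listener, catalog, dr, selector, seed, lik_full,
                         n_runs, trials_per_run, boundary_mat) {
  local_seed(seed, {
    step <- 5
    grid_full <- level_grid(0, 110, step)
    p <- rep(1 / length(catalog), length(catalog))
    ll <- numeric(length(catalog))
    true9 <- listener$true_mcpf$boundary_levels[1:9]
    lower <- dr$lower
    upper <- dr$upper
    n_trials <- n_runs * trials_per_run
    ent <- numeric(n_trials)
    err <- numeric(n_trials)
    prev <- NULL
    t <- 0L
    state <- new_posterior(p)
    for (run in seq_len(n_runs)) {
      resp <- integer(trials_per_run)
      for (j in seq_len(trials_per_run)) {
        t <- t + 1L
        if (selector == "mei") {
          if (is.null(prev)) {
            grid <- level_grid(lower, upper, step)
            level <- grid[which.min(abs(grid - (lower + upper) / 2))]
          } else {
            cons <- selection_constraints(lower_limit = lower,
                                          upper_limit = upper,
                                          previous_level = prev)
            level <- as.numeric(select_mei_level(state, catalog, cons,
                                                 lik = lik_full))
          }
        } else {
          level <- sample_one(level_grid(lower, upper, step))
        }
        r <- respond(listener, level)
        resp[j] <- r
        li <- match(level, grid_full)
        ci <- match(r, cu_values())
        likcol <- lik_full[, ci, li]
        state <- new_posterior(posterior_update_vec(state$probs, likcol),
                               state$n_trials_absorbed + 1L)
        ll <- ll + log(likcol)
        ent[t] <- entropy(state)
        best <- which.max(ll)
        err[t] <- rmse(boundary_mat[best, 1:9], true9)
        prev <- level
      }
      upper <- next_upper_limit(resp, lower, upper)
    }
    list(entropy = ent, rmse = err)
  })
}

#' Run the Monte-Carlo simulation study
#'
#' For each simulated listener and each tracker, runs a full session
#' (dynamic-range pre-phase followed by `trials_per_track` adaptive
#' trials) and records, after every trial, the posterior entropy over the
#' catalog and the rmse between the running ML-CLS estimate and the
#' listener's true CLS function over CU 5-45 (dB). Curves are averaged
#' across listeners. Deterministic given the config seed.
#'
#' @param cfg A [sim_study_config()].
#' @return A list of class `cls_simstudy`: `curves` (data frame
#'   `tracker, trial, mean_entropy, mean_rmse`), `summary` (per-tracker
#'   values at the final trial), `rmse_domain` (metadata), and the
#'   config (without the catalog entries).
#' @export
run_simulation_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_study_config"))
  catalog <- cfg$catalog
  n_runs <- cfg$trials_per_track %/% 9L
  seeds <- local_seed(cfg$seed, {
    list(roster = sample.int(.Machine$integer.max, 1),
         tracks = matrix(sample.int(.Machine$integer.max,
                                    cfg$n_listeners * length(cfg$trackers)),
                         nrow = cfg$n_listeners),
         resp = matrix(sample.int(.Machine$integer.max,
                                  cfg$n_listeners * length(cfg$trackers)),
                       nrow = cfg$n_listeners))
  })
  listeners <- sample_listeners(catalog, cfg$n_listeners,
                                seed = seeds$roster,
                                mode = cfg$listener_mode,
                                perturb_sd = cfg$perturb_sd,
                                listener_mode = "stochastic")
  lik_full <- catalog_likelihoods(catalog, level_grid(0, 110, 5))
  boundary_mat <- t(vapply(catalog$entries, function(e) e$boundary_levels,
                           numeric(10)))
  res <- lapply(cfg$trackers, function(tr) {
    ent <- matrix(NA_real_, cfg$n_listeners, cfg$trials_per_track)
    err <- matrix(NA_real_, cfg$n_listeners, cfg$trials_per_track)
    ti <- match(tr, cfg$trackers)
    for (i in seq_len(cfg$n_listeners)) {
      # fresh response stream per track so the trackers see independent,
      # identically distributed sessions from the same true listener
      li <- simulated_listener(listeners[[i]]$true_mcpf,
                               seed = seeds$resp[i, ti],
                               mode = "stochastic")
      dr <- tryCatch(estimate_dynamic_range(li),
                     error = function(e) true_range_fallback(li$true_mcpf))
      out <- traced_track(li, catalog, dr, tr, seeds$tracks[i, ti],
                          lik_full, n_runs, 9L, boundary_mat)
      ent[i, ] <- out$entropy
      err[i, ] <- out$rmse
    }
    data.frame(tracker = tr,
               trial = seq_len(cfg$trials_per_track),
               mean_entropy = colMeans(ent),
               mean_rmse = colMeans(err))
  })
  curves <- do.call(rbind, res)
  final <- curves[curves$trial == cfg$trials_per_track, ]
  summary <- data.frame(tracker = final$tracker,
                        final_entropy = final$mean_entropy,
                        final_rmse = final$mean_rmse)
  structure(list(curves = curves,
                 summary = summary,
                 rmse_domain = "true vs ML-estimated boundary levels, CU 5-45, dB",
                 config = list(n_listeners = cfg$n_listeners,
                               n_catalog_entries = length(catalog),
                               trackers = cfg$trackers,
                               trials_per_track = cfg$trials_per_track,
                               seed = cfg$seed,
                               listener_mode = cfg$listener_mode,
                               perturb_sd = cfg$perturb_sd)),
            class = "cls_simstudy")
}

#' @export
print.cls_simstudy <- function(x, ...) {
  cat("<cls_simstudy>", x$config$n_listeners, "listeners,",
      x$config$trials_per_track, "trials per track\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
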