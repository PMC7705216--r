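# Bayesian inference over catalog entries and maximum-expected-information
# (MEI) stimulus selection.
#
# The listener's loudness function is treated as an unknown drawn from the
# finite catalog. Each trial multiplies the posterior by the per-entry
# likelihood of the observed category and renormalises; remaining
# uncertainty is the Shannon entropy (bits) of the posterior. MEI picks
# the next level whose response is expected to reduce that entropy most.

# Per-trial likelihood floor. A single lapse response would otherwise zero
# an entry permanently; the floor keeps posteriors and ML fits robust
# without measurably distorting informative likelihoods.
LIK_FLOOR <- 1e-6

#' Per-entry category likelihoods on a level grid
#'
#' Precomputes, for every catalog entry, the floored probability of each
#' of the 11 response categories at each level of a grid. Trackers and
#' the simulation study compute this once per session and pass it to the
#' posterior/selection functions to avoid recomputation.
#'
#' @param catalog A `cls_catalog`.
#' @param levels Numeric vector of levels, dB SPL.
#' @param floor Lower bound applied to every likelihood entry.
#' @return A numeric array of dim `c(n_entries, 11, length(levels))` with
#'   `dimnames` carrying CU codes and level labels.
#' @export
catalog_likelihoods <- function(catalog, levels, floor = LIK_FLOOR) {
  stopifnot(inherits(catalog, "cls_catalog"))
  n <- length(catalog)
  arr <- array(NA_real_, dim = c(n, 11L, length(levels)),
               dimnames = list(NULL, as.character(cu_values()),
                               as.character(levels)))
  for (i in seq_len(n)) {
    arr[i, , ] <- mcpf_prob_matrix(catalog$entries[[i]], levels)
  }
  pmax(arr, floor)
}

#' Initialise the posterior over catalog entries
#'
#' Before the first trial every catalog entry is assumed equally likely,
#' so the posterior is uniform and its entropy is `log2(N)` bits.
#'
#' @param catalog A `cls_catalog`.
#' @return An object of class `cls_posterior` with fields `probs` and
#'   `n_trials_absorbed`.
#' @export
#' @examples
#' cat4 <- generate_catalog(catalog_gen_params(n_entries = 4, seed = 1))
#' entropy(init_posterior(cat4))  # 2 bits
init_posterior <- function(catalog) {
  stopifnot(inherits(catalog, "cls_catalog"))
  new_posterior(rep(1 / length(catalog), length(catalog)), 0L)
}

new_posterior <- function(probs, n_trials_absorbed = 0L) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("posterior probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(probs = as.numeric(probs),
                 n_trials_absorbed = as.integer(n_trials_absorbed)),
            class = "cls_posterior")
}

#' @export
print.cls_posterior <- function(x, ...) {
  cat("<cls_posterior> over", length(x$probs), "entries;",
      x$n_trials_absorbed, "trials absorbed;",
      sprintf("entropy %.3f bits\n", entropy(x)))
  invisible(x)
}

# p' = p * lik / sum(p * lik), shared by the public update and the batch
# machinery.
posterior_update_vec <- function(p, lik) {
  w <- p * lik
  s <- sum(w)
  if (s <= 0) {
    stop("all catalog entries assign zero likelihood to this trial",
         call. = FALSE)
  }
  w / s
}

#' Absorb one trial into the posterior
#'
#' The posterior probability of each entry is multiplied by that entry's
#' (floored) probability of the observed response at the presented level,
#' then renormalised by the sum over entries. The input state is not
#' modified.
#'
#' @param state A `cls_posterior`.
#' @param catalog The `cls_catalog` the state is defined over.
#' @param level Presented level, dB SPL (0 to 110).
#' @param response_cu Observed category, CU 0 to 50 in steps of 5.
#' @return A new `cls_posterior`.
#' @export
update_posterior <- function(state, catalog, level, response_cu) {
  stopifnot(inherits(state, "cls_posterior"), inherits(catalog, "cls_catalog"))
  if (length(state$probs) != length(catalog)) {
    stop("posterior length does not match catalog size", call. = FALSE)
  }
  if (!is_scalar_number(level) || level < 0 || level > 110) {
    stop("level must lie in [0, 110] dB SPL", call. = FALSE)
  }
  ci <- match(response_cu, cu_values())
  if (is.na(ci)) {
    stop("response_cu must be one of 0, 5, ..., 50", call. = FALSE)
  }
  lik <- vapply(catalog$entries,
                function(e) max(category_probs(e, level)[ci], LIK_FLOOR),
                numeric(1))
  new_posterior(posterior_update_vec(state$probs, lik),
                state$n_trials_absorbed + 1L)
}

#' Shannon entropy in bits
#'
#' `H = -sum(p * log2(p))` with the `0 log 0 = 0` convention. For a
#' posterior over N entries, `0 <= H <= log2(N)`, with the maximum at the
#' uniform (no-information) state.
#'
#' @param x A `cls_posterior` or a non-negative numeric vector summing
#'   to 1.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(0.5, 0.25, 0.25))  # 1.5 bits
entropy <- function(x) {
  p <- if (inherits(x, "cls_posterior")) x$probs else as.numeric(x)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("entropy() expects a probability vector", call. = FALSE)
  }
  -sum(xlog2x(p))
}

# Internal batch kernel: expected posterior entropy and predictive
# response distribution for each column-block of a likelihood array.
# lik_arr: c(n_entries, 11, n_levels) floored likelihoods.
# Returns list(epe = numeric(n_levels), predictive = 11 x n_levels).
epe_batch <- function(p, lik_arr) {
  d <- dim(lik_arr)
  n_levels <- d[3]
  flat <- matrix(lik_arr, nrow = d[1], ncol = 11L * n_levels)
  w <- p * flat                              # joint p(entry, response) per level
  m <- colSums(w)                            # predictive mass per (response, level)
  pos <- m > 0
  wn <- w[, pos, drop = FALSE]
  wn <- sweep(wn, 2, m[pos], "/")            # posterior given each response
  h <- numeric(length(m))
  h[pos] <- -colSums(xlog2x(wn))
  mm <- matrix(m, nrow = 11L, ncol = n_levels)
  hm <- matrix(h, nrow = 11L, ncol = n_levels)
  msum <- colSums(mm)
  list(epe = colSums(mm * hm) / msum,
       predictive = sweep(mm, 2, msum, "/"))
}

#' Predictive response distribution at a level
#'
#' Posterior-weighted mixture of the catalog entries' category
#' probabilities: `P(c | L) = sum_i p_i P_i(c | L)`, renormalised after
#' the likelihood floor.
#'
#' @inheritParams update_posterior
#' @param level Candidate level, dB SPL.
#' @return Named numeric vector of 11 probabilities summing to 1.
#' @export
predictive_response_dist <- function(state, catalog, level) {
  stopifnot(inherits(state, "cls_posterior"), inherits(catalog, "cls_catalog"))
  lik <- catalog_likelihoods(catalog, level)
  out <- drop(epe_batch(state$probs, lik)$predictive)
  names(out) <- as.character(cu_values())
  out
}

#' Expected posterior entropy after a probe at a level
#'
#' For a candidate level, enumerates all 11 possible responses, computes
#' the entropy of the posterior that each response would produce, and
#' averages them under the predictive response distribution. By concavity
#' of entropy this never exceeds the current entropy: probing can only be
#' expected to reduce uncertainty.
#'
#' @inheritParams predictive_response_dist
#' @return Expected entropy in bits.
#' @export
expected_posterior_entropy <- function(state, catalog, level) {
  stopifnot(inherits(state, "cls_posterior"), inherits(catalog, "cls_catalog"))
  lik <- catalog_likelihoods(catalog, level)
  epe_batch(state$probs, lik)$epe
}

#' Presentation constraints for adaptive level selection
#'
#' @param level_grid_step Candidate grid spacing, dB (default 5, the
#'   granularity used throughout the procedures).
#' @param lower_limit,upper_limit Current presentation limits, dB SPL;
#'   `upper_limit` never exceeds 110.
#' @param max_transition Largest allowed jump between consecutive levels,
#'   dB (default 45; large transitions bias loudness judgements).
#' @param forbid_consecutive_repeat Disallow presenting the same level
#'   twice in a row (default `TRUE`).
#' @param previous_level Level of the preceding trial, dB SPL, or `NULL`
#'   before the first trial.
#' @return An object of class `selection_constraints`.
#' @export
selection_constraints <- function(level_grid_step = 5,
                                  lower_limit = 0,
                                  upper_limit = 110,
                                  max_transition = 45,
                                  forbid_consecutive_repeat = TRUE,
                                  previous_level = NULL) {
  stopifnot(is_scalar_number(level_grid_step), level_grid_step > 0,
            is_scalar_number(lower_limit), is_scalar_number(upper_limit),
            lower_limit <= upper_limit, upper_limit <= 110,
            is_scalar_number(max_transition), max_transition > 0)
  structure(list(level_grid_step = level_grid_step,
                 lower_limit = lower_limit,
                 upper_limit = upper_limit,
                 max_transition = max_transition,
                 forbid_consecutive_repeat = isTRUE(forbid_consecutive_repeat),
                 previous_level = previous_level),
            class = "selection_constraints")
}

# Candidate levels satisfying the constraints.
candidate_levels <- function(constraints) {
  grid <- level_grid(constraints$lower_limit, constraints$upper_limit,
                     constraints$level_grid_step)
  prev <- constraints$previous_level
  if (!is.null(prev)) {
    grid <- grid[abs(grid - prev) <= constraints$max_transition + 1e-9]
    if (constraints$forbid_consecutive_repeat) {
      grid <- grid[abs(grid - prev) > 1e-9]
    }
  }
  grid
}

#' Maximum-expected-information level selection
#'
#' Evaluates the expected posterior entropy of every admissible candidate
#' level (5-dB grid within the current limits, restricted by the maximum
#' transition and no-repeat rules around the previous level) and returns
#' the level with the smallest expected entropy, i.e. the greatest
#' expected information gain. Ties are broken toward the lowest level,
#' favouring listener comfort. Fully deterministic.
#'
#' @inheritParams update_posterior
#' @param constraints A [selection_constraints()] object.
#' @param lik Optional precomputed [catalog_likelihoods()] array covering
#'   the full 0-110 grid at `constraints$level_grid_step` spacing; passed
#'   by the trackers to avoid recomputation.
#' @return The selected level, dB SPL, with the expected entropies of all
#'   candidates attached as attribute `"expected_entropy"`.
#' @export
select_mei_level <- function(state, catalog, constraints = selection_constraints(),
                             lik = NULL) {
  stopifnot(inherits(state, "cls_posterior"),
            inherits(catalog, "cls_catalog"),
            inherits(constraints, "selection_constraints"))
  cand <- candidate_levels(constraints)
  if (length(cand) == 0L) {
    stop("no admissible candidate levels under the given constraints",
         call. = FALSE)
  }
  if (is.null(lik)) {
    lik_c <- catalog_likelihoods(catalog, cand)
  } else {
    full <- level_grid(0, 110, constraints$level_grid_step)
    idx <- match(cand, full)
    if (anyNA(idx)) {
      stop("precomputed likelihood grid does not cover the candidate levels",
           call. = FALSE)
    }
    lik_c <- lik[, , idx, drop = FALSE]
  }
  epe <- epe_batch(state$probs, lik_c)$epe
  best <- cand[epe <= min(epe) + 1e-12][1]   # candidates ascend: lowest tie wins
  attr(best, "expected_entropy") <- stats::setNames(epe, cand)
  best
}
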