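# Monte-Carlo simulated listeners. Each listener owns a true MCPF and a
# private RNG stream, so trackers and listeners never share randomness
# and a roster of listeners is replayable from its seeds.

#' Create a simulated listener
#'
#' @param true_mcpf The listener's true [mcpf()].
#' @param seed Integer seed for the listener's private response stream.
#' @param mode `"stochastic"` samples each response from the category
#'   probabilities at the presented level (the Monte-Carlo mode);
#'   `"modal"` deterministically returns the most probable category,
#'   useful as a noise-free oracle in tests.
#' @return An object of class `simulated_listener`.
#' @export
#' @examples
#' m <- mcpf(seq(10, 100, by = 10), 5)
#' l <- simulated_listener(m, seed = 1, mode = "modal")
#' respond(l, 55)
simulated_listener <- function(true_mcpf, seed = 1L,
                               mode = c("stochastic", "modal")) {
  stopifnot(inherits(true_mcpf, "mcpf"), is_scalar_number(seed))
  mode <- match.arg(mode)
  rng <- new.env(parent = emptyenv())
  rng$seed <- as.integer(seed)
  rng$state <- NULL
  structure(list(true_mcpf = true_mcpf, seed = as.integer(seed),
                 mode = mode, rng = rng),
            class = "simulated_listener")
}

#' @export
print.simulated_listener <- function(x, ...) {
  cat("<simulated_listener>", x$mode, "mode, seed", x$seed,
      "- true entry", x$true_mcpf$entry_id, "\n")
  invisible(x)
}

# Evaluate `code` under the listener's private RNG stream, preserving the
# caller's global stream.
with_listener_rng <- function(rng, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  if (is.null(rng$state)) {
    set.seed(rng$seed)
  } else {
    assign(".Random.seed", rng$state, envir = globalenv())
  }
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Present a level to a responder
#'
#' Generic over responders: a `simulated_listener` answers from its true
#' MCPF; a plain function is called as `f(level)` (the hook for scripted
#' or interactive responders).
#'
#' @param listener A responder.
#' @param level Stimulus level, dB SPL (0 to 110).
#' @return Response in CU (0 to 50 in steps of 5).
#' @export
respond <- function(listener, level) UseMethod("respond")

#' @export
respond.simulated_listener <- function(listener, level) {
  if (!is_scalar_number(level) || level < 0 || level > 110) {
    stop("level must lie in [0, 110] dB SPL", call. = FALSE)
  }
  probs <- category_probs(listener$true_mcpf, level)
  if (listener$mode == "modal") {
    return(cu_values()[which.max(probs)])
  }
  with_listener_rng(listener$rng, sample_one(cu_values(), prob = probs))
}

#' @export
respond.function <- function(listener, level) listener(level)

#' Sample a roster of simulated listeners
#'
#' @param catalog A `cls_catalog` to draw from.
#' @param n Number of listeners.
#' @param seed Integer seed (drives both entry selection and the
#'   per-listener response seeds).
#' @param mode `"from_catalog"` uses catalog entries verbatim, so the
#'   true listener is inside the hypothesis space; `"perturbed"`
#'   additionally jitters each boundary level with Gaussian noise
#'   (`perturb_sd` dB) and re-validates, modelling listeners the catalog
#'   does not contain exactly.
#' @param perturb_sd Jitter SD in dB for `"perturbed"` mode.
#' @param listener_mode Response mode passed to [simulated_listener()].
#' @return List of `simulated_listener` objects.
#' @export
sample_listeners <- function(catalog, n, seed = 1L,
                             mode = c("from_catalog", "perturbed"),
                             perturb_sd = 3,
                             listener_mode = "stochastic") {
  stopifnot(inherits(catalog, "cls_catalog"), is_scalar_number(n), n >= 1)
  mode <- match.arg(mode)
  local_seed(seed, {
    idx <- sample.int(length(catalog), n, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      true <- catalog$entries[[idx[i]]]
      if (mode == "perturbed" && perturb_sd > 0) {
        ok <- FALSE
        for (attempt in seq_len(100L)) {
          lv <- sort(true$boundary_levels + stats::rnorm(10, 0, perturb_sd))
          if (any(diff(lv) <= 0)) next
          cand <- tryCatch(
            mcpf(lv, true$boundary_widths,
                 entry_id = paste0(true$entry_id, "_pert"),
                 frequency_hz = true$frequency_hz,
                 metadata = true$metadata),
            error = function(e) NULL)
          if (!is.null(cand)) {
            true <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("could not perturb entry ", true$entry_id,
               " into a valid MCPF after 100 attempts", call. = FALSE)
        }
      }
      simulated_listener(true, seed = seeds[i], mode = listener_mode)
    })
  })
}
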