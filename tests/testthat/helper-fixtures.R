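# Shared fixtures: tiny MCPFs, catalogs, scripted responders and an
# independent brute-force MEI oracle. Everything is built in code.

# Equally spaced boundaries with a common width.
uniform_mcpf <- function(l1 = 10, l10 = 100, width = 5, id = "fix") {
  mcpf(seq(l1, l10, length.out = 10), width, entry_id = id)
}

small_catalog <- function(n = 4, seed = 1) {
  generate_catalog(catalog_gen_params(n_entries = n, seed = seed))
}

# Well-separated catalog: thresholds 3 dB apart and boundary widths well
# below the narrowest category band, so every entry has a distinct modal
# response pattern over a range-spanning probe.
separated_catalog <- function(n = 20, width = 2) {
  entries <- lapply(seq_len(n), function(i) {
    l1 <- 3 * (i - 1)
    l10 <- 88 + (i - 1)
    sev <- min(max((l1 - 20) / 60, 0), 1)
    mcpf(clsmei:::place_boundaries(l1, l10, 0.4, sev), width,
         entry_id = sprintf("sep_%02d", i))
  })
  clsmei:::new_catalog(entries, 1000)
}

# Deterministic responder with a hard threshold and "Too Loud" point:
# inaudible below `lo`, Too Loud above `hi`, interior CU grows linearly.
scripted_responder <- function(lo, hi) {
  force(lo); force(hi)
  function(level) {
    if (level < lo) return(0L)
    if (level > hi) return(50L)
    cu <- 5 * round(9 * (level - lo) / (hi - lo))
    as.integer(min(max(cu, 5L), 45L))
  }
}

# Independent brute-force MEI selection: explicit loops over candidate
# levels, the 11 responses and the catalog entries, using only
# category_probs() and base arithmetic. Mirrors the definition, not the
# implementation.
brute_force_mei <- function(probs, catalog, constraints) {
  grid <- seq(0, 110, by = constraints$level_grid_step)
  grid <- grid[grid >= constraints$lower_limit & grid <= constraints$upper_limit]
  prev <- constraints$previous_level
  if (!is.null(prev)) {
    grid <- grid[abs(grid - prev) <= constraints$max_transition]
    if (constraints$forbid_consecutive_repeat) grid <- grid[grid != prev]
  }
  n <- length(catalog)
  epe <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    lev <- grid[gi]
    likmat <- matrix(NA_real_, n, 11)
    for (i in seq_len(n)) {
      likmat[i, ] <- pmax(category_probs(catalog$entries[[i]], lev), 1e-6)
    }
    total <- 0
    acc <- 0
    for (c in 1:11) {
      w <- probs * likmat[, c]
      mc <- sum(w)
      post <- w / mc
      h <- -sum(ifelse(post > 0, post * log2(post), 0))
      acc <- acc + mc * h
      total <- total + mc
    }
    epe[gi] <- acc / total
  }
  list(level = grid[which(epe <= min(epe) + 1e-12)][1], epe = epe, grid = grid)
}

# Session log built directly from (level, response) pairs, for testing
# the estimators without running a tracker.
manual_session <- function(levels, responses, procedure = "fixed",
                           dr = dynamic_range(min(levels), max(levels))) {
  trials <- data.frame(index = seq_along(levels),
                       run = 1L,
                       level = levels,
                       response_cu = as.integer(responses),
                       procedure = procedure,
                       entropy_after = NA_real_)
  clsmei:::new_session_log(trials, dr, procedure, 1000, 1L)
}
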