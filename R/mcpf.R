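# Multi-category psychometric functions (MCPFs).
#
# An MCPF characterises a listener's categorical loudness judgements as a
# stack of ten ordered boundary psychometric functions. Boundary k gives
# the probability that the response is at least CU 5k at a given level;
# differencing adjacent boundaries yields the probability of each of the
# 11 loudness categories at that level.

#' The 11-category loudness scale
#'
#' Categorical loudness scaling assigns each judgement a categorical unit
#' (CU) from 0 ("Can't Hear") to 50 ("Too Loud") in steps of 5. Seven of
#' the 11 categories carry verbal labels; the intermediate bars on the
#' response screen are unlabelled.
#'
#' @return A data frame with columns `cu` (integer, 0 to 50 by 5) and
#'   `label` (character, `""` for unlabelled categories).
#' @export
#' @examples
#' cu_scale()
cu_scale <- function() {
  data.frame(
    cu = seq(0L, 50L, by = 5L),
    label = c("Can't Hear", "Very Soft", "", "Soft", "", "Medium", "",
              "Loud", "", "Very Loud", "Too Loud"),
    stringsAsFactors = FALSE
  )
}

# CU codes, used throughout as the canonical category index.
cu_values <- function() seq(0L, 50L, by = 5L)

#' Construct a multi-category psychometric function
#'
#' Builds a listener model from ten logistic boundary functions. Boundary
#' `k` is the psychometric function for the transition between CU `5(k-1)`
#' and CU `5k`: `Psi_k(L) = 1 / (1 + exp(-(L - L_k) / w_k))`, where `L_k`
#' is the 50% point (dB SPL) and `w_k` the width (dB). Category
#' probabilities are differences of adjacent boundaries, so the entry is
#' only accepted if the boundaries never cross: all 11 category
#' probabilities must be non-negative on a 1-dB grid over 0-110 dB SPL.
#'
#' @param boundary_levels Numeric vector of 10 strictly increasing 50%
#'   points, dB SPL.
#' @param boundary_widths Numeric vector of 10 positive widths, dB. A
#'   single value is recycled.
#' @param entry_id Character identifier, unique within a catalog.
#' @param frequency_hz Stimulus frequency label (metadata only).
#' @param metadata Optional named list (e.g. hearing-status label).
#' @return An object of class `mcpf`.
#' @seealso [boundary_prob()], [category_probs()], [cls_function_from_mcpf()]
#' @export
#' @examples
#' m <- mcpf(seq(10, 100, by = 10), 5)
#' category_probs(m, 55)
mcpf <- function(boundary_levels, boundary_widths, entry_id = "mcpf",
                 frequency_hz = 1000, metadata = list()) {
  boundary_levels <- as.numeric(boundary_levels)
  if (length(boundary_widths) == 1L) {
    boundary_widths <- rep(as.numeric(boundary_widths), 10L)
  }
  boundary_widths <- as.numeric(boundary_widths)
  if (length(boundary_levels) != 10L || length(boundary_widths) != 10L) {
    stop("an MCPF requires 10 boundary levels and 10 boundary widths",
         call. = FALSE)
  }
  if (anyNA(boundary_levels) || anyNA(boundary_widths)) {
    stop("boundary parameters must be finite", call. = FALSE)
  }
  if (any(diff(boundary_levels) <= 0)) {
    stop(sprintf("entry '%s': boundary levels must be strictly increasing",
                 entry_id), call. = FALSE)
  }
  if (any(boundary_widths <= 0)) {
    stop(sprintf("entry '%s': boundary widths must be positive", entry_id),
         call. = FALSE)
  }
  obj <- structure(
    list(entry_id = as.character(entry_id),
         frequency_hz = frequency_hz,
         boundary_levels = boundary_levels,
         boundary_widths = boundary_widths,
         metadata = metadata),
    class = "mcpf"
  )
  pm <- mcpf_prob_matrix(obj, seq(0, 110, by = 1))
  if (min(pm) < -1e-12) {
    stop(sprintf(
      "entry '%s': crossing boundary functions produce negative category probabilities",
      entry_id), call. = FALSE)
  }
  obj
}

#' @export
print.mcpf <- function(x, ...) {
  cat("<mcpf> entry", x$entry_id, "at", x$frequency_hz, "Hz\n")
  cat("  boundary levels (dB SPL):",
      paste(formatC(x$boundary_levels, format = "f", digits = 1),
            collapse = " "), "\n")
  cat("  boundary widths (dB):   ",
      paste(formatC(x$boundary_widths, format = "f", digits = 1),
            collapse = " "), "\n")
  invisible(x)
}

#' Boundary psychometric function
#'
#' Probability that the response is at least CU `5k` when a tone is
#' presented at `level` dB SPL; the logistic boundary function
#' `Psi_k(L) = 1 / (1 + exp(-(L - L_k) / w_k))`.
#'
#' @param mcpf An [mcpf()] object.
#' @param k Boundary index, 1 to 10.
#' @param level Stimulus level(s), dB SPL.
#' @return Probability (vectorised over `level`), non-decreasing in level.
#' @export
#' @examples
#' m <- mcpf(seq(10, 100, by = 10), 5)
#' boundary_prob(m, 6, 65)  # 0.5 at the 50% point
boundary_prob <- function(mcpf, k, level) {
  stopifnot(inherits(mcpf, "mcpf"))
  if (!is_scalar_number(k) || k < 1 || k > 10 || k != round(k)) {
    stop("boundary index k must be an integer in 1..10", call. = FALSE)
  }
  stats::plogis((level - mcpf$boundary_levels[k]) / mcpf$boundary_widths[k])
}

# 11 x length(levels) matrix of category probabilities. Row j+1 is
# P(CU = 5j | level); columns sum to 1 exactly by telescoping.
mcpf_prob_matrix <- function(mcpf, levels) {
  psi <- vapply(seq_len(10L), function(k) {
    stats::plogis((levels - mcpf$boundary_levels[k]) / mcpf$boundary_widths[k])
  }, numeric(length(levels)))
  psi <- matrix(psi, nrow = length(levels), ncol = 10L)
  upper <- cbind(rep(1, length(levels)), psi)      # Psi_0 .. Psi_9 shifted
  lower <- cbind(psi, rep(0, length(levels)))      # Psi_1 .. Psi_11
  t(upper - lower)
}

#' Category probabilities at a level
#'
#' Probability of each of the 11 loudness categories at one stimulus
#' level: `P(CU = 5j | L) = Psi_j(L) - Psi_(j+1)(L)` with `Psi_0 = 1` and
#' `Psi_11 = 0`. The vector sums to 1 by construction.
#'
#' @param mcpf An [mcpf()] object.
#' @param level A single stimulus level, dB SPL.
#' @return Named numeric vector of 11 probabilities, names are CU codes.
#' @export
#' @examples
#' m <- mcpf(seq(10, 100, by = 10), 5)
#' sum(category_probs(m, 42))  # 1
category_probs <- function(mcpf, level) {
  stopifnot(inherits(mcpf, "mcpf"), is_scalar_number(level))
  p <- drop(mcpf_prob_matrix(mcpf, level))
  names(p) <- as.character(cu_values())
  p
}

#' Expected CU at a level
#'
#' Mean categorical unit under the category distribution at one level;
#' non-decreasing in level for any valid MCPF.
#'
#' @inheritParams category_probs
#' @return Expected CU (numeric scalar).
#' @export
expected_cu <- function(mcpf, level) {
  sum(category_probs(mcpf, level) * cu_values())
}

#' CLS loudness-growth function of an MCPF
#'
#' The conventional loudness-growth function of a catalog entry: the 50%
#' point of each boundary function is taken as the level at which the
#' response reaches the corresponding CU. For the logistic
#' parameterisation these are exactly the entry's boundary levels. CU 0
#' carries no bounded level (any sufficiently soft tone is inaudible) and
#' the CU 50 point is retained structurally but flagged as excluded from
#' analyses, mirroring how the unbounded extreme categories are handled.
#'
#' @param mcpf An [mcpf()] object.
#' @return A [cls_function] with levels for CU 5 to 50, method `"ml"`.
#' @export
cls_function_from_mcpf <- function(mcpf) {
  stopifnot(inherits(mcpf, "mcpf"))
  new_cls_function(cu = seq(5L, 50L, by = 5L),
                   level = mcpf$boundary_levels,
                   method = "ml",
                   source = mcpf$entry_id)
}
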