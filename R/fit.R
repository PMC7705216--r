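# Estimating CLS loudness-growth functions from trial-by-trial session
# logs: the median-per-category method, the maximum-likelihood catalog
# fit, CU-to-phon conversion, and threshold estimation.

#' Median-per-category CLS function
#'
#' For every CU that received at least one response, the estimated level
#' is the median of the levels that received that CU (midpoint convention
#' for even counts). No outlier removal is applied; with sparse adaptive
#' data a median may rest on a single response. CUs never used by the
#' listener are simply missing, and CU 0/50 rows are flagged excluded
#' because their level sets are unbounded.
#'
#' @param log A `cls_session`.
#' @return A `cls_function`, method `"median"`.
#' @export
median_cls <- function(log) {
  stopifnot(inherits(log, "cls_session"))
  if (nrow(log$trials) == 0L) {
    stop("empty session log", call. = FALSE)
  }
  med <- tapply(log$trials$level, factor(log$trials$response_cu,
                                         levels = cu_values()),
                stats::median)
  present <- !is.na(med)
  new_cls_function(cu = cu_values()[present],
                   level = as.numeric(med[present]),
                   method = "median",
                   source = log$procedure)
}

#' Maximum-likelihood catalog fit
#'
#' Selects the catalog entry maximising the log-likelihood of the
#' session's stimulus/response pairs, `sum(log P_i(response | level))`
#' with the same likelihood floor used during tracking (so the ML fit is
#' the posterior mode under the uniform prior). Ties are broken toward
#' the lowest entry index. Because the entry carries a full MCPF, the
#' resulting CLS function is smoothed across categories: categories the
#' listener never used still receive levels.
#'
#' @param log A `cls_session`.
#' @param catalog A `cls_catalog`.
#' @return A list with `entry_id`, `entry_index`, `log_likelihood`, and
#'   `cls` (a `cls_function` via [cls_function_from_mcpf()]).
#' @export
ml_cls <- function(log, catalog) {
  stopifnot(inherits(log, "cls_session"), inherits(catalog, "cls_catalog"))
  if (nrow(log$trials) == 0L) {
    stop("empty session log", call. = FALSE)
  }
  ulev <- sort(unique(log$trials$level))
  lik <- catalog_likelihoods(catalog, ulev)
  n <- length(catalog)
  flat <- matrix(lik, nrow = n, ncol = 11L * length(ulev))
  lev_idx <- match(log$trials$level, ulev)
  resp_idx <- match(log$trials$response_cu, cu_values())
  if (anyNA(resp_idx)) {
    stop("session log contains responses off the CU scale", call. = FALSE)
  }
  cols <- (lev_idx - 1L) * 11L + resp_idx
  ll <- rowSums(log(flat[, cols, drop = FALSE]))
  best <- which.max(ll)   # which.max returns the first (lowest) maximiser
  entry <- catalog$entries[[best]]
  cls <- cls_function_from_mcpf(entry)
  cls$method <- "ml"
  cls$source <- entry$entry_id
  list(entry_id = entry$entry_id,
       entry_index = best,
       log_likelihood = ll[best],
       cls = cls)
}

#' CU-to-phon conversion map
#'
#' A monotone anchor table mapping categorical units to loudness level in
#' phon; intermediate CUs are linearly interpolated. The packaged default
#' is a synthetic linear map (phon = 2.2 CU, so "Medium" = 25 CU sits at
#' 55 phon and "Too Loud" = 50 CU at 110 phon); substitute a published
#' conversion table for real analyses. The map identifier travels with
#' every converted function.
#'
#' @param cu Anchor CUs (must cover 5 to 45).
#' @param phon Strictly increasing phon values at the anchors.
#' @param id Identifier for the conversion source.
#' @return An object of class `phon_map`.
#' @export
phon_map <- function(cu, phon, id = "custom") {
  stopifnot(length(cu) == length(phon), length(cu) >= 2)
  ord <- order(cu)
  cu <- as.numeric(cu[ord]); phon <- as.numeric(phon[ord])
  if (any(diff(cu) <= 0) || any(diff(phon) <= 0)) {
    stop("phon map anchors must be strictly increasing in CU and phon",
         call. = FALSE)
  }
  structure(list(cu = cu, phon = phon, id = id), class = "phon_map")
}

#' @rdname phon_map
#' @export
default_phon_map <- function() {
  phon_map(seq(0, 50, by = 5), 2.2 * seq(0, 50, by = 5),
           id = "synthetic-linear-2.2")
}

#' Convert a CLS function from CU to phon
#'
#' Relabels the loudness axis through a [phon_map()]; the level estimates
#' are untouched. The map must cover CU 5 to 45 (the analysed
#' categories).
#'
#' @param fn A `cls_function`.
#' @param map A [phon_map()] (default [default_phon_map()]).
#' @return The `cls_function` with a `loudness_phon` column added and the
#'   map id recorded in `$phon_map_id`.
#' @export
cu_to_phon <- function(fn, map = default_phon_map()) {
  stopifnot(inherits(fn, "cls_function"), inherits(map, "phon_map"))
  if (min(map$cu) > 5 || max(map$cu) < 45) {
    stop("phon map must cover CU 5 through 45", call. = FALSE)
  }
  fn$points$loudness_phon <- stats::approx(map$cu, map$phon,
                                           xout = fn$points$cu,
                                           rule = 1)$y
  fn$phon_map_id <- map$id
  fn
}

#' Threshold estimate from a CLS function
#'
#' The level corresponding to 2.5 CU — midway between "Can't Hear" (0 CU)
#' and "Very Soft" (5 CU), i.e. the level audible half the time — by
#' ordinary least squares on the (level, CU) points with CU <= 20, where
#' loudness grows linearly with level. If fewer than two such points are
#' available (sparse adaptive data), the lowest level present in the
#' function is returned instead.
#'
#' @param fn A `cls_function`.
#' @return Threshold estimate, dB SPL.
#' @export
#' @examples
#' fn <- clsmei:::new_cls_function(c(5, 10, 15, 20), c(25, 35, 45, 55), "median")
#' estimate_threshold(fn)  # exact line, 2.5 CU at 20 dB SPL
estimate_threshold <- function(fn) {
  stopifnot(inherits(fn, "cls_function"))
  pts <- fn$points[!fn$points$excluded, , drop = FALSE]
  if (nrow(pts) == 0L) {
    stop("CLS function has no analysable (CU 5-45) points", call. = FALSE)
  }
  low <- pts[pts$cu <= 20, , drop = FALSE]
  if (nrow(low) < 2L) {
    return(min(pts$level_db_spl))
  }
  if (length(unique(low$level_db_spl)) < 2L) {
    stop("degenerate regression: all CU <= 20 levels identical",
         call. = FALSE)
  }
  fit <- stats::lm(cu ~ level_db_spl, data = low)
  b <- stats::coef(fit)
  as.numeric((2.5 - b[1]) / b[2])
}
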