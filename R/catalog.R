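# MCPF catalogs: the finite hypothesis space for Bayesian tracking. A
# catalog bundles validated MCPF entries with the generator provenance
# (parameters + seed) needed to replay a simulation study.

#' Parameters for synthetic catalog generation
#'
#' Describes a population of loudness-growth functions spanning normal
#' hearing through moderate sensorineural loss. Each entry is built by
#' sampling the softest boundary (CU 5, roughly threshold) and the
#' loudest boundary (CU 50, the "Too Loud" point) and placing the
#' interior boundaries by a two-segment bent-line interpolation whose
#' bend grows with the sampled degree of loss: entries with elevated
#' thresholds get steep low-level loudness growth (recruitment) and a
#' compressed dynamic range.
#'
#' @param n_entries Number of catalog entries (default 1460, the scale of
#'   the reference catalog this generator stands in for).
#' @param threshold_range Interval (dB SPL) for the CU-5 boundary, from
#'   normal hearing to moderate loss.
#' @param upper_range Interval (dB SPL) for the CU-50 boundary.
#' @param min_dynamic_range Minimum CU-50 minus CU-5 span, dB.
#' @param width_range Interval (dB) for the common per-entry boundary
#'   width.
#' @param knee_fraction_range Interval for the position of the bent-line
#'   knee along the CU axis (fraction of the 10 boundaries).
#' @param frequency_hz Stimulus frequency label.
#' @param seed Integer seed; mandatory so catalogs are replayable.
#' @return An object of class `catalog_gen_params`.
#' @export
catalog_gen_params <- function(n_entries = 1460,
                               threshold_range = c(0, 60),
                               upper_range = c(85, 110),
                               min_dynamic_range = 30,
                               width_range = c(3, 10),
                               knee_fraction_range = c(0.25, 0.6),
                               frequency_hz = 1000,
                               seed = 1L) {
  stopifnot(is_scalar_number(n_entries), n_entries >= 2,
            length(threshold_range) == 2, diff(threshold_range) >= 0,
            length(upper_range) == 2, diff(upper_range) >= 0,
            is_scalar_number(min_dynamic_range), min_dynamic_range > 0,
            length(width_range) == 2, all(width_range > 0),
            length(knee_fraction_range) == 2,
            all(knee_fraction_range > 0), all(knee_fraction_range < 1),
            is_scalar_number(seed))
  if (max(upper_range) - min(threshold_range) < min_dynamic_range) {
    stop("infeasible ranges: even the widest threshold/upper combination ",
         "cannot reach min_dynamic_range", call. = FALSE)
  }
  structure(list(n_entries = as.integer(n_entries),
                 threshold_range = as.numeric(threshold_range),
                 upper_range = as.numeric(upper_range),
                 min_dynamic_range = as.numeric(min_dynamic_range),
                 width_range = as.numeric(width_range),
                 knee_fraction_range = as.numeric(knee_fraction_range),
                 frequency_hz = frequency_hz,
                 seed = as.integer(seed)),
            class = "catalog_gen_params")
}

# Bent-line placement of the 10 boundary levels. `severity` in [0, 1]
# controls the bend: 0 gives equal spacing, 1 compresses the low-CU
# segment (steep growth just above threshold).
place_boundaries <- function(l1, l10, knee_x, severity) {
  t <- (0:9) / 9
  knee_y <- knee_x * (1 - 0.7 * severity)
  g <- ifelse(t <= knee_x,
              t * knee_y / knee_x,
              knee_y + (t - knee_x) * (1 - knee_y) / (1 - knee_x))
  l1 + (l10 - l1) * g
}

#' Generate a synthetic MCPF catalog
#'
#' Deterministic given the seed in `params`. Every entry passes full MCPF
#' validation; entries get ids `mcpf_0001`, `mcpf_0002`, ...
#'
#' @param params A [catalog_gen_params()] object.
#' @return An object of class `cls_catalog`.
#' @export
#' @examples
#' cat20 <- generate_catalog(catalog_gen_params(n_entries = 20, seed = 7))
#' length(cat20)
generate_catalog <- function(params) {
  stopifnot(inherits(params, "catalog_gen_params"))
  local_seed(params$seed, {
    entries <- vector("list", params$n_entries)
    for (i in seq_len(params$n_entries)) {
      entry <- NULL
      for (attempt in seq_len(1000L)) {
        l1 <- stats::runif(1, params$threshold_range[1], params$threshold_range[2])
        l10 <- stats::runif(1, params$upper_range[1], params$upper_range[2])
        if (l10 - l1 < params$min_dynamic_range) next
        # threshold elevation on an absolute audiological scale: <= 20 dB
        # SPL counts as normal hearing (no bend), 80 dB as profound
        severity <- min(max((l1 - 20) / 60, 0), 1)
        knee_x <- stats::runif(1, params$knee_fraction_range[1],
                               params$knee_fraction_range[2])
        levels <- place_boundaries(l1, l10, knee_x, severity)
        width <- stats::runif(1, params$width_range[1], params$width_range[2])
        # cap the common width at a third of the tightest boundary gap so
        # adjacent categories keep appreciable mass
        width <- min(width, max(min(diff(levels)) / 3, 0.5))
        entry <- tryCatch(
          mcpf(levels, width,
               entry_id = sprintf("mcpf_%04d", i),
               frequency_hz = params$frequency_hz,
               metadata = list(severity = severity)),
          error = function(e) NULL)
        if (!is.null(entry)) break
      }
      if (is.null(entry)) {
        stop("could not generate a valid entry under the given ranges",
             call. = FALSE)
      }
      entries[[i]] <- entry
    }
    new_catalog(entries, params$frequency_hz,
                provenance = list(params = unclass(params), seed = params$seed))
  })
}

new_catalog <- function(entries, frequency_hz, provenance = list()) {
  if (length(entries) < 2L) {
    stop("a catalog requires at least 2 entries", call. = FALSE)
  }
  ids <- vapply(entries, function(e) e$entry_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate entry_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries,
                 frequency_hz = frequency_hz,
                 provenance = provenance),
            class = "cls_catalog")
}

#' @export
length.cls_catalog <- function(x) length(x$entries)

#' @export
print.cls_catalog <- function(x, ...) {
  cat("<cls_catalog>", length(x$entries), "MCPF entries at",
      x$frequency_hz, "Hz\n")
  if (!is.null(x$provenance$seed)) {
    cat("  generated with seed", x$provenance$seed, "\n")
  }
  invisible(x)
}

#' Read and write MCPF catalogs as JSON
#'
#' The on-disk schema is
#' `{frequency_hz, provenance: {params, seed}, entries: [{entry_id,
#' frequency_hz, boundary_levels, boundary_widths, metadata}, ...]}`.
#' Entries are fully re-validated on read; a malformed or crossing entry
#' is rejected with its `entry_id` in the message.
#'
#' @param catalog A `cls_catalog`.
#' @param path JSON file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog`
#'   returns a `cls_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "cls_catalog"))
  payload <- list(
    frequency_hz = catalog$frequency_hz,
    provenance = catalog$provenance,
    entries = lapply(catalog$entries, function(e) {
      list(entry_id = e$entry_id,
           frequency_hz = e$frequency_hz,
           boundary_levels = e$boundary_levels,
           boundary_widths = e$boundary_widths,
           metadata = e$metadata)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$entries)) {
    stop("not a catalog file: no 'entries' field in ", path, call. = FALSE)
  }
  entries <- lapply(raw$entries, function(e) {
    id <- if (is.null(e$entry_id)) "<missing id>" else e$entry_id
    if (length(e$boundary_levels) != 10L || length(e$boundary_widths) != 10L) {
      stop(sprintf("entry '%s': expected 10 boundary levels and widths", id),
           call. = FALSE)
    }
    mcpf(unlist(e$boundary_levels), unlist(e$boundary_widths),
         entry_id = id,
         frequency_hz = if (is.null(e$frequency_hz)) raw$frequency_hz else e$frequency_hz,
         metadata = if (is.null(e$metadata)) list() else e$metadata)
  })
  new_catalog(entries, raw$frequency_hz,
              provenance = if (is.null(raw$provenance)) list() else raw$provenance)
}
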