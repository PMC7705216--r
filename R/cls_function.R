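# CLS loudness-growth functions: per-CU level estimates produced either
# from raw trial data (median method) or from a fitted catalog entry
# (maximum-likelihood method). The extreme categories CU 0 ("Can't Hear")
# and CU 50 ("Too Loud") correspond to unbounded level sets, so they are
# kept in the structure but flagged as excluded from analyses.

new_cls_function <- function(cu, level, method, source = NA_character_) {
  stopifnot(length(cu) == length(level))
  ord <- order(cu)
  df <- data.frame(cu = as.integer(cu[ord]),
                   level_db_spl = as.numeric(level[ord]),
                   excluded = as.integer(cu[ord]) %in% c(0L, 50L))
  structure(list(points = df,
                 method = match.arg(method, c("median", "ml")),
                 source = source),
            class = "cls_function")
}

#' @export
print.cls_function <- function(x, ...) {
  cat("<cls_function>", x$method, "method",
      if (!is.na(x$source)) paste0("(source: ", x$source, ")"), "\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Per-CU levels of a CLS function
#'
#' @param fn A `cls_function`.
#' @param include_excluded Keep the unbounded CU 0/50 rows? Default drops
#'   them, matching how downstream statistics treat them.
#' @return Named numeric vector of levels (dB SPL), names are CU codes.
#' @export
cls_levels <- function(fn, include_excluded = FALSE) {
  stopifnot(inherits(fn, "cls_function"))
  pts <- fn$points
  if (!include_excluded) pts <- pts[!pts$excluded, , drop = FALSE]
  stats::setNames(pts$level_db_spl, pts$cu)
}

#' Write / read a CLS function as CSV
#'
#' Columns: `cu`, `level_db_spl`, `loudness_phon` (NA unless converted),
#' `method`, `excluded`.
#'
#' @param fn A `cls_function`.
#' @param path File path.
#' @return `write_cls_function` returns `path` invisibly;
#'   `read_cls_function` returns a `cls_function`.
#' @export
write_cls_function <- function(fn, path) {
  stopifnot(inherits(fn, "cls_function"))
  df <- fn$points
  df$loudness_phon <- if (is.null(fn$points$loudness_phon)) NA_real_ else fn$points$loudness_phon
  df$method <- fn$method
  utils::write.csv(df[, c("cu", "level_db_spl", "loudness_phon", "method",
                          "excluded")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cls_function
#' @export
read_cls_function <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cu", "level_db_spl", "method")
  if (!all(need %in% names(df))) {
    stop("not a CLS function CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  fn <- new_cls_function(df$cu, df$level_db_spl, method = df$method[1])
  if ("loudness_phon" %in% names(df) && !all(is.na(df$loudness_phon))) {
    fn$points$loudness_phon <- df$loudness_phon[order(df$cu)]
  }
  fn
}
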