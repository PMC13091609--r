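## Per-position summary statistics, kernel density estimates and histograms.
## Conventions: std is the population standard deviation (divide by n);
## skewness is the Fisher-Pearson moment coefficient g1 = m3 / m2^(3/2);
## kurtosis is excess kurtosis g2 = m4 / m2^2 - 3.  Zero-variance (and
## single-sample) segments yield std 0 and skewness/kurtosis 0 by convention.

stat_mean <- function(x) mean(x)
stat_median <- function(x) stats::median(x)
stat_std <- function(x) sqrt(mean((x - mean(x))^2))
stat_duration <- function(x) length(x)
stat_max <- function(x) max(x)
stat_min <- function(x) min(x)
stat_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
stat_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

BUILTIN_STATS <- list(mean = stat_mean, median = stat_median, std = stat_std,
                      duration = stat_duration, max = stat_max,
                      min = stat_min, skewness = stat_skewness,
                      kurtosis = stat_kurtosis)

## normalize a stats argument (character names and/or named functions) to a
## named list of functions
resolve_stats <- function(specs) {
  if (is.character(specs)) specs <- as.list(specs)
  if (!is.list(specs)) stop2("stats must be names or a named list of functions")
  out <- list()
  nm <- names(specs) %||% rep("", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (is.character(s)) {
      if (!s %in% names(BUILTIN_STATS))
        stop2("unknown statistic '", s, "'; available: ",
              paste(names(BUILTIN_STATS), collapse = ", "))
      out[[s]] <- BUILTIN_STATS[[s]]
    } else if (is.function(s)) {
      if (!nzchar(nm[[i]])) stop2("custom statistic functions must be named")
      out[[nm[[i]]]] <- s
    } else stop2("each statistic must be a builtin name or a function")
  }
  if (anyDuplicated(names(out))) stop2("duplicate statistic names")
  out
}

#' Per-read, per-position summary statistics for extracted windows
#'
#' @param extractions one [extract_window()] result or a list of them
#'   (conditions are kept apart by label).
#' @param stats builtin statistic names (mean, median, std, duration, max,
#'   min, skewness, kurtosis) and/or named custom functions mapping a sample
#'   vector to a scalar.
#' @param duration_unit "samples" (default) or "ms" (uses each read's sample
#'   rate).
#' @return a \code{position_stat_table}: long data.frame with columns
#'   condition, ref_pos, offset (relative to the window center), statistic,
#'   read_id, value.
#' @export
compute_stats <- function(extractions,
                          stats = c("mean", "median", "std", "duration"),
                          duration_unit = c("samples", "ms")) {
  duration_unit <- match.arg(duration_unit)
  if (inherits(extractions, "window_extraction"))
    extractions <- list(extractions)
  stopifnot(all(vapply(extractions, inherits, logical(1), "window_extraction")))
  fns <- resolve_stats(stats)
  rows <- list()
  for (ex in extractions) {
    if (!length(ex$reads)) next
    center <- ex$window$center
    for (r in ex$reads) {
      for (i in seq_len(ex$window$K)) {
        v <- r$samples[[i]]
        for (s in names(fns)) {
          val <- fns[[s]](v)
          if (s == "duration" && duration_unit == "ms")
            val <- val / r$sample_rate * 1000
          rows[[length(rows) + 1L]] <- list(
            condition = ex$condition_label,
            ref_pos = ex$window$positions[[i]],
            offset = ex$window$positions[[i]] - center,
            statistic = s, read_id = r$read_id, value = as.numeric(val))
        }
      }
    }
  }
  if (!length(rows))
    stop2("no surviving reads in any extraction; nothing to summarize")
  df <- do.call(rbind, lapply(rows, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  class(df) <- c("position_stat_table", "data.frame")
  df
}

#' Export a position statistic table as TSV
#'
#' @param table a [compute_stats()] result.
#' @param path output path.
#' @return the table, invisibly.
#' @export
export_stat_table <- function(table, path) {
  stopifnot(inherits(table, "position_stat_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Gaussian kernel density estimate with Scott's-rule bandwidth
#'
#' Bandwidth is \code{sd(values) * n^(-1/5)}; the grid spans
#' \code{[min - 3 bw, max + 3 bw]} with \code{grid_size} points, so the
#' density integrates to ~1 by the trapezoidal rule.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param grid_size number of grid points.
#' @return object of class \code{signal_kde}: list(grid, density, bandwidth).
#' @export
signal_kde <- function(values, grid_size = 512L) {
  values <- as.numeric(values)
  if (length(unique(values)) < 2L)
    stop2("degenerate distribution (all values identical); ",
          "use signal_histogram() instead")
  n <- length(values)
  bw <- stats::sd(values) * n^(-1 / 5)
  lo <- min(values) - 3 * bw
  hi <- max(values) + 3 * bw
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = lo, to = hi, n = grid_size)
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "signal_kde")
}

#' Mode (grid argmax) of a kernel density estimate
#' @param kde a [signal_kde()] result.
#' @return the grid location of maximum density.
#' @export
kde_mode <- function(kde) {
  stopifnot(inherits(kde, "signal_kde"))
  kde$grid[[which.max(kde$density)]]
}

#' Equal-width histogram
#'
#' Bins span \code{[min, max]}; bins are right-closed (left-open except the
#' first), so counts always sum to the number of values.
#'
#' @param values numeric vector, length >= 1.
#' @param bins number of bins, >= 1.
#' @return list(counts, edges).
#' @export
signal_histogram <- function(values, bins = 30L) {
  values <- as.numeric(values)
  if (!length(values)) stop2("need at least one value")
  if (!is_count(bins) || bins < 1L) stop2("bins must be a positive integer")
  lo <- min(values); hi <- max(values)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = bins + 1L)
  h <- graphics::hist(values, breaks = edges, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  list(counts = h$counts, edges = edges)
}
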