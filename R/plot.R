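## Plotting: sequence-aligned trace geometry, multi-read signal overlays,
## per-position KDE panels, UMAP scatter and GMM contour plots.  Base
## graphics throughout; devices are opened per requested format.

#' Plot styling options
#'
#' @param line_width trace line width.
#' @param color optional named vector of per-condition colors; defaults to a
#'   fixed palette in condition order.
#' @param alpha_mode "auto" (alpha = 10 / n_reads clamped to [0.05, 1]) or
#'   "fixed".
#' @param alpha opacity in (0, 1], used exactly when \code{alpha_mode} is
#'   "fixed".
#' @param line_style "solid", "dashed" or "dotted".
#' @param dpi raster resolution for PNG output.
#' @param highlight_positions reference positions (0-based) to band-highlight.
#' @param annotations list of \code{list(position = <ref pos>, text = <label>)}.
#' @return object of class \code{plot_style}.
#' @export
plot_style <- function(line_width = 1, color = NULL,
                       alpha_mode = c("auto", "fixed"), alpha = 0.6,
                       line_style = c("solid", "dashed", "dotted"),
                       dpi = 150L, highlight_positions = integer(0),
                       annotations = list()) {
  alpha_mode <- match.arg(alpha_mode)
  line_style <- match.arg(line_style)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop2("alpha must lie in (0, 1]")
  structure(list(line_width = line_width, color = color,
                 alpha_mode = alpha_mode, alpha = alpha,
                 line_style = line_style, dpi = as.integer(dpi),
                 highlight_positions = as.integer(highlight_positions),
                 annotations = annotations),
            class = "plot_style")
}

#' Transparency under the automatic rule
#'
#' @param n_reads number of overlaid reads.
#' @return \code{10 / n_reads}, clamped to \code{[0.05, 1]}.
#' @export
auto_alpha <- function(n_reads) min(max(10 / n_reads, 0.05), 1)

style_alpha <- function(style, n_reads) {
  if (style$alpha_mode == "auto") auto_alpha(n_reads) else style$alpha
}

style_lty <- function(style) {
  c(solid = 1L, dashed = 2L, dotted = 3L)[[style$line_style]]
}

#' Sequence-aligned x-coordinates for variable-dwell signal segments
#'
#' Window position n (0-based) occupies the unit interval [n, n+1) on the
#' x-axis; a position with k samples gets them at the k evenly spaced,
#' left-aligned coordinates \code{x_j = n + j/k}, j = 0..k-1.  Amplitudes
#' are never altered.
#'
#' @param segment_lengths integer vector of per-position sample counts, all
#'   >= 1.
#' @return object of class \code{trace_geometry}: list(x = list of numeric
#'   vectors, one per position).
#' @export
#' @examples
#' layout_trace(c(4L))$x[[1]]  # 0.00 0.25 0.50 0.75
layout_trace <- function(segment_lengths) {
  segment_lengths <- as.integer(segment_lengths)
  if (any(segment_lengths < 1L))
    stop2("zero-length segment reached the plot layer; it should have been ",
          "filtered upstream")
  x <- lapply(seq_along(segment_lengths), function(n)
    (n - 1L) + (seq_len(segment_lengths[[n]]) - 1L) / segment_lengths[[n]])
  structure(list(x = x), class = "trace_geometry")
}

open_device <- function(out_path, format, dpi, width = 9, height = 5) {
  format <- tolower(format %||% tools::file_ext(out_path))
  if (!format %in% c("png", "pdf", "svg"))
    stop2("unknown output format '", format,
          "'; supported formats: png, pdf, svg")
  switch(format,
         png = grDevices::png(out_path, width = width, height = height,
                              units = "in", res = dpi),
         pdf = grDevices::pdf(out_path, width = width, height = height),
         svg = grDevices::svg(out_path, width = width, height = height))
  format
}

#' Plot multi-read ionic current traces on the sequence-aligned frame
#'
#' One line per read, colored by condition, with vertical gray boundaries at
#' integer x and reference coordinates/bases labeled below each unit
#' interval.  Consecutive samples are connected across base boundaries
#' (switchable), so each read appears as one continuous trace.
#'
#' @param extractions one [extract_window()] result or a list of them.
#' @param style a [plot_style()].
#' @param out_path optional output file; when NULL, draws on the current
#'   device.
#' @param format "png", "pdf" or "svg" (default: from the file extension).
#' @param connect_bases connect samples across base boundaries.
#' @return invisibly, a list with the per-condition alpha used, highlight
#'   bands (window-index intervals) and read counts.
#' @export
plot_signals <- function(extractions, style = plot_style(), out_path = NULL,
                         format = NULL, connect_bases = TRUE) {
  if (inherits(extractions, "window_extraction"))
    extractions <- list(extractions)
  stopifnot(all(vapply(extractions, inherits, logical(1), "window_extraction")))
  win <- extractions[[1]]$window
  labs <- vapply(extractions, `[[`, character(1), "condition_label")
  cols <- style$color %||% stats::setNames(default_palette(length(labs)), labs)
  if (!is.null(out_path)) {
    open_device(out_path, format, style$dpi)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ylim <- range(unlist(lapply(extractions, function(ex)
    lapply(ex$reads, function(r) range(unlist(r$samples))))), finite = TRUE)
  graphics::plot(NA, xlim = c(0, win$K), ylim = ylim, xaxt = "n",
                 xlab = "reference position", ylab = "current (pA)",
                 main = sprintf("%s:%d (K = %d)", win$reference_name,
                                win$center + 1L, win$K))
  bands <- list()
  for (p in style$highlight_positions) {
    i <- match(p, win$positions)
    if (!is.na(i)) {
      graphics::rect(i - 1L, ylim[[1]], i, ylim[[2]],
                     col = grDevices::adjustcolor("gold", 0.25), border = NA)
      bands[[length(bands) + 1L]] <- c(i - 1L, i)
    }
  }
  graphics::abline(v = 0:win$K, col = "gray70")
  alphas <- numeric(0); nreads <- integer(0)
  for (ex in extractions) {
    n <- length(ex$reads)
    a <- style_alpha(style, max(n, 1L))
    alphas[ex$condition_label] <- a
    nreads[ex$condition_label] <- n
    col <- grDevices::adjustcolor(cols[[ex$condition_label]], a)
    for (r in ex$reads) {
      geo <- layout_trace(r$dwell)
      x <- unlist(geo$x); y <- unlist(r$samples)
      if (connect_bases) {
        graphics::lines(x, y, col = col, lwd = style$line_width,
                        lty = style_lty(style))
      } else {
        for (i in seq_len(win$K))
          graphics::lines(geo$x[[i]], r$samples[[i]], col = col,
                          lwd = style$line_width, lty = style_lty(style))
      }
    }
  }
  ref_bases <- if (length(extractions[[1]]$reads))
    strsplit(extractions[[1]]$reads[[1]]$ref_bases, "")[[1]]
  else rep("", win$K)
  graphics::axis(1, at = seq_len(win$K) - 0.5,
                 labels = paste0(win$positions + 1L, "\n", ref_bases),
                 padj = 0.5, cex.axis = 0.7, tick = FALSE)
  for (an in style$annotations) {
    i <- match(an$position, win$positions)
    if (!is.na(i))
      graphics::text(i - 0.5, ylim[[2]], an$text, pos = 1, cex = 0.8)
  }
  if (length(labs) > 1L)
    graphics::legend("topright", legend = labs, col = cols[labs], lwd = 2,
                     bty = "n", cex = 0.8)
  invisible(list(alpha = alphas, n_reads = nreads, highlight_bands = bands))
}

#' Per-position KDE panels of summary statistics
#'
#' One panel row per statistic and one column per window position;
#' conditions are overlaid within each panel.  Degenerate distributions
#' (all values identical) fall back to a histogram with a warning.
#'
#' @param stat_table a [compute_stats()] result (one or more conditions).
#' @param style a [plot_style()].
#' @param layout "separate" (statistic panels only) or "with_signals" (a
#'   signal-trace row on top; requires \code{extractions}).
#' @param extractions extractions for the "with_signals" layout.
#' @param out_path,format as in [plot_signals()].
#' @return invisibly, list(rows, cols) of the panel grid.
#' @export
plot_stats <- function(stat_table, style = plot_style(),
                       layout = c("separate", "with_signals"),
                       extractions = NULL, out_path = NULL, format = NULL) {
  layout <- match.arg(layout)
  stopifnot(inherits(stat_table, "position_stat_table"))
  stats <- unique(stat_table$statistic)
  positions <- sort(unique(stat_table$ref_pos))
  labs <- unique(stat_table$condition)
  cols <- style$color %||% stats::setNames(default_palette(length(labs)), labs)
  if (!is.null(out_path)) {
    open_device(out_path, format, style$dpi,
                width = max(8, 1.2 * length(positions)),
                height = 2 * (length(stats) + (layout == "with_signals")))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(no.readonly = TRUE)
  # restore par before any device opened above is closed
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  nr <- length(stats); nc <- length(positions)
  if (layout == "with_signals") {
    if (is.null(extractions))
      stop2("layout 'with_signals' needs the extractions")
    graphics::layout(rbind(matrix(1L, 1L, nc),
                           matrix(seq_len(nr * nc) + 1L, nr, nc, byrow = TRUE)))
    graphics::par(mar = c(2.5, 2.5, 1.5, 0.5), cex = 0.6)
    plot_signals(extractions, style)
  } else {
    graphics::par(mfrow = c(nr, nc), mar = c(2, 2, 1.5, 0.5), cex = 0.6)
  }
  for (s in stats) {
    for (p in positions) {
      panels <- lapply(labs, function(l)
        stat_table$value[stat_table$statistic == s & stat_table$ref_pos == p &
                         stat_table$condition == l])
      dens <- lapply(panels, function(v) {
        if (length(unique(v)) < 2L) NULL else signal_kde(v, grid_size = 128L)
      })
      xr <- range(unlist(c(lapply(dens, function(d) if (!is.null(d)) range(d$grid)),
                           panels)))
      yr <- c(0, max(unlist(lapply(dens, function(d)
        if (!is.null(d)) max(d$density) else 1))))
      graphics::plot(NA, xlim = xr, ylim = yr, main = sprintf("%s @ %d", s, p + 1L),
                     xlab = "", ylab = "")
      for (j in seq_along(labs)) {
        if (is.null(dens[[j]])) {
          warning("degenerate distribution for ", s, " at position ", p,
                  " (", labs[[j]], "); histogram drawn instead", call. = FALSE)
          h <- signal_histogram(panels[[j]], bins = 10L)
          graphics::rect(h$edges[-length(h$edges)], 0, h$edges[-1L],
                         h$counts / max(h$counts) * yr[[2]],
                         border = cols[[labs[[j]]]], col = NA)
        } else {
          graphics::lines(dens[[j]]$grid, dens[[j]]$density,
                          col = cols[[labs[[j]]]], lwd = style$line_width,
                          lty = style_lty(style))
        }
      }
    }
  }
  invisible(list(rows = nr, cols = nc))
}

#' Plot read populations: UMAP scatter or GMM clustering
#'
#' UMAP embeddings are drawn as per-read points colored by condition.  GMM
#' fits are drawn as per-read points with per-component density contours and
#' an X marker at each component mean.
#'
#' @param x a [umap_embed()] or [fit_gmm()] result.
#' @param style a [plot_style()].
#' @param out_path,format as in [plot_signals()].
#' @return invisibly, list(n_points, centroids) (centroids NULL for UMAP).
#' @export
plot_populations <- function(x, style = plot_style(), out_path = NULL,
                             format = NULL) {
  if (!is.null(out_path)) {
    open_device(out_path, format, style$dpi, width = 6, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  if (inherits(x, "umap_embedding")) {
    labs <- unique(x$condition)
    cols <- style$color %||% stats::setNames(default_palette(length(labs)), labs)
    graphics::plot(x$coords, col = grDevices::adjustcolor(cols[x$condition], 0.7),
                   pch = 19, cex = 0.6, xlab = "UMAP1", ylab = "UMAP2",
                   main = "UMAP embedding")
    if (length(labs) > 1L)
      graphics::legend("topright", legend = labs, col = cols[labs], pch = 19,
                       bty = "n", cex = 0.8)
    return(invisible(list(n_points = nrow(x$coords), centroids = NULL)))
  }
  if (inherits(x, "gmm_fit")) {
    labs <- unique(x$condition)
    cols <- style$color %||% stats::setNames(default_palette(length(labs)), labs)
    graphics::plot(x$data, col = grDevices::adjustcolor(cols[x$condition], 0.6),
                   pch = 19, cex = 0.6, xlab = x$feature_names[[1]],
                   ylab = x$feature_names[[2]], main = "GMM clustering")
    for (k in seq_len(x$n_components)) {
      mu <- x$means[k, ]; S <- x$covariances[, , k]
      g1 <- seq(mu[[1]] - 3.5 * sqrt(S[1, 1]), mu[[1]] + 3.5 * sqrt(S[1, 1]),
                length.out = 60L)
      g2 <- seq(mu[[2]] - 3.5 * sqrt(S[2, 2]), mu[[2]] + 3.5 * sqrt(S[2, 2]),
                length.out = 60L)
      Si <- solve(S)
      z <- outer(g1, g2, function(u, v) {
        du <- u - mu[[1]]; dv <- v - mu[[2]]
        exp(-0.5 * (Si[1, 1] * du^2 + 2 * Si[1, 2] * du * dv + Si[2, 2] * dv^2))
      })
      graphics::contour(g1, g2, z, levels = c(0.1, 0.3, 0.6, 0.9),
                        add = TRUE, col = "gray40", drawlabels = FALSE)
    }
    graphics::points(x$means, pch = 4, cex = 2, lwd = 3, col = "black")
    if (length(labs) > 1L)
      graphics::legend("topright", legend = labs, col = cols[labs], pch = 19,
                       bty = "n", cex = 0.8)
    return(invisible(list(n_points = nrow(x$data), centroids = x$means)))
  }
  stop2("x must be a umap_embedding or gmm_fit")
}
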