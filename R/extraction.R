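## Window extraction: compose fetch -> CIGAR/MD map -> move-table segments
## -> calibrated signal slices for a K-base reference window, applying the
## read-level filters.

#' Specify a reference window
#'
#' @param reference_name reference sequence name.
#' @param center 0-based reference position of interest.
#' @param K odd window width in bases; the window is the inclusive range
#'   \code{[center - (K-1)/2, center + (K-1)/2]}.
#' @param molecule "DNA" or "RNA" (RNA triggers the signal-time orientation
#'   flip, see [orient_segments()]).
#' @return object of class \code{window_spec}.
#' @export
window_spec <- function(reference_name, center, K = 13L,
                        molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (!is_count(K) || K < 1L || K %% 2L == 0L)
    stop2("K must be an odd positive integer (got ", K, ")")
  if (!is_count(center) || center < 0) stop2("center must be a 0-based position")
  half <- (K - 1L) %/% 2L
  structure(list(reference_name = reference_name, center = as.integer(center),
                 K = as.integer(K), molecule = molecule,
                 positions = as.integer(center - half):as.integer(center + half)),
            class = "window_spec")
}

#' Extraction filter and transformation options
#'
#' @param primary_only keep only primary alignments.
#' @param read_ids optional read-id whitelist.
#' @param max_reads optional cap on fetched reads (BAM iteration order).
#' @param exclude_reads_with_indels drop reads whose alignment has any
#'   insertion or deletion within the window.
#' @param matched_query_base drop reads whose query base differs from the
#'   reference base at any window position (whole-window, i.e. stricter than
#'   a center-only match).
#' @param normalizer optional function applied to the full calibrated signal
#'   before slicing; must preserve the sample count.
#' @return object of class \code{extraction_options}.
#' @export
extraction_options <- function(primary_only = TRUE, read_ids = NULL,
                               max_reads = NULL,
                               exclude_reads_with_indels = FALSE,
                               matched_query_base = FALSE,
                               normalizer = NULL) {
  if (!is.null(normalizer) && !is.function(normalizer))
    stop2("normalizer must be a function(signal) -> signal")
  structure(list(primary_only = isTRUE(primary_only), read_ids = read_ids,
                 max_reads = max_reads,
                 exclude_reads_with_indels = isTRUE(exclude_reads_with_indels),
                 matched_query_base = isTRUE(matched_query_base),
                 normalizer = normalizer),
            class = "extraction_options")
}

#' Extract per-read calibrated signal segments for a reference window
#'
#' For every fetched read the reference-to-query map is built from CIGAR+MD;
#' reads not covering every window position are excluded
#' (\code{incomplete_span}), then the optional indel and query-match filters
#' are applied (\code{indel_in_window}, \code{mismatch_in_window}).  A read
#' whose alignment deletes a window position can never supply a segment
#' there and is excluded with reason \code{deletion_in_window} regardless of
#' the indel flag.  Survivors get, per window position, the calibrated (and
#' optionally normalized) signal samples assigned to that base by the move
#' table.
#'
#' @param condition a [signal_condition()].
#' @param window a [window_spec()].
#' @param options an [extraction_options()].
#' @param index optional pre-built [build_read_index()] for the condition's
#'   signal directory (built on the fly when omitted).
#' @return object of class \code{window_extraction}: list with
#'   \code{condition_label}, \code{window}, \code{reads} (per-read records:
#'   read_id, strand, samples [list of K numeric vectors, pA], dwell
#'   [K sample counts], segments [K x 2 sample bounds in the resolved signal
#'   window], slice [contiguous calibrated samples spanning the segments],
#'   ref_bases, query_bases, sample_rate) and \code{excluded}
#'   (named integer counts by reason).
#' @export
extract_window <- function(condition, window, options = extraction_options(),
                           index = NULL) {
  stopifnot(inherits(condition, "signal_condition"),
            inherits(window, "window_spec"),
            inherits(options, "extraction_options"))
  hdr <- Rsamtools::scanBamHeader(condition$bam_path)[[1]]$targets
  rlen <- hdr[[window$reference_name]]
  if (is.null(rlen))
    stop2("reference '", window$reference_name, "' absent from BAM header")
  wlo <- window$positions[[1]]; whi <- window$positions[[window$K]]
  if (wlo < 0L || whi >= rlen)
    stop2("window [", wlo, ", ", whi, "] falls off reference '",
          window$reference_name, "' (length ", rlen, ")")
  if (is.null(index)) index <- build_read_index(condition$pod5_dir)

  reads <- fetch_reads(condition, window$reference_name, wlo, whi + 1L,
                       primary_only = options$primary_only,
                       read_ids = options$read_ids,
                       max_reads = options$max_reads)
  excluded <- c(incomplete_span = 0L, indel_in_window = 0L,
                mismatch_in_window = 0L, deletion_in_window = 0L)
  kept <- list()
  for (read in reads) {
    map <- build_ref_query_map(read)
    hit <- match(window$positions, map$pairs$ref_pos)
    deleted <- any(map$deletions$ref_start <= whi & map$deletions$ref_end > wlo)
    inserted <- any(map$insertions$ref_anchor > wlo &
                    map$insertions$ref_anchor <= whi)
    if (anyNA(hit) && !deleted) {
      excluded[["incomplete_span"]] <- excluded[["incomplete_span"]] + 1L
      next
    }
    if (options$exclude_reads_with_indels && (deleted || inserted)) {
      excluded[["indel_in_window"]] <- excluded[["indel_in_window"]] + 1L
      next
    }
    if (anyNA(hit)) {   # deletion removed a window position
      excluded[["deletion_in_window"]] <- excluded[["deletion_in_window"]] + 1L
      next
    }
    cols <- map$pairs[hit, ]
    if (options$matched_query_base && any(cols$ref_base != cols$query_base)) {
      excluded[["mismatch_in_window"]] <- excluded[["mismatch_in_window"]] + 1L
      next
    }
    seg <- parse_move_table(read$tags$mv, read$tags$ts, read$tags$ns)$segments
    if (nrow(seg) != nchar(read$query))
      stop2("move table emits ", nrow(seg), " bases but query has ",
            nchar(read$query), " (read ", read$read_id, ")")
    seg <- orient_segments(seg, read$strand, window$molecule)
    sig <- resolve_split_signal(index, read)
    cal <- calibrate(sig)
    if (!is.null(options$normalizer)) {
      cal2 <- options$normalizer(cal)
      if (length(cal2) != length(cal))
        stop2("normalizer changed the sample count (", length(cal), " -> ",
              length(cal2), ")")
      cal <- cal2
    }
    wseg <- seg[cols$query_pos + 1L, , drop = FALSE]
    samples <- lapply(seq_len(window$K), function(i)
      cal[(wseg[i, 1L] + 1L):wseg[i, 2L]])
    lo <- min(wseg[, 1L]); hi <- max(wseg[, 2L])
    kept[[length(kept) + 1L]] <- list(
      read_id = read$read_id, strand = read$strand,
      samples = samples, dwell = wseg[, 2L] - wseg[, 1L],
      segments = wseg, slice_start = lo, slice = cal[(lo + 1L):hi],
      ref_bases = paste(cols$ref_base, collapse = ""),
      query_bases = paste(cols$query_base, collapse = ""),
      sample_rate = sig$sample_rate)
  }
  structure(list(condition_label = condition$label, window = window,
                 reads = kept, excluded = excluded,
                 fetched = length(reads),
                 skipped_missing_tags = attr(reads, "skipped_missing_tags")),
            class = "window_extraction")
}

#' @export
print.window_extraction <- function(x, ...) {
  cat(sprintf("<window_extraction '%s': %s:%d +/- %d, %d read(s) kept, %d excluded>\n",
              x$condition_label, x$window$reference_name, x$window$center,
              (x$window$K - 1L) %/% 2L, length(x$reads), sum(x$excluded)))
  if (sum(x$excluded))
    cat("  excluded by reason:",
        paste(sprintf("%s=%d", names(x$excluded), x$excluded)[x$excluded > 0],
              collapse = ", "), "\n")
  invisible(x)
}

#' Verify segment contiguity for one extracted read
#'
#' Checks that concatenating the read's K per-position segments in signal
#' order reproduces the contiguous calibrated slice between the first and
#' last segment bound.  True by construction for indel-free reads; a
#' self-test for the segment bookkeeping.
#'
#' @param extraction a [extract_window()] result.
#' @param read_id read present in the extraction.
#' @return logical.
#' @export
concat_check <- function(extraction, read_id) {
  stopifnot(inherits(extraction, "window_extraction"))
  ids <- vapply(extraction$reads, `[[`, character(1), "read_id")
  i <- match(read_id, ids)
  if (is.na(i)) stop2("read ", read_id, " not present in extraction")
  r <- extraction$reads[[i]]
  ord <- order(r$segments[, 1L])                # signal order
  concat <- unlist(r$samples[ord], use.names = FALSE)
  isTRUE(all.equal(concat, r$slice, tolerance = 1e-12)) &&
    length(concat) == length(r$slice)
}

#' Export an extraction as a tidy TSV
#'
#' One row per (read, window position) with per-position summary values —
#' the interchange surface for external statistical environments.
#'
#' @param extraction a [extract_window()] result.
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_extraction_tsv <- function(extraction, path) {
  stopifnot(inherits(extraction, "window_extraction"))
  rows <- list()
  for (r in extraction$reads) {
    for (i in seq_len(extraction$window$K)) {
      v <- r$samples[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = extraction$condition_label, read_id = r$read_id,
        ref_pos = extraction$window$positions[[i]],
        ref_base = substr(r$ref_bases, i, i),
        dwell_samples = r$dwell[[i]],
        mean_pA = mean(v), median_pA = stats::median(v),
        std_pA = sqrt(mean((v - mean(v))^2)),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(0), read_id = character(0),
               ref_pos = integer(0), ref_base = character(0),
               dwell_samples = integer(0), mean_pA = numeric(0),
               median_pA = numeric(0), std_pA = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
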