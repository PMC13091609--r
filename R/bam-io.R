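## BAM side of the input layer: experimental conditions and tagged-read
## fetching via Rsamtools.

REQUIRED_TAGS <- c("mv", "ts", "ns", "MD")

#' Declare an experimental condition
#'
#' A condition pairs a sorted+indexed BAM (carrying move-table tags) with the
#' directory holding the corresponding raw signals.
#'
#' @param label short condition label used in plots and tables.
#' @param bam_path path to a coordinate-sorted, indexed BAM file.
#' @param pod5_dir directory of signal-store files for the same reads.
#' @return an object of class \code{signal_condition}.
#' @export
signal_condition <- function(label, bam_path, pod5_dir) {
  if (!file.exists(bam_path)) stop2("BAM file does not exist: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop2("BAM index (.bai) not found for ", bam_path,
          "; sort and index the BAM first (samtools sort; samtools index)")
  if (!dir.exists(pod5_dir)) stop2("signal directory does not exist: ", pod5_dir)
  if (!length(list.files(pod5_dir, pattern = "\\.parquet$")))
    stop2("signal directory contains no signal files: ", pod5_dir)
  structure(list(label = as.character(label), bam_path = bam_path,
                 pod5_dir = pod5_dir),
            class = "signal_condition")
}

#' @export
print.signal_condition <- function(x, ...) {
  cat(sprintf("<condition '%s': %s + %s>\n", x$label, x$bam_path, x$pod5_dir))
  invisible(x)
}

#' Fetch tagged alignments overlapping a reference region
#'
#' Returns alignments overlapping the half-open, 0-based interval
#' \code{[start, end)}.  Reads missing any required tag (mv, ts, ns, MD) are
#' skipped with a warning and counted in the result's
#' \code{"skipped_missing_tags"} attribute.  When \code{max_reads} is set, the
#' first \code{max_reads} reads passing all filters in BAM iteration order
#' (coordinate order) are returned.
#'
#' @param condition a [signal_condition()].
#' @param reference_name reference sequence name present in the BAM header.
#' @param start,end 0-based half-open reference interval, \code{start < end}.
#' @param primary_only drop secondary and supplementary alignments.
#' @param read_ids optional character vector restricting to those read ids.
#' @param max_reads optional cap on the number of reads returned.
#' @return list of \code{aligned_read} objects, each holding
#'   \code{read_id}, \code{query} (sequence as stored in the BAM),
#'   \code{cigar}, \code{strand} ("forward"/"reverse"), \code{reference_name},
#'   \code{reference_start} (0-based), \code{flag} and a \code{tags} list
#'   (\code{mv}, \code{ts}, \code{ns}, \code{sp}, \code{pi}, \code{MD}).
#' @export
fetch_reads <- function(condition, reference_name, start, end,
                        primary_only = TRUE, read_ids = NULL,
                        max_reads = NULL) {
  stopifnot(inherits(condition, "signal_condition"))
  if (!is_count(start) || !is_count(end) || start >= end)
    stop2("need 0-based half-open interval with start < end")
  hdr <- Rsamtools::scanBamHeader(condition$bam_path)[[1]]$targets
  if (!reference_name %in% names(hdr))
    stop2("reference '", reference_name, "' absent from BAM header of ",
          condition$bam_path, " (known: ", paste(names(hdr), collapse = ", "), ")")
  flag <- if (primary_only)
    Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isUnmappedQuery = FALSE)
  else Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  which <- GenomicRanges::GRanges(reference_name,
                                  IRanges::IRanges(start + 1L, end))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "strand", "pos", "cigar", "seq"),
    tag = c("mv", "ts", "ns", "sp", "pi", "MD"),
    which = which, flag = flag)
  res <- Rsamtools::scanBam(condition$bam_path, param = param)[[1]]
  n <- length(res$qname)
  out <- vector("list", n)
  skipped <- 0L
  kept <- 0L
  for (i in seq_len(n)) {
    if (!is.null(read_ids) && !(res$qname[[i]] %in% read_ids)) next
    tagval <- function(nm) {
      v <- res$tag[[nm]]
      if (is.null(v)) NULL else v[[i]]
    }
    tg <- list(mv = tagval("mv"), ts = tagval("ts"), ns = tagval("ns"),
               sp = tagval("sp"), pi = tagval("pi"), MD = tagval("MD"))
    if (is.null(tg$mv) || length(tg$mv) < 2L ||
        is.null(tg$ts) || is.na(tg$ts) || is.null(tg$ns) || is.na(tg$ns) ||
        is.null(tg$MD) || is.na(tg$MD)) {
      skipped <- skipped + 1L
      next
    }
    if (!is.null(tg$sp) && !is.na(tg$sp)) tg$sp <- as.integer(tg$sp)
    else tg$sp <- NULL
    if (is.null(tg$pi) || is.na(tg$pi)) tg$pi <- NULL
    kept <- kept + 1L
    out[[i]] <- structure(list(
      read_id = res$qname[[i]],
      query = as.character(res$seq[i]),
      cigar = res$cigar[[i]],
      strand = if (bitwAnd(res$flag[[i]], 16L) > 0L) "reverse" else "forward",
      reference_name = reference_name,
      reference_start = res$pos[[i]] - 1L,
      flag = res$flag[[i]],
      tags = tg), class = "aligned_read")
    if (!is.null(max_reads) && kept >= max_reads) break
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (skipped > 0L)
    warning(skipped, " read(s) skipped for missing required tags (",
            paste(REQUIRED_TAGS, collapse = "/"), ") in ",
            condition$bam_path, call. = FALSE)
  attr(out, "skipped_missing_tags") <- skipped
  out
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read %s: %s:%d %s, %d bases, stride %d>\n",
              x$read_id, x$reference_name, x$reference_start, x$strand,
              nchar(x$query), x$tags$mv[[1]]))
  invisible(x)
}
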