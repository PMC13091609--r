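## Move-table semantics: the mv tag is a stride followed by a binary vector
## with one entry per signal block of `stride` samples; a 1 marks the block
## where a new base was emitted.  Composing block indices with the signal
## trim (ts) and window length (ns) gives each base's half-open sample
## interval.

#' Parse a move-table tag into per-base signal segments
#'
#' The i-th emitted base's segment starts at \code{ts + stride * b_i}, where
#' \code{b_i} is the block index of the i-th 1 in the move vector, and ends at
#' the start of base i+1 (or at \code{ns} for the last base; the final block
#' may be truncated when \code{ns - ts} is not a multiple of the stride).
#'
#' @param mv_tag integer vector: stride followed by the binary move vector.
#' @param ts integer, samples trimmed at the signal start.
#' @param ns integer, number of samples in the read's signal window.
#' @return list with \code{move_table} (stride, moves, ts, ns) and
#'   \code{segments}, an L x 2 integer matrix of half-open sample intervals
#'   \code{[start, end)} in basecall (signal-time) order.
#' @export
#' @examples
#' parse_move_table(c(2L, 1L, 0L, 1L, 1L), ts = 4, ns = 12)$segments
parse_move_table <- function(mv_tag, ts, ns) {
  mv_tag <- as.integer(mv_tag)
  ts <- as.integer(ts); ns <- as.integer(ns)
  if (length(mv_tag) < 2L) stop2("malformed mv tag: need stride plus moves")
  stride <- mv_tag[[1L]]
  moves <- mv_tag[-1L]
  if (stride < 1L) stop2("malformed mv tag: stride must be >= 1")
  if (any(!moves %in% c(0L, 1L))) stop2("malformed mv tag: moves must be 0/1")
  if (sum(moves) == 0L) stop2("malformed mv tag: no bases emitted (all zeros)")
  if (moves[[1L]] != 1L)
    stop2("malformed mv tag: first move entry must be 1")
  if (ts < 0L) stop2("malformed mv tag: ts must be >= 0")
  if (ts >= ns) stop2("malformed mv tag: ts (", ts, ") must be < ns (", ns, ")")
  blocks <- which(moves == 1L) - 1L          # 0-based block index per base
  starts <- ts + stride * blocks
  if (any(starts >= ns))
    stop2("malformed mv tag: move blocks extend past ns")
  ends <- c(starts[-1L], ns)
  list(move_table = list(stride = stride, moves = moves, ts = ts, ns = ns),
       segments = cbind(start = starts, end = ends))
}

#' Reorder per-base segments into BAM query coordinates
#'
#' [parse_move_table()] yields segments in basecall (signal-time) order.  Two
#' index flips relate that order to the query string stored in the BAM:
#' (a) for reverse-strand alignments the BAM stores the reverse complement,
#' so query position q corresponds to basecall index L-1-q; (b) for RNA the
#' molecule traverses the pore 3'->5' while the basecalled sequence is
#' reported 5'->3', so the i-th emitted base is sequence index L-1-i.
#' Applying both flips cancels to the identity.
#'
#' @param segments L x 2 segment matrix in basecall order.
#' @param strand "forward" or "reverse".
#' @param molecule "DNA" or "RNA".
#' @return L x 2 matrix whose row q+1 is the signal interval of the base at
#'   0-based BAM query coordinate q.
#' @export
orient_segments <- function(segments, strand = c("forward", "reverse"),
                            molecule = c("DNA", "RNA")) {
  strand <- match.arg(strand)
  molecule <- match.arg(molecule)
  if (!is.matrix(segments) || ncol(segments) != 2L)
    stop2("segments must be an L x 2 matrix")
  L <- nrow(segments)
  flip <- xor(strand == "reverse", molecule == "RNA")
  idx <- if (flip) L:1 else seq_len(L)
  segments[idx, , drop = FALSE]
}

#' Resolve the signal window a read's segments index into
#'
#' Split reads carry a parent read id (\code{pi}) and a sample offset
#' (\code{sp}); their move-table coordinates apply to the slice
#' \code{[sp, sp + ns)} of the parent's signal.  Reads without \code{pi} use
#' their own signal over \code{[0, ns)}.
#'
#' @param index a [build_read_index()] result.
#' @param read an \code{aligned_read} from [fetch_reads()].
#' @return a [read_signal()] whose raw array is the resolved \code{ns}-sample
#'   window.
#' @export
resolve_split_signal <- function(index, read) {
  stopifnot(inherits(read, "aligned_read"))
  tg <- read$tags
  ns <- as.integer(tg$ns)
  if (is.null(tg$pi)) {
    sig <- load_read_signal(index, read$read_id)
    if (ns > length(sig$raw))
      stop2("malformed tags: ns (", ns, ") exceeds signal length (",
            length(sig$raw), ") for read ", read$read_id)
    sig$raw <- sig$raw[seq_len(ns)]
    return(sig)
  }
  parent <- tryCatch(load_read_signal(index, tg$pi),
                     error = function(e)
                       stop2("split read ", read$read_id,
                             ": parent signal not found for pi=", tg$pi))
  sp <- as.integer(tg$sp %||% 0L)
  if (sp < 0L || sp + ns > length(parent$raw))
    stop2("malformed tags: slice [", sp, ", ", sp + ns,
          ") outside parent signal of length ", length(parent$raw),
          " (read ", read$read_id, ", parent ", tg$pi, ")")
  read_signal(read_id = read$read_id,
              raw = parent$raw[(sp + 1L):(sp + ns)],
              calibration_offset = parent$calibration_offset,
              calibration_scale = parent$calibration_scale,
              sample_rate = parent$sample_rate)
}
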