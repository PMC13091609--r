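## CIGAR + MD composition: which query base sits at which reference
## position, and what the reference base there is.  The MD tag lets the
## reference sequence be reconstructed without a FASTA.

## tokenize an MD string into match-run lengths, mismatch ref bases and
## deletion runs, in order
parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != md)
    stop2("malformed MD tag: ", md)
  toks
}

#' Map reference positions to query positions for one read
#'
#' Walks the CIGAR emitting (reference, query) coordinate pairs for aligned
#' (M/=/X) columns; insertions advance the query only, deletions the
#' reference only, soft clips the query only (clipped bases get no reference
#' position).  The MD tag is walked in parallel to reconstruct the reference
#' base at every aligned or deleted column.  Hard clips are rejected: the
#' signal of hard-clipped bases cannot be reconstructed.
#'
#' @param read an \code{aligned_read} (needs \code{cigar},
#'   \code{reference_start}, \code{query}, \code{tags$MD}).
#' @return object of class \code{ref_query_map}: a list with
#'   \code{pairs} (data.frame ref_pos, query_pos, ref_base, query_base; both
#'   coordinates 0-based), \code{insertions} (data.frame ref_anchor, length:
#'   insertion between ref_anchor-1 and ref_anchor), and \code{deletions}
#'   (data.frame ref_start, ref_end half-open, ref_bases).
#' @export
build_ref_query_map <- function(read) {
  stopifnot(inherits(read, "aligned_read"))
  cig <- parse_cigar(read$cigar)
  if (any(cig$op %in% c("P", "B")))
    stop2("unsupported CIGAR op '", intersect(cig$op, c("P", "B"))[1],
          "' in read ", read$read_id)
  if (any(cig$op == "H"))
    stop2("hard-clipped read ", read$read_id,
          ": signal for clipped bases cannot be reconstructed; realign ",
          "with soft clipping (minimap2 -Y)")
  bad <- setdiff(cig$op, c("M", "=", "X", "I", "D", "N", "S"))
  if (length(bad)) stop2("unsupported CIGAR op '", bad[1], "'")
  md <- read$tags$MD
  if (is.null(md) || is.na(md)) stop2("read ", read$read_id, " lacks an MD tag")
  toks <- parse_md(md)
  qchars <- strsplit(read$query, "", fixed = TRUE)[[1]]

  qpos <- 0L                     # 0-based query cursor
  rpos <- read$reference_start   # 0-based reference cursor
  ti <- 1L                       # MD token cursor
  run <- 0L                      # remaining match/mismatch columns in token
  run_base <- NA_character_      # mismatch ref base when run is a mismatch
  advance_md <- function() {
    while (run == 0L) {
      if (ti > length(toks)) stop2("MD tag shorter than CIGAR implies: ", md)
      tk <- toks[[ti]]; ti <<- ti + 1L
      if (grepl("^[0-9]+$", tk)) {
        run <<- as.integer(tk); run_base <<- NA_character_
      } else if (startsWith(tk, "^")) {
        stop2("MD/CIGAR mismatch: deletion in MD where CIGAR has aligned ",
              "columns: ", md)
      } else {
        run <<- 1L; run_base <<- toupper(tk)
      }
      # zero-length match runs just separate tokens
    }
  }

  rp <- integer(0); qp <- integer(0); rb <- character(0); qb <- character(0)
  ins <- list(); del <- list()
  for (k in seq_len(nrow(cig))) {
    op <- cig$op[[k]]; len <- cig$len[[k]]
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        advance_md()
        base <- if (is.na(run_base)) toupper(qchars[[qpos + 1L]]) else run_base
        rp <- c(rp, rpos); qp <- c(qp, qpos)
        rb <- c(rb, base); qb <- c(qb, toupper(qchars[[qpos + 1L]]))
        run <- run - 1L
        qpos <- qpos + 1L; rpos <- rpos + 1L
      }
    } else if (op == "I") {
      ins[[length(ins) + 1L]] <- data.frame(ref_anchor = rpos, length = len)
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (run != 0L) stop2("MD/CIGAR mismatch at deletion: ", md)
      if (op == "D") {
        if (ti <= length(toks) && grepl("^[0-9]+$", toks[[ti]]) &&
            toks[[ti]] == "0") ti <- ti + 1L
        if (ti > length(toks) || !startsWith(toks[[ti]], "^"))
          stop2("MD/CIGAR mismatch: CIGAR deletion not mirrored in MD: ", md)
        bases <- toupper(sub("^\\^", "", toks[[ti]])); ti <- ti + 1L
        if (nchar(bases) != len)
          stop2("MD deletion length disagrees with CIGAR: ", md)
        del[[length(del) + 1L]] <- data.frame(ref_start = rpos,
                                              ref_end = rpos + len,
                                              ref_bases = bases)
      }
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }
  # trailing explicit "0" match runs are legal
  while (ti <= length(toks) && grepl("^[0-9]+$", toks[[ti]]) &&
         as.integer(toks[[ti]]) == 0L) ti <- ti + 1L
  if (ti <= length(toks) || run != 0L)
    stop2("MD tag longer than CIGAR implies: ", md)
  structure(list(
    pairs = data.frame(ref_pos = rp, query_pos = qp, ref_base = rb,
                       query_base = qb, stringsAsFactors = FALSE),
    insertions = if (length(ins)) do.call(rbind, ins)
                 else data.frame(ref_anchor = integer(0), length = integer(0)),
    deletions = if (length(del)) do.call(rbind, del)
                else data.frame(ref_start = integer(0), ref_end = integer(0),
                                ref_bases = character(0))),
    class = "ref_query_map")
}

#' @export
print.ref_query_map <- function(x, ...) {
  cat(sprintf("<ref_query_map: %d aligned columns, %d insertion(s), %d deletion(s)>\n",
              nrow(x$pairs), nrow(x$insertions), nrow(x$deletions)))
  invisible(x)
}
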